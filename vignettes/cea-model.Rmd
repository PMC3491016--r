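---
title: "The early-vs-deferred cART decision model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The early-vs-deferred cART decision model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartcea)
```

## The decision problem

HIV-positive patients presenting with CD4 counts of 250–350 cells/µL face a
policy choice in resource-limited settings: start combination antiretroviral
therapy (cART) immediately ("early", Scenario A), or defer until a biannual
CD4 measurement falls below 250 cells/µL ("delayed", Scenario B), as older
eligibility rules required. Early initiation lengthens life but moves the
full drug and monitoring cost stream forward; deferral saves drug costs
temporarily but the patient enters treatment sicker, lives less long, and is
hospitalised more while waiting. `cartcea` implements a deterministic
decision-analytic cohort model of this trade-off and expresses it as a cost
per disability-adjusted life year (DALY) averted, judged against the
WHO-style per-capita-GDP threshold ($490 for the modelled setting).

The cohort is stratified into ten 10-cell baseline CD4 bins (250–259 …
340–350), each represented by its midpoint (`low + 5`, so 255 … 345).
Baseline CD4 is assumed uniform over the window, so cohort means are
unweighted bin averages.

## Life expectancy

Undiscounted life expectancy at cART initiation is a piecewise-linear
function of the CD4 count at initiation, anchored at three published
conditional estimates placed at the midpoints of their source strata:
7.9 years at CD4 25, 9.6 at 125, and 19.3 at 275 cells/µL. Between 125 and
275 the slope is \((19.3-9.6)/150 \approx 0.0647\) years per cell.

Two extrapolation rules are deliberate design choices:

* **Above 275** the 125→275 slope continues uncapped. The cohort's upper
  bins (e.g. midpoint 345 → 23.83 years) live on this extension, so a cap
  would change the headline results.
* **Below 25** the curve is clamped at 7.9 years rather than extrapolated
  toward zero. The base-case cohort never reaches this region (the lowest
  initiation CD4 is 207.75 cells/µL), but sensitivity runs with extreme
  decline rates could, and a negative life expectancy would be nonsense.

The third anchor (25, 7.9) exists precisely so the function is defined below
125 cells/µL; with only the two upper anchors, extrapolation below 125 would
go negative near CD4 0.

## The waiting model

A Scenario B patient is measured at entry (t = 0) at the bin midpoint and
re-measured every 6 months while CD4 falls by a fixed amount per period
(base case 45.75 cells/µL per 6 months; quartiles 30.65 and 62.35 are used
as alternative scenarios). Initiation happens at the first measurement
**strictly below** 250 cells/µL:

* a measurement of exactly 250 (or 253.5, as the 340–350 bin produces after
  two periods) keeps waiting — this strictness is what yields the 18-month
  maximum wait;
* a patient at or above the threshold at entry waits at least one period,
  so the minimum wait is 6 months.

Under the base case the ten bins wait {6,6,6,6,6,12,12,12,12,18} months and
initiate at CD4 counts whose median (mean of the 5th and 6th order
statistics) is 226.375, printed as 226. Scenario B's life expectancy is the
waiting time plus the interpolated life expectancy at the initiation CD4.
The interquartile range of the ten initiation counts depends strongly on
the quartile rule chosen for a 10-point sample; we report
`stats::quantile()` type-7 values and do not treat the IQR as a replication
target.

After initiation, CD4 recovers at 114 cells/µL/year for one year and is
then held flat. Only the resulting stratum (≤350 vs >350 cells/µL) matters
downstream, so the post-year-1 plateau is inconsequential beyond that
boundary.

## Discounting

All benefits and costs are discounted at 3%/year. The original spreadsheet's
exact accrual convention is not recoverable from its outputs, so the
convention is a configurable parameter with three implementations:

* `semiannual_midperiod` (default): life and costs accrue in 6-month slices,
  each slice of size \(s\) contributing \(s\,(1+r)^{-t_{mid}}\); a fractional
  terminal slice is discounted at its own midpoint. This matches the model's
  6-month step structure and reproduces the published discounted values
  within 1%.
* `annual_endperiod`: 1-year slices valued at slice end.
* `continuous`: the closed-form annuity
  \((1+r)^{-d}\,\bigl(1-(1+r)^{-L}\bigr)/\ln(1+r)\).

At 3% and horizons up to 30 years the mid-period and continuous forms agree
to well under 1%; a calibration test in the suite reports which convention
sits closest to the published discounted life expectancies. Deferred
streams are discounted from model entry: a stream of length \(L\) starting
after a wait \(d\) is worth \(D(L)\cdot(1+r)^{-d}\) under time-separable
conventions, and the waiting period itself (being lived) is discounted too.

## DALYs

DALYs averted = YLL + YLD, where

* **YLL** is the difference in *discounted* life expectancy between
  scenarios (early minus deferred), and
* **YLD** is the signed difference in disability-weighted discounted
  life-years: every year lived with HIV carries weight 0.123 and the final
  `aids_years_before_death` (1 year) carries weight 0.5. Because the early
  scenario's longer life accumulates more disability-weighted time, the YLD
  term is negative (about −0.25 at the cohort mean), partially offsetting
  the YLL gain of about 2.23 and yielding ≈1.98 DALYs averted per patient.

The HIV weight is taken as 0.123 (the sourced tabular value) rather than
the rounded 0.1 that sometimes accompanies it in prose; the end-to-end DALY
replication is consistent with 0.123. Both weights are configurable.

The terminal-AIDS year is valued as the difference
\(D(L) - D(L - 1)\) on each scenario's own slice grid; with 6-month slices
the grids of \(L\) and \(L-1\) align except in the final fractional slice,
an effect far below the reporting precision.

## Costs

Three components, all in 2011 USD:

1. **Waiting monitoring** — $84.76/year (clinic personnel, laboratory, other
   medication, radiology) over the waiting interval, discounted.
2. **cART + monitoring** — $305.84/year ($192.44 drugs + $113.40
   maintenance) times the discounted life-years lived on treatment.
3. **Hospitalization** — a fixed 24-month horizon from model entry, split
   into four 6-month intervals. Each interval contributes
   \(0.5 \times \text{days/yr} \times \$31.48\) discounted at the interval
   midpoint, where days/yr (with-OI plus without-OI admissions) is looked up
   from the patient's state at the interval **start**: on/off cART, and CD4
   stratum ≤350 vs >350 cells/µL. Waiting patients are off cART in the
   201–350 stratum (verified, not assumed: the state is computed from the
   trajectory); treated patients reconstitute and may cross into the >350
   stratum mid-horizon.

Two deliberate choices here:

* The horizon runs from **model entry** for both scenarios, not from each
  patient's initiation. Only with a common window do the deferred arm's
  waiting-period admissions (13.8 days/yr off-cART vs ≈0.9 on-cART) land
  inside the costed period, which is what drives its much larger
  hospitalization cost (≈$375 vs ≈$40 at the cohort mean).
* States are evaluated at interval starts with no intra-interval proration;
  the model's resolution is the 6-month interval, and finer proration would
  imply precision the inputs do not have. The immediate-start arm's mean
  hospitalization cost is the quantity most sensitive to this rule (interval
  vs annual granularity moves it between roughly $38 and $44), which is why
  it is checked only loosely.

Net cost is the sum of the three components; the deferred arm's waiting
monitoring is folded into its "Lifetime Cost, cART + Monitoring" column when
rendering the two-scenario table, but stays separable in the underlying
objects.

## Aggregation and the ICER

The summary rows are *lowest* (250–259 bin), *highest* (340–350 bin), and
*mean* — the unweighted average of the ten bins. The mean row must be a bin
average: evaluating the deferred scenario at the single midpoint 300 gives
≈16.0 years, not the ≈16.96 the bin average produces, because the waiting
rule is nonlinear in baseline CD4.

Each row's cost per DALY averted is the **ratio of that row's aggregates**
(mean incremental cost over mean DALYs averted), not the mean of per-bin
ratios. Ratio-of-means is the standard population-level ICER and is what
the replication requires (≈$521/1.978 ≈ $263 at the mean). When a
perturbation produces non-positive DALYs averted or negative incremental
cost, the row is labelled dominated/dominant instead of carrying a signed
ICER, which is meaningless across quadrants.

One known non-replication: the published deferred-arm cells for the
**highest bin** (17.38 undiscounted / 13.54 discounted, and the YLL 3.49,
DALY 3.10, ICER $262 derived from them) cannot be produced by the stated
waiting rule, which gives 16.45 undiscounted years (345 → 299.25 → 253.5 →
207.75, so 1.5 + LE(207.75)). A regression test pins the reconstructed
value; the headline mean-row results are unaffected.

## One-way sensitivity

Eight parameters are varied one at a time over their published ranges, the
rest held at base case, and the mean-row ICER recomputed: annual drug cost
($100–$300), annual maintenance cost ($50–$200), a ±50% joint scale on all
eight inpatient-day rates, the bed-day cost ($15.74–$47.22), the discount
rate (0–6%), the 6-month CD4 decline (its quartiles 30.65–62.35), the
annual waiting cost ($0–$150), and a ±15% joint scale on the
life-expectancy anchors. Scale-type parameters multiply all underlying
values because the quantities they perturb exist only as tables (the LE
function is defined solely by its anchors; the inpatient burden by its
eight rates). Entries are ordered by the width of the ICER interval — the
tornado ordering — and the two cART cost components dominate, since
incremental cost is nearly proportional to the annual treatment total while
DALYs averted do not depend on costs at all.

## The synthetic cohort and what it validates

The microsimulation module generates individual patients with the
statistical structure the deterministic model assumes: baseline CD4 uniform
over 250–350 (continuous, to expose the discretisation error of the ten-bin
model; a bin-atom mode exists for exact-equivalence checks), and a
patient-specific 6-month decline drawn from a lognormal anchored at the
published median (meanlog = ln 45.75) with spread from the quartile ratio
(sdlog = ln(62.35/30.65)/(2 z₀.₇₅) ≈ 0.527). The fitted median and quartile
*ratio* match the published values exactly; the individual quartiles are
≈4.7% off because the published quartiles are not log-symmetric about the
median (their geometric mean is 43.7, not 45.75) — no two-parameter
lognormal can match all three. A three-point q25/median/q75 distribution
(weights ¼/½/¼) is provided as the alternative reading, since the
deterministic analysis only ever evaluates those three rates.

Each simulated patient runs through the *identical* deterministic pipeline,
so with a degenerate cohort (bin-midpoint baselines, fixed median decline)
the cohort means equal the deterministic mean row to machine precision —
the module's core validation. Under full heterogeneity the cohort mean DALY
shifts modestly upward (faster-declining patients lose more), which is a
genuine feature of the heterogeneity, not an error; Monte-Carlo standard
errors scale as \(1/\sqrt{n}\), verified at n = 1k/4k/16k.

What the generator does **not** emulate: measurement error on CD4 counts,
correlation between baseline CD4 and decline rate, treatment failure and
second-line ART, adherence effects, and HIV-transmission benefits of
earlier viral suppression. Passing tests therefore validate the internal
consistency of the cohort model, not those aspects of real cohorts. Whether
the published decline IQR describes between-patient heterogeneity or
estimation uncertainty of a common rate is ambiguous; the package supports
both readings (the microsimulation draws per-patient rates; the sensitivity
module shifts a common rate) without asserting which was intended.

## Numerical conventions and problem sizes

Discount sums use closed-form geometric series (no loops over slices), so
50,000-patient microsimulations are vectorised and run in well under a
minute. Tests use 10-bin deterministic runs (instant), 17 full model runs
for the tornado, and microsimulation cohorts of 1k–20k, chosen to keep the
whole suite around ten seconds while leaving Monte-Carlo noise far below
the tested tolerances. CD4 trajectories are floored at zero; ICERs are
undefined (error or dominance label) at zero DALYs averted; parameter
accounting identities (treatment total = drug + maintenance; waiting total
= sum of components) are enforced to the cent at validation and maintained
automatically by the override and perturbation helpers.

## Limitations

The model inherits the source estimates' limitations: life expectancies are
modelled extrapolations from observational cohorts, not trial results; the
linearity of life expectancy in baseline CD4 over 250–350 may overstate the
benefit at the top of the range; costs are a single setting's 2011 prices;
and no probabilistic sensitivity analysis is attempted (the published
analysis is one-way only). The hospitalization horizon and stratum split
are structural constants of the published design, configurable but not
varied here.
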
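# Base-case model inputs (2011 USD). Every key shown here is optional:
# omitted keys keep the package defaults, which equal these values.
anchors:
  - cd4_midpoint: 25
    life_expectancy: 7.9
  - cd4_midpoint: 125
    life_expectancy: 9.6
  - cd4_midpoint: 275
    life_expectancy: 19.3
decline:
  median_per_period: 45.75
  q25_per_period: 30.65
  q75_per_period: 62.35
  period_years: 0.5
  reconstitution_rate_year1: 114
disability:
  hiv_weight: 0.123
  aids_weight: 0.5
  aids_years_before_death: 1
costs:
  cart_drug_annual: 192.44
  cart_maintenance_annual: 113.40
  treatment_total_annual: 305.84
  waiting_components:
    clinic_personnel: 14.32
    lab: 35.04
    other_medication: 33.72
    radiology: 1.68
  waiting_total_annual: 84.76
  cost_per_inpatient_day: 31.48
discount:
  annual_rate: 0.03
  convention: semiannual_midperiod
cd4_threshold: 250
cd4_range: [250, 350]
measurement_interval: 0.5
hospitalization_horizon: 2
gdp_per_capita: 490
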
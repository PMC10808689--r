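meta:
  currency: USD
  rmb_per_usd: 7.2897
survival:
  os:
    intervention:
      family: log-logistic
      scale: 24.217
      shape: 1.546
    comparator:
      family: log-logistic
      scale: 17.255
      shape: 1.718
  pfs:
    intervention:
      family: log-logistic
      scale: 12.2045
      shape: 1.4758
    comparator:
      family: log-logistic
      scale: 8.1898
      shape: 1.7748
patient:
  bsa_m2: 1.62
  weight_kg: 59.0
drugs:
  pembrolizumab:
    price_per_vial: 2457.99
    vial_mg: 100.0
    dose:
      rule: flat
      amount: 200.0
    max_cycles: .inf
    arms: intervention
  paclitaxel:
    price_per_vial: 22.15
    vial_mg: 30.0
    dose:
      rule: per_m2
      amount: 175.0
    max_cycles: 6.0
    arms:
    - intervention
    - comparator
  cisplatin:
    price_per_vial: 2.62
    vial_mg: 30.0
    dose:
      rule: per_m2
      amount: 50.0
    max_cycles: 6.0
    arms:
    - intervention
    - comparator
  bevacizumab:
    price_per_vial: 158.85
    vial_mg: 100.0
    dose:
      rule: per_kg
      amount: 15.0
    max_cycles: .inf
    arms:
    - intervention
    - comparator
    uptake:
      intervention: 0.636
      comparator: 0.625
admin:
  hospitalization: 41.15
  preventive_medication: 1.65
  infusion: 1.63
labs:
  ecg: 3.7
  hematology: 3.43
  serum_chemistry: 24.69
  urinalysis: 4.12
  coagulation: 9.13
  thyroid: 20.58
imaging:
  ct: 336.09
  first_scan_week: 9.0
  early_interval_weeks: 9.0
  early_until_week: 54.0
  late_interval_weeks: 12.0
ae:
  costs:
    anemia: 138.57
    nausea: 20.13
    diarrhea: 3.51
    constipation: 4.04
    arthralgia: 17.69
    peripheral_neuropathy: 1.45
    vomiting: 20.13
    hypertension: 0.07
    urinary_tract_infection: 126.03
    neutropenia: 399.63
    peripheral_sensory_neuropathy: 1.45
    thrombocytopenia: 1094.7
  risks:
    intervention:
      anemia: 0.303
      nausea: 0.02
      diarrhea: 0.02
      constipation: 0.003
      arthralgia: 0.007
      peripheral_neuropathy: 0.026
      vomiting: 0.026
      hypertension: 0.094
      urinary_tract_infection: 0.088
      neutropenia: 0.124
      peripheral_sensory_neuropathy: 0.01
      thrombocytopenia: 0.075
    comparator:
      anemia: 0.269
      nausea: 0.016
      diarrhea: 0.026
      constipation: 0.01
      arthralgia: 0.013
      peripheral_neuropathy: 0.029
      vomiting: 0.019
      hypertension: 0.107
      urinary_tract_infection: 0.081
      neutropenia: 0.097
      peripheral_sensory_neuropathy: 0.019
      thrombocytopenia: 0.045
terminal:
  bsc_per_cycle: 274.36
  eol_once: 685.9
progression_consult_once: 0.0
utilities:
  pf: 0.76
  pd: 0.52
  dead: 0.0
  ae_disutility: -0.28
settings:
  cycle_days: 21.0
  n_cycles: 86.0
  discount_annual: 0.05
  wtp: 35268.94
  gdp_per_capita: 11756.31
  occupancy_eval: start
  pricing: original
  donation_multiplier: 0.414
  psa_range_divisor: 3.92
subgroups:
- label: Age <65 years
  hr: 0.64
  lo: 0.5
  hi: 0.82
- label: Age >=65 years
  hr: 0.88
  lo: 0.47
  hi: 1.64
- label: White
  hr: 0.68
  lo: 0.5
  hi: 0.91
- label: Non-White
  hr: 0.7
  lo: 0.47
  hi: 1.04
- label: ECOG 0
  hr: 0.68
  lo: 0.49
  hi: 0.96
- label: ECOG 1
  hr: 0.68
  lo: 0.5
  hi: 0.94
- label: PD-L1 CPS <1
  hr: 1.0
  lo: 0.53
  hi: 1.89
- label: PD-L1 CPS 1 to <10
  hr: 0.67
  lo: 0.46
  hi: 0.97
- label: PD-L1 CPS >=10
  hr: 0.61
  lo: 0.44
  hi: 0.84
- label: 'Concomitant bevacizumab: yes'
  hr: 0.63
  lo: 0.47
  hi: 0.87
- label: 'Concomitant bevacizumab: no'
  hr: 0.74
  lo: 0.53
  hi: 1.04
- label: 'Metastatic at diagnosis: yes'
  hr: 0.84
  lo: 0.56
  hi: 1.26
- label: 'Metastatic at diagnosis: no'
  hr: 0.61
  lo: 0.46
  hi: 0.8
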
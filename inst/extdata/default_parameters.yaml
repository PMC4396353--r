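clinical:
  prucalopride:
    r4:
      responders: 178.0
      total: 640.0
    r12:
      responders: 151.0
      total: 640.0
  laxative:
    r4:
      responders: 68.0
      total: 645.0
    r12:
      responders: 73.0
      total: 645.0
  female:
    prucalopride:
      r4:
        responders: 166.0
        total: 566.0
      r12:
        responders: 138.0
        total: 566.0
    laxative:
      r4:
        responders: 58.0
        total: 580.0
      r12:
        responders: 62.0
        total: 580.0
  pacqol:
    prucalopride:
      r4:
        responders: 271.0
        total: 598.0
      r12:
        responders: 273.0
        total: 621.0
    laxative:
      r4:
        responders: 129.0
        total: 605.0
      r12:
        responders: 137.0
        total: 618.0
  switch_response: 0.654
  failure_practice:
    referral_specialist: 0.282
    hospitalization: 0.049
    none: 0.669
  one_way_bounds:
    r4:
      low: 0.244
      high: 0.314
    r12:
      low: 0.204
      high: 0.25
utilities:
  prucalopride:
    start: 0.786
    weeks5_12: 0.813
    maintenance: 0.89
  laxative:
    start: 0.781
    weeks5_12: 0.805
    maintenance: 0.879
  switch:
    start: 0.784
    maintenance: 0.879
    dropout: 0.784
complications:
  items:
    hemorrhoids:
      prob:
        weeks1_4: 0.19
        weeks5_12: 0.22
        switch: 0.12
      pcp_consults: 2.2
      specialist_consults: 1.5
      hospitalization_fraction: 0.017
      los_days: 1.0
    anal_fissures:
      prob:
        weeks1_4: 0.07
        weeks5_12: 0.11
        switch: 0.06
      pcp_consults: 2.3
      specialist_consults: 1.0
      hospitalization_fraction: 0.017
      los_days: 3.0
    fecal_incontinence:
      prob:
        weeks1_4: 0.08
        weeks5_12: 0.07
        switch: 0.06
      pcp_consults: 1.8
      specialist_consults: 1.6
      hospitalization_fraction: 0.089
      los_days: 4.5
    perianal_thrombosis:
      prob:
        weeks1_4: 0.07
        weeks5_12: 0.09
        switch: 0.02
      pcp_consults: 2.0
      specialist_consults: 1.1
      hospitalization_fraction: 0.056
      los_days: 1.7
    rectal_prolapse:
      prob:
        weeks1_4: 0.034
        weeks5_12: 0.05
        switch: 0.008
      pcp_consults: 1.2
      specialist_consults: 1.7
      hospitalization_fraction: 0.367
      los_days: 5.2
    fecal_impaction:
      prob:
        weeks1_4: 0.141
        weeks5_12: 0.154
        switch: 0.038
      pcp_consults: 1.8
      specialist_consults: 1.2
      hospitalization_fraction: 0.162
      los_days: 3.0
  period_months:
    weeks1_4: 1.0
    weeks5_12: 2.0
    switch: 3.0
resources:
  phases:
    weeks1_4:
      specialist_consult: 0.6
      specialist_phone: 0.3
      pcp_consult: 0.9
      pcp_phone: 0.6
      nurse_consult: 0.2
      dietician_consult: 0.1
      colonoscopy: 0.6
      rectal_exam: 0.8
      anoscopy: 0.2
      blood_tests: 0.8
      radiograph: 0.2
      gi_transit: 0.2
      enema: 0.3
    weeks5_12:
      specialist_consult: 0.6
      specialist_phone: 0.6
      pcp_consult: 1.0
      pcp_phone: 1.1
      nurse_consult: 0.2
      dietician_consult: 0.2
      colonoscopy: 0.5
      rectal_exam: 0.6
      anoscopy: 0.5
      blood_tests: 0.9
      radiograph: 0.7
      gi_transit: 0.0
      enema: 0.6
    maintenance:
      specialist_consult: 0.4
      specialist_phone: 0.4
      pcp_consult: 0.7
      pcp_phone: 0.5
      nurse_consult: 0.2
      dietician_consult: 0.3
      colonoscopy: 0.4
      rectal_exam: 0.4
      anoscopy: 0.1
      blood_tests: 0.5
      radiograph: 0.5
      gi_transit: 0.0
      enema: 0.5
    switch_weeks1_4:
      specialist_consult: 0.8
      specialist_phone: 0.4
      pcp_consult: 0.7
      pcp_phone: 0.3
      nurse_consult: 0.2
      dietician_consult: 0.2
      colonoscopy: 0.4
      rectal_exam: 0.6
      anoscopy: 0.2
      blood_tests: 0.0
      radiograph: 0.3
      gi_transit: 0.2
      enema: 0.2
    switch_maintenance:
      specialist_consult: 0.3
      specialist_phone: 0.1
      pcp_consult: 0.6
      pcp_phone: 0.3
      nurse_consult: 0.1
      dietician_consult: 0.1
      colonoscopy: 0.2
      rectal_exam: 0.3
      anoscopy: 0.2
      blood_tests: 0.0
      radiograph: 0.1
      gi_transit: 0.1
      enema: 0.0
costs:
  prucalopride:
    mg2:
      first_pack_daily: 2.77
      after_daily: 2.49
    mg1:
      first_pack_daily: 1.95
      after_daily: 1.62
    costing_year: 2010.0
    annual_cap_days: 220.0
    first_year_maintenance_days: 130.0
  prescription_fee: 6.35
  laxatives:
    items:
      movicolon:
        daily_cost: 0.48
        start_share: 0.42
        switch_share: 0.27
      bisacodyl:
        daily_cost: 0.17
        start_share: 0.08
        switch_share: 0.17
      forlax:
        daily_cost: 0.61
        start_share: 0.15
        switch_share: 0.07
      metamucil:
        daily_cost: 0.6
        start_share: 0.18
        switch_share: 0.23
      lactulose:
        daily_cost: 0.23
        start_share: 0.17
        switch_share: 0.0
      magnesium_oxide:
        daily_cost: 0.21
        start_share: 0.0
        switch_share: 0.26
    costing_year: 2010.0
  units:
    pcp_visit: 28.0
    specialist_visit_manual: 72.0
    pcp_phone: 14.0
    specialist_phone: 14.0
    nurse_visit: 10.0
    nurse_phone: 0.0
    dietician_visit: 27.0
    dbc_specialist: 195.89
    dbc_hospitalization: 3102.0
    costing_year:
      pcp_visit: 2009.0
      specialist_visit_manual: 2009.0
      pcp_phone: 2009.0
      specialist_phone: 2009.0
      nurse_visit: 2009.0
      nurse_phone: 2009.0
      dietician_visit: 2009.0
      dbc_specialist: 2010.0
      dbc_hospitalization: 2010.0
  procedures:
    colonoscopy: 0.0
    rectal_exam: 0.0
    anoscopy: 0.0
    blood_tests: 0.0
    radiograph: 0.0
    gi_transit: 0.0
    enema: 0.0
  transport:
    km_pcp: 1.1
    km_specialist: 7.0
    km_dietician: 1.7
    cost_per_km: 0.2
    parking: 3.0
    costing_year: 2009.0
  inflation:
    '2009': 0.012
    '2010': 0.013
    '2011': 0.0
    '2012': 0.0
    '2013': 0.0
indirect:
  share_absent: 0.12
  days_per_month: 2.4
  cost_per_hour: 26.99
  annual_hours: 1540.0
  working_age_share: 0.87
  hours_per_day: 8.0
analysis:
  horizon_months: 12.0
  cycle_days: 30.4
  first_pack_days: 28.0
  discount_costs: 0.0
  discount_effects: 0.0
  stopping_rule: yes
  include_complications: yes
  include_transport: yes
  include_indirect: no
  include_parking: no
  dose: 2mg
  population: all
  endpoint: bowel_function
  hospital_costing: dbc_fixed
  inflation_target_year: 2011.0
  death_prob_monthly: 0.0
  failure_workup: all
  complication_states:
    START_W1_4: none
    START_W5_8: none
    START_W9_12: none
    MAINTENANCE: none
    SWITCH_W1_4: switch
    SWITCH_W5_8: none
    SWITCH_W9_12: none
    SWITCH_MAINTENANCE: none
    DROPOUT: switch
  resource_states:
    START_W1_4: weeks1_4
    START_W5_8: weeks5_12
    START_W9_12: weeks5_12
    MAINTENANCE: maintenance
    SWITCH_W1_4: switch_weeks1_4
    SWITCH_W5_8: switch_weeks1_4
    SWITCH_W9_12: switch_weeks1_4
    SWITCH_MAINTENANCE: switch_maintenance
    DROPOUT: switch_weeks1_4
  one_way_r4_coupling: proportional
  week12_failure_split: late
  probability_conversion: rate
  psa:
    se_probability_frac: 0.2
    se_utility: 0.05
    se_quantity_frac: 0.25
    n_draws: 5000.0
    threshold_max: 80000.0
    threshold_step: 1000.0
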
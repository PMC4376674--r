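# Model parameters: probabilities of incident VTE and adverse events within
# 30 days of admission, unit costs (2013 US$), and population constants.
# Section order mirrors the row groups of the source tables so the file can
# be diffed against them line by line.

strategies:
  LMWH:                      # enoxaparin 40 mg qd x 7 days
    p_dvt: 0.055             # efficacy of prophylaxis: P(DVT)
    p_bleed: 0.031           # safety of prophylaxis: P(bleed)
    p_hit: 0.001             # safety of prophylaxis: P(HIT)
    prophylaxis_cost: 380    # 7 days of prophylaxis, incl. administration
  UFH:                       # unfractionated heparin 5000 IU bid x 7 days
    p_dvt: 0.066
    p_bleed: 0.058
    p_hit: 0.010
    prophylaxis_cost: 236
  NONE:
    p_dvt: 0.142
    p_bleed: 0.020
    p_hit: 0.000             # structural zero: no drug, no HIT
    prophylaxis_cost: 0

shared:
  # consequences of adverse events
  p_major_given_bleed: 0.185
  p_death_given_major_bleed: 0.148
  p_symptomatic_given_hit: 0.543
  p_death_given_symptomatic_hit: 0.098
  # efficacy and safety of DVT treatment
  p_bleed_given_dvt_tx: 0.083
  p_hit_given_dvt_tx: 0.012
  p_pe_given_dvt_tx: 0.018
  # efficacy and safety of PE treatment
  p_death_given_pe_tx_pos: 0.015
  p_death_given_pe_tx_neg: 0.003
  # natural history
  p_sudden_death_given_pe: 0.100
  p_pe_given_untreated_dvt: 0.511
  p_death_given_untreated_pe: 0.260
  p_death_underlying: 0.100
  # diagnosis of DVT
  dvt_clin_sens: 0.657
  dvt_clin_spec: 0.869
  dvt_us_sens: 0.960
  dvt_us_spec: 0.962
  # diagnosis of PE
  pe_clin_sens: 0.291
  pe_clin_spec: 0.910
  pe_ct_sens: 0.760
  pe_ct_spec: 0.894
  pe_vq_sens: 0.410
  pe_vq_spec: 0.970
  pe_scan_avg_sens: 0.585    # average of CT and V/Q scans; checked at load
  pe_scan_avg_spec: 0.932    # average of CT and V/Q scans; checked at load

costs:                       # 2013 US$
  major_bleed: 10717
  minor_bleed: 5466
  asymptomatic_hit: 1064
  symptomatic_hit: 14032
  treated_dvt: 10758
  treated_pe: 19032
  dvt_diagnosis: 449
  pe_diagnosis: 582

population:
  cohort_size: 10000
  endorse_counts:            # ENDORSE US eligibility funnel
    enrolled: 9257
    medical_ward: 5196
    at_vte_risk: 2720
    receiving_prophylaxis: 1292
    contraindicated: 331     # among patients at VTE risk
  nis_eligible_total: 14300000
  at_risk_fraction: 0.511    # US medical inpatients at ACCP-defined VTE risk
  at_risk_iqr: [0.448, 0.622]
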
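photophys:
  HL:
    ps_chl: 0.05
    alpha_chl: 0.001
    beta_chl: 2.0e-05
  LL:
    ps_chl: 0.03
    alpha_chl: 0.002
    beta_chl: 0.00015
allocation:
  a0: 0.0004
  a1: 0.0015
  a2: 0.0012
  mu_hat: 0.6
  k_i: 25.0
  k_r: 0.05
nutrients:
  vmax_n: 3.2e-16
  k_n: 1.0e-05
  q_n: 4.0e-16
  vmax_p: 2.5e-17
  k_p: 5.0e-06
  q_p: 2.5e-17
  k_fe_sa: 3.0e-18
  surface_area: 1.13
  q_fe: 2.0e-19
  fe_detection_limit: 0.03
integration:
  carbon_quota: 5.0e-14
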
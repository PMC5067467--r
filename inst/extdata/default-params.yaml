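model:
  goal:
    tau_str: 0.1
    sigma_str: 1.0
    theta_str: 0.1
    iota: 1.0
    delta: 1.0
    tau_stn: 0.1
    sigma_stn: 2.0
    theta_stn: 0.1
    tau_gpi: 0.1
    sigma_gpi: 0.6
    theta_gpi: -1.0
    tau_th: 0.1
    sigma_th: 2.0
    theta_th: -0.05
    tau_n: 0.5
    nu: 3.8
    tau_ctx: 0.2
    sigma_ctx: 2.0
    theta_ctx: 0.1
    w_cs: 0.9
    w_ce: 0.5
    w_se: 0.6
    w_sg: 2.0
    w_gt: 0.95
    w_tc: 1.0
    w_ct: 0.6
    w_tt: 1.2
  assoc:
    tau_str: 0.1
    sigma_str: 1.0
    theta_str: 0.2
    iota: 1.0
    delta: 3.0
    tau_stn: 0.1
    sigma_stn: 2.0
    theta_stn: 0.1
    tau_gpi: 0.1
    sigma_gpi: 0.6
    theta_gpi: -1.0
    tau_th: 0.1
    sigma_th: 2.0
    theta_th: -0.05
    tau_n: 0.5
    nu: 2.7
    tau_ctx: 0.1
    sigma_ctx: 2.0
    theta_ctx: 0.1
    w_cs: 0.6
    w_ce: 0.5
    w_se: 0.6
    w_sg: 1.2
    w_gt: 0.8
    w_tc: 1.0
    w_ct: 1.0
    w_tt: 0.4
  motor:
    tau_str: 0.1
    sigma_str: 1.0
    theta_str: 0.2
    iota: 1.0
    delta: 3.0
    tau_stn: 0.1
    sigma_stn: 2.0
    theta_stn: 0.1
    tau_gpi: 0.1
    sigma_gpi: 0.6
    theta_gpi: -1.0
    tau_th: 0.1
    sigma_th: 2.0
    theta_th: -0.05
    tau_n: 0.5
    nu: 2.7
    tau_ctx: 0.1
    sigma_ctx: 2.0
    theta_ctx: 0.1
    w_cs: 0.6
    w_ce: 0.5
    w_se: 0.6
    w_sg: 1.2
    w_gt: 0.8
    w_tc: 1.0
    w_ct: 0.6
    w_tt: 0.4
  bla:
    tau_o: 0.1
    tau_i: 3.0
    w_lever: 1.0
    w_food: 1.5
    w_sat: 10.0
    trace_alpha: 1.0
    trace_tau: 4.0
    eta: 4.0
    theta_da: 0.3
    max_w: 1.5
  lh:
    tau_o: 0.05
    tau_i: 1.0
    w_food: 1.0
  ppn:
    tau_o: 0.05
    tau_i: 1.0
    w_food: 1.0
  vta:
    tau: 0.1
    sigma: 2.0
    theta: 0.1
    w_lh: 1.5
  snpc:
    tau_e: 0.1
    sigma_e: 2.0
    theta_e: -0.5
    tau_i: 0.8
    sigma_i: 2.0
    theta_i: -0.5
    w_ppn: 2.0
    w_inh: 0.55
    w_spiral: 0.8
  nac:
    eta: 0.1
    theta_da: 0.3
    theta_str: 0.75
    theta_inp: 0.6
    w_cap: 3.0
  dms:
    eta: 0.05
    theta_da: 0.8
    theta_str: 0.4
    theta_inp: 0.5
    w_cap: 0.2
  dls:
    eta: 0.05
    theta_da: 0.8
    theta_str: 0.4
    theta_inp: 0.5
    w_cap: 0.2
  cc:
    w_pl_actx: 0.05
    w_actx_mc: 0.5
    w_mc_actx: 0.4
    w_actx_pl: 0.4
experiment:
  cycle_s: 0.05
  substeps: 1.0
  hold_s: 0.5
  reward_s: 1.0
  timeout_s: 15.0
  silence_s: 2.0
  train_session_min: 20.0
  test_session_min: 2.0
  n_bins: 10.0
  n_reps: 40.0
  base_seed: 1.0
  theta_mc: 0.5
  variant: two-manipulanda
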
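compartments:
  cleft: 0.0015
  PSD: 0.002
  cytosol: 0.02
  ER: 0.002
diffusion:
  D: 330.0
  h: 0.0145834
  sigma0: 0.2
  ambient: 0.0
transporters:
  density: 500.0
  exclusion_radius: 200.0
  k_bind: 0.7601223
mglur:
  R_tot: 8.0
  G_tot: 40.0
  PLC_tot: 0.5
  PIP2_tot: 40.0
  K_L: 0.105
  J: 0.02
  beta: 20.0
  M: 0.0001
  gamma: 1.0
  alpha_c: 3450.0
  delta: 1.0
  kon_L: 4.0
  kact: 50.0
  kg_on: 0.04
  k_ex_act: 50.0
  k_ex_basal: 0.05
  k_hyd: 5.0
  k_re: 0.5
  kp_on: 20.0
  kp_off: 0.2
  k_gap: 2.0
  K_plc_ca: 0.3
  n_plc_ca: 1.0
  k_pip2: 0.25
  v_ip3_basal: .na
  k_rep: 1.0
  V3k: 120.0
  K3k_ca: 0.4
  n3k: 2.0
  Km3k: 10.0
  V5p: 14.0
  Km5p: 10.0
ip3r:
  a1: 400.0
  d1: 0.2
  a2: 0.2
  d2: 1.049
  a3: 400.0
  d3: 1.451903114186851
  a4: 0.2
  d4: 0.1445
  a5: 40.0
  d5: 0.08234
  n_open: 3.0
  v_ip3r: 0.7
  v_leak_er: .na
  V_serca: 22.0
  K_serca: 0.2
  n_serca: 2.0
calcium:
  ca_basal: 0.06
  ca_cleft: 2000.0
  ca_er: 500.0
  V_pmca: 7.0
  K_pmca: 0.25
  n_pmca: 2.0
  V_ncx: 14.0
  K_ncx: 1.0
  n_ncx: 1.0
  v_leak_pm: .na
  buffers:
    CaM:
      total: 25.0
      kon: 50.0
      Kd: 2.0
    CaN:
      total: 1.0
      kon: 10.0
      Kd: 0.1
    PKC:
      total: 1.0
      kon: 10.0
      Kd: 0.5
  psd_buffer_scale: 1.0
  k_ca_psd_cyt: 0.06
  k_ip3_psd_cyt: 0.004
iglur:
  ampa_kon: 10.0
  ampa_koff: 2000.0
  ampa_beta: 4000.0
  ampa_alpha: 2000.0
  ampa_kd: 1000.0
  ampa_kr: 15.0
  n_ampa: 80.0
  ampa_ca_coef: 0.0
  nmda_kon: 5.0
  nmda_koff: 4.7
  nmda_beta: 50.0
  nmda_alpha: 100.0
  nmda_kd: 80.0
  nmda_kr: 1.8
  n_nmda: 20.0
  k_nmda_ca: 1150.0
  receptor_radius: 20.0
simulation:
  mglur_location: 100.0
  transporters: 'on'
  receptors: all
  dt: 0.001
  post_stimulus: 20.0
  rtol: 1.0e-08
  atol: 1.0e-12
  ip3_basal: 0.1
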
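profile: reduced
engine:
  dt: 0.1
  refractory: 5.0
  exp_cap: 10.0
  settle: 500.0
mg_block:
  eta: 0.28
  mg_out: 1.0
  gamma: 0.04
populations:
  GC: 360
  BC: 50
  MC: 18
  HC: 5
input:
  n_trains: 280
  rate_hz: 8.0
  duration_ms: 2000.0
  betas:
  - 0.0
  - 0.1
  - 0.2
  - 0.3
  - 0.4
  - 0.5
  - 0.6
  - 0.7
  - 0.8
  - 0.9
  - 1.0
  distinctness_r: 0.05
analysis_window:
- 500.0
- 2000.0
wiring: fixed_in
neuron_defaults:
  GC:
    subtype: GC
    C_m: 1.0
    R_m: 23.0
    A: 0.0001
    E_l: -75.0
    V_th: -52.0
    Delta_T: 2.0
    V_reset: -62.0
    tau_w: 120.0
    alpha: 0.0005
    b: 0.026
  BC:
    subtype: BC
    C_m: 1.0
    R_m: 10.0
    A: 8.000000000000001e-05
    E_l: -65.0
    V_th: -48.0
    Delta_T: 1.0
    V_reset: -58.0
    tau_w: 15.0
    alpha: 0.0001
    b: 0.0
  MC:
    subtype: MC
    C_m: 1.0
    R_m: 20.0
    A: 0.0001
    E_l: -68.0
    V_th: -50.0
    Delta_T: 2.0
    V_reset: -60.0
    tau_w: 150.0
    alpha: 0.0008
    b: 0.015
  HC:
    subtype: HC
    C_m: 1.0
    R_m: 35.0
    A: 5.5e-05
    E_l: -70.0
    V_th: -52.0
    Delta_T: 2.0
    V_reset: -60.0
    tau_w: 100.0
    alpha: 0.0003
    b: 0.01
neuron_ranges:
  GC:
    R_m:
    - 17.25
    - 28.75
    A:
    - 7.500000000000001e-05
    - 1.25e-04
    Delta_T:
    - 1.5
    - 2.5
    tau_w:
    - 90.0
    - 150.0
    alpha:
    - 0.000375
    - 0.000625
    b:
    - 0.0195
    - 0.0325
    E_l:
    - -78.0
    - -72.0
    V_th:
    - -55.0
    - -49.0
    V_reset:
    - -65.0
    - -59.0
  BC:
    R_m:
    - 7.5
    - 12.5
    A:
    - 6.000000000000001e-05
    - 1.0e-04
    Delta_T:
    - 0.75
    - 1.25
    tau_w:
    - 11.25
    - 18.75
    alpha:
    - 7.500000000000001e-05
    - 1.25e-04
    b:
    - 0.0
    - 0.01
    E_l:
    - -68.0
    - -62.0
    V_th:
    - -51.0
    - -45.0
    V_reset:
    - -61.0
    - -55.0
  MC:
    R_m:
    - 15.0
    - 25.0
    A:
    - 7.500000000000001e-05
    - 1.25e-04
    Delta_T:
    - 1.5
    - 2.5
    tau_w:
    - 112.5
    - 187.5
    alpha:
    - 0.0006
    - 0.001
    b:
    - 0.01125
    - 0.01875
    E_l:
    - -71.0
    - -65.0
    V_th:
    - -53.0
    - -47.0
    V_reset:
    - -63.0
    - -57.0
  HC:
    R_m:
    - 26.25
    - 43.75
    A:
    - 4.125e-05
    - 6.875e-05
    Delta_T:
    - 1.5
    - 2.5
    tau_w:
    - 75.0
    - 125.0
    alpha:
    - 0.000225
    - 0.000375
    b:
    - 0.0075
    - 0.0125
    E_l:
    - -73.0
    - -67.0
    V_th:
    - -55.0
    - -49.0
    V_reset:
    - -63.0
    - -57.0
ephys_bounds:
  GC:
    tau_m:
    - 15.0
    - 35.0
    sag:
    - 0.85
    - 1.0
    R_in:
    - 170.0
    - 260.0
    SFA:
    - 0.2
    - 0.8
    f50:
    - 0.0
    - 2.0
    f150:
    - 12.0
    - 20.0
  BC:
    tau_m:
    - 5.0
    - 18.0
    sag:
    - 0.9
    - 1.0
    R_in:
    - 60.0
    - 220.0
    SFA:
    - 0.5
    - 1.05
    f50:
    - 0.0
    - 10.0
    f150:
    - 10.0
    - 80.0
  MC:
    tau_m:
    - 12.0
    - 35.0
    sag:
    - 0.8
    - 1.0
    R_in:
    - 100.0
    - 350.0
    SFA:
    - 0.1
    - 0.9
    f50:
    - 0.0
    - 15.0
    f150:
    - 5.0
    - 60.0
  HC:
    tau_m:
    - 20.0
    - 60.0
    sag:
    - 0.85
    - 1.0
    R_in:
    - 350.0
    - 1000.0
    SFA:
    - 0.1
    - 1.0
    f50:
    - 5.0
    - 60.0
    f150:
    - 10.0
    - 120.0
synapses:
  projection:
  - PP_GC
  - PP_HC
  - GC_BC
  - GC_MC
  - MC_GC
  - MC_BC
  - BC_GC
  - HC_GC
  pre:
  - PP
  - PP
  - GC
  - GC
  - MC
  - MC
  - BC
  - HC
  post:
  - GC
  - HC
  - BC
  - MC
  - GC
  - BC
  - GC
  - GC
  receptor:
  - AMPA_NMDA
  - AMPA_NMDA
  - AMPA_NMDA
  - AMPA_NMDA
  - AMPA_NMDA
  - AMPA_NMDA
  - GABAA
  - GABAA
  E_syn:
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - -90.0
  - -90.0
  tau_rise:
  - 0.5
  - 0.5
  - 0.3
  - 0.5
  - 0.5
  - 0.5
  - 0.4
  - 0.9
  tau_decay:
  - 3.5
  - 3.5
  - 2.5
  - 3.0
  - 3.0
  - 3.0
  - 6.0
  - 11.0
  tau_rise_nmda:
  - 5.0
  - 5.0
  - 5.0
  - 5.0
  - 5.0
  - 5.0
  - 5.0
  - 5.0
  tau_decay_nmda:
  - 50.0
  - 50.0
  - 50.0
  - 50.0
  - 50.0
  - 50.0
  - 50.0
  - 50.0
  nmda_ratio:
  - 0.3
  - 0.3
  - 0.3
  - 0.3
  - 0.3
  - 0.3
  - 0.0
  - 0.0
  delay:
  - 1.5
  - 1.5
  - 0.8
  - 1.0
  - 1.0
  - 1.0
  - 0.8
  - 1.0
  prob:
  - 0.035714285714286
  - 0.25
  - 0.3
  - 0.3
  - 0.388888888888889
  - 0.388888888888889
  - 0.6
  - 0.8
  gbar:
  - 3.0
  - 0.35
  - 6.0
  - 3.0
  - 0.15
  - 0.3
  - 10.0
  - 1.8
weight_ranges:
  PP_GC:
  - 1.5
  - 4.5
  PP_HC:
  - 0.175
  - 0.525
  GC_BC:
  - 3.0
  - 9.0
  GC_MC:
  - 1.5
  - 4.5
  MC_GC:
  - 0.075
  - 0.225
  MC_BC:
  - 0.15
  - 0.45
  BC_GC:
  - 5.0
  - 15.0
  HC_GC:
  - 0.9
  - 2.7
ps_bounds:
  A_PS_min: 0.15
  A_PC_max: 0.02
  T_PCPS_max: 0.25
  PS_max_min: 0.2
perturbations:
  levels:
  - 1.0
  - 3.0
  - 5.0
  jitter_scale: 0.02
  noise_scale_pa: 10.0
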
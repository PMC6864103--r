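name: control_synthetic
provenance: 'Synthetic control parameter set: the IP3R constants d1, d5 and a2 are
  the canonical De Young-Keizer/Li-Rinzel values and the physical constants are standard;
  d2 and d3 were adjusted during calibration (IP3R-isoform variability makes them
  the least certain gating constants).  All flux amplitudes, buffer levels, volumes,
  leak rates and connectivity coefficients were calibrated by simulation against the
  published behaviour of the four-compartment microdomain model (two oscillatory regions
  with distinct driving compartments, clamping and knockout dichotomies, ER-Mt distance
  threshold). Not transcribed from any source table.'
parameters:
  vol_cyt:
    value: 700.0
  vol_er:
    value: 140.0
  vol_mt:
    value: 70.0
  sa_mito:
    value: 3.1415927
  n_mito:
    value: 200.0
  d_er_mt:
    value: 0.02
  bp_cyt:
    value: 800.0
  bp_er:
    value: 5776.2
  bp_mt:
    value: 3597.0
  bp_ud:
    value: 800.0
  k_buf_cyt:
    value: 21.6
  k_buf_er:
    value: 131.0
  k_buf_mt:
    value: 2.0
  k_buf_ud:
    value: 21.6
  v_ip3r:
    value: 0.5276
  d1:
    value: 0.13
  d2:
    value: 0.7563
  d3:
    value: 0.4163
  d5:
    value: 0.08234
  a2:
    value: 0.2
  v_serca:
    value: 22.0
  k_serca:
    value: 0.084
  v_mcu0:
    value: 1.573
  k_mcu:
    value: 1.89
  b_mcu:
    value: 0.5
  psi0:
    value: 91.0
  psi:
    value: 170.0
  faraday:
    value: 96485.0
  gas_const:
    value: 8.314
  temperature:
    value: 310.0
  v_mncx:
    value: 2.558
  k_na:
    value: 9.4
  k_mncx:
    value: 0.08377
  na_cyt:
    value: 10.0
  na_ud:
    value: 10.0
  k_leak_er_cyt:
    value: 0.0105
  k_leak_er_ud:
    value: 0.000208
  k_leak_ud_cyt:
    value: 0.3059
  c_ip3r:
    value: 0.3507
  c_serca:
    value: 0.1998
  c_mcu:
    value: 0.98
  c_mncx:
    value: 0.7154
  ip3:
    value: 0.0
bounds:
  vol_cyt:
    lower: 420.0
    upper: 980.0
    variable: yes
  vol_er:
    lower: 84.0
    upper: 196.0
    variable: yes
  vol_mt:
    lower: 42.0
    upper: 98.0
    variable: yes
  sa_mito:
    variable: no
  n_mito:
    variable: no
  d_er_mt:
    lower: 0.012
    upper: 0.028
    variable: yes
  bp_cyt:
    lower: 480.0
    upper: 1120.0
    variable: yes
  bp_er:
    lower: 3465.72
    upper: 8086.68
    variable: yes
  bp_mt:
    lower: 2158.2
    upper: 5035.8
    variable: yes
  bp_ud:
    lower: 480.0
    upper: 1120.0
    variable: yes
  k_buf_cyt:
    lower: 12.96
    upper: 30.24
    variable: yes
  k_buf_er:
    lower: 78.6
    upper: 183.4
    variable: yes
  k_buf_mt:
    lower: 1.2
    upper: 2.8
    variable: yes
  k_buf_ud:
    lower: 12.96
    upper: 30.24
    variable: yes
  v_ip3r:
    lower: 0.31656
    upper: 0.73864
    variable: yes
  d1:
    lower: 0.078
    upper: 0.182
    variable: yes
  d2:
    lower: 0.45378
    upper: 1.05882
    variable: yes
  d3:
    lower: 0.24978
    upper: 0.58282
    variable: yes
  d5:
    lower: 0.049404
    upper: 0.115276
    variable: yes
  a2:
    lower: 0.12
    upper: 0.28
    variable: yes
  v_serca:
    lower: 13.2
    upper: 30.8
    variable: yes
  k_serca:
    lower: 0.0504
    upper: 0.1176
    variable: yes
  v_mcu0:
    lower: 0.9438
    upper: 2.2022
    variable: yes
  k_mcu:
    lower: 1.134
    upper: 2.646
    variable: yes
  b_mcu:
    lower: 0.3
    upper: 0.7
    variable: yes
  psi0:
    lower: 54.6
    upper: 127.4
    variable: yes
  psi:
    variable: no
  faraday:
    variable: no
  gas_const:
    variable: no
  temperature:
    variable: no
  v_mncx:
    lower: 1.5348
    upper: 3.5812
    variable: yes
  k_na:
    lower: 5.64
    upper: 13.16
    variable: yes
  k_mncx:
    lower: 0.050262
    upper: 0.117278
    variable: yes
  na_cyt:
    lower: 6.0
    upper: 14.0
    variable: yes
  na_ud:
    lower: 6.0
    upper: 14.0
    variable: yes
  k_leak_er_cyt:
    lower: 0.0063
    upper: 0.0147
    variable: yes
  k_leak_er_ud:
    lower: 0.0001248
    upper: 0.0002912
    variable: yes
  k_leak_ud_cyt:
    lower: 0.18354
    upper: 0.42826
    variable: yes
  c_ip3r:
    lower: 0.21042
    upper: 0.49098
    variable: yes
  c_serca:
    lower: 0.11988
    upper: 0.27972
    variable: yes
  c_mcu:
    lower: 0.588
    upper: 1.0
    variable: yes
  c_mncx:
    lower: 0.42924
    upper: 1.0
    variable: yes
  ip3:
    variable: no
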
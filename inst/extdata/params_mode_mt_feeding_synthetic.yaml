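name: mode_mt_feeding_synthetic
provenance: Synthetic alternative parameter set illustrating the Mt feeding oscillatory
  mode (which store refills the cytosol during the interspike interval).  Selected
  from a Latin hypercube ensemble (+/-40% around the synthetic control set, seed 42)
  by running an IP3 step to 0.2 uM and classifying the feeder mode; not transcribed
  from any source table.  Stimulate at 0.2 uM IP3 to reproduce the mode.
parameters:
  vol_cyt:
    value: 916.0656833
  vol_er:
    value: 119.7644256
  vol_mt:
    value: 72.500542
  sa_mito:
    value: 3.1415927
  n_mito:
    value: 200.0
  d_er_mt:
    value: 0.0185765
  bp_cyt:
    value: 961.8155575
  bp_er:
    value: 5242.1613882
  bp_mt:
    value: 4922.3342002
  bp_ud:
    value: 516.7939262
  k_buf_cyt:
    value: 29.7023597
  k_buf_er:
    value: 107.9572708
  k_buf_mt:
    value: 2.3127701
  k_buf_ud:
    value: 19.5098728
  v_ip3r:
    value: 0.3614318
  d1:
    value: 0.1096124
  d2:
    value: 0.5970993
  d3:
    value: 0.3676785
  d5:
    value: 0.0648611
  a2:
    value: 0.208693
  v_serca:
    value: 17.2509499
  k_serca:
    value: 0.0808677
  v_mcu0:
    value: 1.6740697
  k_mcu:
    value: 1.6776972
  b_mcu:
    value: 0.4405969
  psi0:
    value: 71.9195577
  psi:
    value: 170.0
  faraday:
    value: 96485.0
  gas_const:
    value: 8.314
  temperature:
    value: 310.0
  v_mncx:
    value: 3.4883669
  k_na:
    value: 13.1164524
  k_mncx:
    value: 0.0887203
  na_cyt:
    value: 8.9607292
  na_ud:
    value: 12.9910749
  k_leak_er_cyt:
    value: 0.00944
  k_leak_er_ud:
    value: 0.0002543
  k_leak_ud_cyt:
    value: 0.3900329
  c_ip3r:
    value: 0.2156117
  c_serca:
    value: 0.2777031
  c_mcu:
    value: 0.9574596
  c_mncx:
    value: 0.4352108
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
    lower: .na.real
    upper: .na.real
    variable: no
  n_mito:
    lower: .na.real
    upper: .na.real
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
    lower: .na.real
    upper: .na.real
    variable: no
  faraday:
    lower: .na.real
    upper: .na.real
    variable: no
  gas_const:
    lower: .na.real
    upper: .na.real
    variable: no
  temperature:
    lower: .na.real
    upper: .na.real
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
    lower: .na.real
    upper: .na.real
    variable: no
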
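patient:
  theta_range:
  - -9.5
  - -0.25
  tau_nominal_s: 35.0
  tau_range_s:
  - 10.0
  - 60.0
  h_nominal_s: 40.0
  h_range_s:
  - 20.0
  - 60.0
  M0_mmHg: 100.0
regions:
  auto: no
  boundaries:
  - -9.5
  - -5.8
  - -3.03
  - -1.42
  - -0.6
  - -0.25
synthesis:
  bisection_tol: 0.0001
  slack_split: 0.5
hysteresis:
  half_width: 0.2
certification:
  grid_size: 201.0
  lambda_margin: auto
  beta_fraction: 0.5
  extend_by_hysteresis: yes
scenario:
  kind: fig7_like
  rate_per_s: 0.0085
  duration_s: 2000.0
  setpoint_mmHg: 100.0
  start_mmHg: 150.0
  dt_s: 0.1
  infusion_max_ml_hr: 180.0
seed: 1
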
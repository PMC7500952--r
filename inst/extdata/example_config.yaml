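# Example run configuration; unset keys fall back to package defaults.
model:
  k1: 2000
  k2: 2000
  k3: 10000
  k4: 20
  k5: 50
  tau: 8
program:
  type: pretreatment
  pre: 24
  break_h: 8
  second: 10
gating:
  mode: cell_cycle
  T_cycle: 21.82
  w: 7.3
noise:
  sigma_irf9: 250
  sigma_usp18: 1000
  convention: plain_euler
integrator:
  dt: 0.001
  t_end: 42
  thin: 100
cohort:
  n_cells: 400
  pre_durations: [2, 10, 24]
  break_h: 8
  horizon: 34
seed: 1
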
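# Default run configuration: summer water column (h_d = 140 m, h_u = 20 m).
# Units: depths m, weights ug C, metabolic costs ug C/ind/h, mortalities and
# grazing per day, speeds m/h, times in days (t0 is a day fraction).
environment:
  P0: 30.0        # maximal phytoplankton density, ug C/l
  sigma: 0.125    # food/light profile steepness, 1/m
  h_p: 40.0       # half-maximum chlorophyll depth, m
  m_A: 0.05       # maximal adult basal metabolic cost, ug C/ind/h
  M_A0: 0.13      # maximal adult active metabolic cost, ug C/ind/h
  sigma_m: 0.065  # metabolic profile steepness, 1/m
  delta_hm: 12.0  # h_m sits this far above h_d, m
  h_d: 140.0      # lower unfavorable boundary (hypoxia), m
  h_u: 20.0       # upper unfavorable boundary (warm layer), m
  delta_d: 2.0    # deep-zone extra mortality amplitude, 1/day
  delta_u: 0.5    # surface-zone extra mortality amplitude, 1/day
  sigma_d: 0.2
  sigma_u: 0.2
  h_max: 200.0
  const_cost: no
  avg_predation: no
stages:
  gamma_Y: 0.8
  gamma_J: 0.8
  gamma_A: 0.8
  gamma_Y0: 0.1
  gamma_J0: 0.0
  gamma_A0: 0.0
  W_A: 110.0
  W_J: 25.0
  W_Y: 1.2
  W_0: 0.25
  alpha_A: 1.1
  alpha: 0.05
  eps_Y: 0.7
  eps_J: 0.7
  eps_A: 0.7
  T0: 40.0
  max_age: 365.0
trajectory:
  c_down: 45.0
  c_up: 45.0
fitness:
  R: 1.0
optimizer:
  seed: 1
  n_lhs: 16
  n_refine: 5
  cycles: 6
scan:
  parameter: P0
  grid: [25, 30, 35, 40, 45, 50, 55, 60]
simulator:
  dtau: 0.05
  horizon: 1000
  coupled: no
  record_every: 20
output:
  dir: dvm-output
seed: 1
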
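# Splitting regime: expansion inhibition.
# Constant margin expansion suppressed under the strongly saturated
# (plateau-forming) activator peaks; troughs bulge outward and stretched
# plateaus pinch into two, doubling the count by repeated splitting.
rd:
  a: 0.35
  b: -0.4
  c: 0.15
  d: 0.3
  e: -0.25
  f: 0.05
  S_u: 0.12
  S_v: 0.5
  mu_u: 0.1
  mu_v: 0.1
  D_u: 0.3
  D_v: 6.0
  dt_rd: 0.04
  coupling_mode: topological
growth:
  mode: inhibition
  g0: 0.02
  k_h: 0.015
  reactant_select: u
  L_div: 1.0
  dt_growth: 1.0
sim:
  n_cells_init: 6
  radius_init: 1.0
  init_amplitude: 0.1
  rd_substeps: 25
  n_growth_steps: 1700
  snapshot_every: 5
  seed: 1
  max_cells: 1000
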
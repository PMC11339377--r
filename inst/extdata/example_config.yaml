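# Desk-scale seven-scenario comparison; see ?pipeline_config for every key.
landscape:
  nrows: 64
  ncols: 64
  cell_size: 500
  forest_fraction: 0.55
  pa_fraction: 0.08
  seed: 1
unit_size_cells: 4
area_fraction: 0.17
bandwidths: 12500
annealing:
  iterations: 2000
  runs: 20
popgen:
  n_loci: 15
  generations: 50
  replicates: 5
seed: 1
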
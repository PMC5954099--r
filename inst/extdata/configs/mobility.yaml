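experiment: mobility
seed: 1
output_dir: glyx-results/mobility
mobility:
  scenario: outer
  molecules_grid: [0.0, 1.5e+5, 3.0e+5, 4.5e+5, 6.0e+5, 7.5e+5, 9.5e+5, 1.2e+6]
  noise_sd: 0.02
  free_params: [total_surface_charge]
electrokinetics:
  n_nodes: 800
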
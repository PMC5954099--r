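experiment: camouflage
seed: 1
output_dir: glyx-results/camouflage
cytometry:
  antigens: [RhD, CD47]
  control_mfi: 1000
  protection_noncrowded: 30
  protection_crowded: 60
  cv: 0.1
  n_events: 10000
  n_replicates: 5
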
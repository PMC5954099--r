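experiment: distribution
seed: 1
output_dir: glyx-results/distribution
stack:
  n_slices: 40
  z_step: 0.2
  xy_shape: [24, 24]
  membrane_z: 1.1
  glyx_height: 4.0
  psf_sigma_z: 0.1
  photon_gain: 2000
  read_noise_sd: 0.5
  bleach_per_slice: 0.99
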
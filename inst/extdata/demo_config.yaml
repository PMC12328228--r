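# Demo pipeline configuration: 12 scenes on 64 x 64 grids of 30 m pixels,
# two overpasses per scene, default generator truth. Matches the built-in
# defaults; provided as a template — any unknown key is rejected.
study:
  n_scenes: 12
  n_overpasses: 2
  grid_size: 64
  pixel_size: 30
  n_points_per_sxo: 1000
  canopy_threshold: 30
  max_edge_distance: 1000
  cloud_fraction: 0.1
  seed: 1
  n_patches: 4
  patch_scale: 500
truth:
  a0: 0.4
  a1: -0.05
  a2: 0.004
  lam: 90
  lapse: -0.0065
  sigma_noise: 1.5
  sigma_scene: 2
analysis:
  d_edge: 30
  d_interior: 500
  variant_edge: 50
  variant_interior: 1000
  se_rule: as-printed
  morans_points: 2000
topt:
  mode: offset-from-interior
  offset: -2
  cell_size: 960
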
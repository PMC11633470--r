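# Example wellTFM pipeline configuration. All lengths in micrometres,
# moduli/tractions in pascals.
paths:
  reference: demo/reference.tif   # relaxed-state bead stack (multi-page TIFF)
  deformed: demo/deformed.tif     # deformed-state bead stack
  output_dir: demo/out
  # lensing_calibration: demo/lensing.csv   # optional displacement CSV
  # well_center: [10.25, 10.25, 5.25]       # optional manual cx, cy, radius

imaging:
  pixel_size_xy: 0.104   # lateral voxel size
  z_step: 0.2            # nominal objective z-step (before Visser correction)

geometry:
  radius: 5.25
  depth: 12
  gel_height: 60
  lateral_extent: 60
  fillet_bottom: 0.5
  fillet_top: 1.0

optics:                  # omit the block to skip the axial correction
  na: 1.2
  n_immersion: 1.47      # glycerin
  n_sample: 1.34         # hydrogel / medium
  z_step: 0.2

piv:
  box: [16, 16, 8]       # voxels; 32x32x8 for larger wells
  overlap: 0.5

mesh:
  target_edge_length: 1.05

material:
  youngs_modulus: 15000
  poisson_ratio: 0.45
  law: linear            # or neo_hookean

inverse:
  lambda: 1.0e-3         # unitless Tikhonov weight

seed: 1
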
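# Demo run configuration: synthetic two-sheet scene at tilt 23 degrees,
# sheets rotated 60 degrees in plane, reduced solver schedule.
# All angles in degrees. Per-stage seeds derive from `seed` unless given
# under `seeds:`.
version: 1
seed: 1
stages: [simulate, segment, fit, train, solve, check_geometry]
scene:
  dim: [48, 64]
  snr: 56
  baseline: 10
  sheets:
    - {center: [18, 22], side: 13, phi_deg: 25, theta_deg: 23,
       beta: [1, 0.45, 0.3, 0.25, 0.15, -0.1, 0.2], scale: 1}
    - {center: [47, 26], side: 13, phi_deg: 85, theta_deg: 23,
       beta: [1, 0.45, 0.3, 0.25, 0.15, -0.1, 0.2], scale: 1.3}
segmentation:
  k: 3
rois:
  - {box: [12, 34, 10, 36], sheet_id: sheet1}
  - {box: [38, 60, 12, 40], sheet_id: sheet2}
solver:
  n_train: 20000
  epochs: 200
  batch_size: 100
  hidden: [200, 100, 50]
  lr: 0.002
  lr_decay: 0.99
  val_frac: 0.1
observation:
  delta_phi_deg: 60
geometry:
  h_observed: 2.9
  h_upright: 3.1
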
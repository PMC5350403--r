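# Example run configuration for the stemopt pipeline.
# Any key may be omitted; missing entries use the package defaults.
stem_material: ti6al4v     # or "fgm" for the 11-layer graded stem
n_axial: 95                # axial surface sampling stations
n_circ: 32                 # circumferential samples (95 x 32 = 3040)
seed: 1
design_life: 2.0e+06       # cycles at which nodal cement damage is assessed
sn:
  a_mpa: 90                # S = A * N^b (PMMA bone cement fit)
  b: -0.13
  n_min: 1.0e+02
  n_max: 1.0e+08
loads:
  joint_kn: 2.5            # hip joint contact force, 10 deg from the axis
  joint_angle_deg: 10
  abductor_kn: 1.5         # abductor muscle force, 15 deg from the axis
  abductor_angle_deg: 15
  joint_offset_mm: 45
  abductor_offset_mm: 45
optimizer:
  n_init: 10               # random initial vertices
  max_restarts: 30         # farthest-vertex probabilistic restarts
  offset: 0.2              # Taguchi level offset, fraction of domain width
  weighting: variance      # restart selection: variance | uniform
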
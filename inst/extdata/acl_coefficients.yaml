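# Data-driven knee model coefficients (synthetic defaults).
#
# The three-plane ACL model needs cadaver-regression coefficients that are
# not shipped with any public dataset; the values below are literature-scale
# defaults chosen to reproduce the expected qualitative behaviour (sagittal
# proportion of anterior ligamentous shear decreasing with flexion; frontal
# and transverse components exponential in the plane moment and decaying
# with flexion).  Absolute ACL forces are therefore coefficient-dependent;
# edit this file to use a specific regression set.
sagittal_proportion:
  flexion_deg: [0, 15, 30, 45, 60, 75, 90]
  proportion: [0.85, 0.85, 0.75, 0.60, 0.50, 0.40, 0.35]
frontal:
  scale_N: 44.0
  moment_rate_per_Nm: 0.08
  flexion_rate_per_rad: 1.0
moment_cap_Nm: 60.0
transverse:
  scale_N: 25.0
  moment_rate_per_Nm: 0.30
  flexion_rate_per_rad: 1.0
patellar_tendon_angle:
  flexion_deg: [0, 15, 30, 45, 60, 70, 80, 90]
  angle_deg: [20, 15, 10, 5, 2, 0, -3, -5]
# constant anterior line-of-action angles (deg) for non-quadriceps knee
# muscles; quadriceps act through the patellar tendon table above
muscle_lines:
  hamstrings: -20
  gastroc: -8
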
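name: nominal_3d
# Full-body 3D skier: free pelvis (6), ball lumbar (3), per leg a ball hip
# (3), revolute knee (1) and revolute ankle (1); subtalar and toe joints
# locked (ski boot); arms welded to the trunk in a typical skiing posture.
# Segment masses follow standard anthropometric proportions scaled to the
# subject (height 1.90 m, mass 72 kg) plus boot and ski equipment masses.
subject:
  height_m: 1.90
  mass_kg: 72
reference_posture:
  pelvis_tz: 0.85
  lumbar_flex: 0.25
  hip_r_flex: 1.10
  hip_l_flex: 1.10
  knee_r: 1.20
  knee_l: 1.20
  ankle_r: 0.285
  ankle_l: 0.285
boot:
  neutral_angle: 0.28
  deadband: 0.03
  stiffness: [150, 100000]
  damping: 5.0
segments:
  - name: pelvis
    parent: world
    joint: {name: pelvis, kind: free6}
    origin: [0.0, 0.0, 0.0]
    mass: 8.2
    com: [0.0, 0.0, 0.07]
    inertia: [0.08, 0.08, 0.06]
  - name: torso
    parent: pelvis
    joint: {name: lumbar, kind: ball3}
    origin: [0.0, 0.0, 0.15]
    mass: 28.0
    com: [0.02, 0.0, 0.25]
    inertia: [1.2, 1.3, 0.35]
  - name: arm_r
    parent: torso
    joint: {name: shoulder_r, kind: locked, fixed_rotation_zxy: [0.0, -0.25, 0.45]}
    origin: [0.0, -0.20, 0.42]
    mass: 3.6
    com: [0.0, 0.0, -0.28]
    inertia: [0.17, 0.17, 0.01]
  - name: arm_l
    parent: torso
    joint: {name: shoulder_l, kind: locked, fixed_rotation_zxy: [0.0, 0.25, 0.45]}
    origin: [0.0, 0.20, 0.42]
    mass: 3.6
    com: [0.0, 0.0, -0.28]
    inertia: [0.17, 0.17, 0.01]
  - name: femur_r
    parent: pelvis
    joint: {name: hip_r, kind: ball3, signs: [1, 1, -1]}
    origin: [0.0, -0.09, 0.0]
    mass: 10.2
    com: [0.0, 0.0, -0.20]
    inertia: [0.18, 0.18, 0.03]
  - name: tibia_r
    parent: femur_r
    joint: {name: knee_r, kind: revolute1, axis: [0, 1, 0]}
    origin: [0.0, 0.0, -0.46]
    mass: 3.1
    com: [0.0, 0.0, -0.19]
    inertia: [0.05, 0.05, 0.005]
  - name: talus_r
    parent: tibia_r
    joint: {name: ankle_r, kind: revolute1, axis: [0, -1, 0]}
    origin: [0.0, 0.0, -0.44]
    mass: 0.1
    com: [0.0, 0.0, -0.01]
    inertia: [0.001, 0.001, 0.001]
  - name: calcn_r
    parent: talus_r
    joint: {name: subtalar_r, kind: locked}
    origin: [-0.05, 0.0, -0.04]
    mass: 2.7
    com: [0.09, 0.0, -0.03]
    inertia: [0.01, 0.02, 0.02]
  - name: toes_r
    parent: calcn_r
    joint: {name: mtp_r, kind: locked}
    origin: [0.18, 0.0, -0.06]
    mass: 0.2
    com: [0.03, 0.0, 0.0]
    inertia: [0.001, 0.001, 0.001]
  - name: ski_r
    parent: calcn_r
    joint: {name: binding_r, kind: locked}
    origin: [0.05, 0.0, -0.07]
    mass: 4.5
    com: [0.0, 0.0, 0.0]
    inertia: [0.005, 1.08, 1.08]
    contact_points:
      - [0.8, 0.0, 0.0]
      - [0.0, 0.0, 0.0]
      - [-0.7, 0.0, 0.0]
  - name: femur_l
    parent: pelvis
    joint: {name: hip_l, kind: ball3, signs: [-1, -1, -1]}
    origin: [0.0, 0.09, 0.0]
    mass: 10.2
    com: [0.0, 0.0, -0.20]
    inertia: [0.18, 0.18, 0.03]
  - name: tibia_l
    parent: femur_l
    joint: {name: knee_l, kind: revolute1, axis: [0, 1, 0]}
    origin: [0.0, 0.0, -0.46]
    mass: 3.1
    com: [0.0, 0.0, -0.19]
    inertia: [0.05, 0.05, 0.005]
  - name: talus_l
    parent: tibia_l
    joint: {name: ankle_l, kind: revolute1, axis: [0, -1, 0]}
    origin: [0.0, 0.0, -0.44]
    mass: 0.1
    com: [0.0, 0.0, -0.01]
    inertia: [0.001, 0.001, 0.001]
  - name: calcn_l
    parent: talus_l
    joint: {name: subtalar_l, kind: locked}
    origin: [-0.05, 0.0, -0.04]
    mass: 2.7
    com: [0.09, 0.0, -0.03]
    inertia: [0.01, 0.02, 0.02]
  - name: toes_l
    parent: calcn_l
    joint: {name: mtp_l, kind: locked}
    origin: [0.18, 0.0, -0.06]
    mass: 0.2
    com: [0.03, 0.0, 0.0]
    inertia: [0.001, 0.001, 0.001]
  - name: ski_l
    parent: calcn_l
    joint: {name: binding_l, kind: locked}
    origin: [0.05, 0.0, -0.07]
    mass: 4.5
    com: [0.0, 0.0, 0.0]
    inertia: [0.005, 1.08, 1.08]
    contact_points:
      - [0.8, 0.0, 0.0]
      - [0.0, 0.0, 0.0]
      - [-0.7, 0.0, 0.0]
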
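name: reduced_planar
subject:
  height_m: 1.90
  mass_kg: 72
# reference skiing crouch used to calibrate muscle reference lengths;
# knee flexion ~69 deg matches the consistently deep-flexed turning regime
reference_posture:
  pelvis_pitch: 0.40
  hip_r: 1.10
  hip_l: 1.10
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
    joint: {name: pelvis, kind: planar3}
    origin: [0.0, 0.0, 0.0]
    mass: 8.2
    com: [0.0, 0.0, 0.07]
    inertia: [0.08, 0.08, 0.06]
  - name: torso
    parent: pelvis
    joint: {name: lumbar, kind: locked}
    origin: [0.0, 0.0, 0.15]
    mass: 35.2
    com: [0.02, 0.0, 0.25]
    inertia: [1.4, 1.5, 0.4]
  - name: thigh_r
    parent: pelvis
    joint: {name: hip_r, kind: revolute1, axis: [0, -1, 0]}
    origin: [0.0, -0.09, 0.0]
    mass: 10.2
    com: [0.0, 0.0, -0.20]
    inertia: [0.18, 0.18, 0.03]
  - name: shank_r
    parent: thigh_r
    joint: {name: knee_r, kind: revolute1, axis: [0, 1, 0]}
    origin: [0.0, 0.0, -0.46]
    mass: 3.1
    com: [0.0, 0.0, -0.19]
    inertia: [0.05, 0.05, 0.005]
  - name: foot_r
    parent: shank_r
    joint: {name: ankle_r, kind: revolute1, axis: [0, -1, 0]}
    origin: [0.0, 0.0, -0.44]
    mass: 3.0
    com: [0.06, 0.0, -0.05]
    inertia: [0.01, 0.02, 0.02]
  - name: ski_r
    parent: foot_r
    joint: {name: binding_r, kind: locked}
    origin: [0.0, 0.0, -0.11]
    mass: 4.5
    com: [0.0, 0.0, 0.0]
    inertia: [0.005, 1.08, 1.08]
    contact_points:
      - [0.8, 0.0, 0.0]
      - [0.0, 0.0, 0.0]
      - [-0.7, 0.0, 0.0]
  - name: thigh_l
    parent: pelvis
    joint: {name: hip_l, kind: revolute1, axis: [0, -1, 0]}
    origin: [0.0, 0.09, 0.0]
    mass: 10.2
    com: [0.0, 0.0, -0.20]
    inertia: [0.18, 0.18, 0.03]
  - name: shank_l
    parent: thigh_l
    joint: {name: knee_l, kind: revolute1, axis: [0, 1, 0]}
    origin: [0.0, 0.0, -0.46]
    mass: 3.1
    com: [0.0, 0.0, -0.19]
    inertia: [0.05, 0.05, 0.005]
  - name: foot_l
    parent: shank_l
    joint: {name: ankle_l, kind: revolute1, axis: [0, -1, 0]}
    origin: [0.0, 0.0, -0.44]
    mass: 3.0
    com: [0.06, 0.0, -0.05]
    inertia: [0.01, 0.02, 0.02]
  - name: ski_l
    parent: foot_l
    joint: {name: binding_l, kind: locked}
    origin: [0.0, 0.0, -0.11]
    mass: 4.5
    com: [0.0, 0.0, 0.0]
    inertia: [0.005, 1.08, 1.08]
    contact_points:
      - [0.8, 0.0, 0.0]
      - [0.0, 0.0, 0.0]
      - [-0.7, 0.0, 0.0]
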
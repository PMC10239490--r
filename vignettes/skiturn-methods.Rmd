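---
title: "Methods: musculoskeletal simulation of carved-turn skiing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: musculoskeletal simulation of carved-turn skiing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

`skiturn` estimates muscle forces and anterior-cruciate-ligament (ACL)
loading of an alpine skier during a carved turn by tracking reference
kinematics with a muscle-driven multibody model. The computation has four
layers:

1. a rigid-body skier with Hill-type muscles and ski-boot passive
   stiffness, whose dynamics are written as an implicit residual
   `f(x, xdot, u) = 0` with states `x = [q, qdot, s, a]` (generalized
   coordinates and velocities, projected fiber lengths, activations) plus
   one hypoplastic contact-memory depth per ski contact point, and controls
   `u` the neural excitations;
2. a segmented-ski / snow environment: penetration normal force with a
   two-branch hypoplastic law, edge-orthogonal shear, regularized Coulomb
   friction (`mu = 0.08`), and quadratic air drag (`CdA = 0.3 m^2`,
   `rho = 1.07 kg/m^3`) applied at the pelvis;
3. a direct-collocation tracking optimizer (implicit Euler, 75 mesh points
   nominal) minimizing
   `J = (1/T) \int (w1/n_d)||err_d||^2 + (w2/n_m)||a||_p^p +
   (w3/n_xu)(||xdot||^2 + ||udot||^2) dt`;
4. Newton–Euler intersegmental knee loads and a data-driven three-plane
   ACL model.

Because no motion-capture recordings ship with the package, a synthetic-data
module generates the complete study conditions: the 12.3-degree slope with
gates offset 8 m transverse / 16 m downhill, a dynamically consistent
single-turn reference motion, noisy tracked channels and surface-EMG
envelopes.

# Models and presets

## Rigid-body skier

Two presets ship as YAML configurations. `nominal_3d` is the full
three-dimensional skier: a free pelvis (6 DOF), ball lumbar and hip joints
(3 DOF each), revolute knees and ankles (1 DOF each), 19 DOF in total;
subtalar and toe joints are locked because the ski boot admits only
dorsi-/plantarflexion, and the arms are welded to the trunk in a typical
skiing posture with their mass and inertia folded into the trunk assembly
(`compress_model()`). Segment masses follow standard anthropometric
proportions scaled to the subject (height 1.90 m, mass 72 kg) plus boot and
ski equipment masses (total 85 kg). Ball joints use an extrinsic Z-X-Y
rotation sequence; per-coordinate sign flags make hip flexion, adduction and
internal rotation anatomically positive on both legs.

`reduced_planar` is the sagittal-plane workhorse used for forward
simulation and optimization studies: a planar pelvis joint (x, z, pitch)
plus one hip, knee and ankle hinge per leg (9 DOF), with the trunk-arm
assembly welded to the pelvis and a rigid ski welded to each foot carrying
three contact points (tip, binding, tail). A carved turn is inherently
three-dimensional; the planar model instead runs the fall line and executes
the turn's *loading cycle* (flexion-extension under elevated leg load), so
all muscle-path, contact, activation and tracking machinery is exercised at
a scale where the optimization is cheap. What planar tests cannot show:
lateral balance, edging-angle dynamics, and frontal/transverse knee
moments; those paths are exercised by the prescribed three-dimensional
carved-turn fixture (below).

The engine exists in two implementations with identical semantics: a
generic tree engine (any joint set, velocity-level quantities by high-order
finite differencing of the exact pose map) and a fast analytic planar
engine vectorized across evaluation points. The two are cross-checked
against each other and against an independently derived symbolic Lagrangian
oracle in the test suite (agreement to machine precision).

## Muscles

Muscles are three-element Hill models in the implicit formulation: the
contraction state is the projected fiber length `s`; the residual balances
the tendon force (quadratic toe to linear, 4% strain at maximal isometric
force) against the fiber force (Gaussian active force-length of width 0.45,
hyperbolic force-velocity with `v_max = 10 l_opt/s`, eccentric plateau 1.5,
quadratic passive element engaging above optimal length, constant-thickness
pennation). A normalized fiber damping of 0.01 makes the residual solvable
in `sdot` at zero activation. Activation follows
`adot = (u - a)(u/tau_act + (1 - u)/tau_deact)` with `tau_act = 0.015 s`,
`tau_deact = 0.060 s`.

Muscle path geometry is a polynomial moment-arm surrogate: each spanned
coordinate carries an arm polynomial and the musculotendon length is its
negative integral, so `r = -dl_mt/dq` holds identically. The nominal roster
has 94 muscles (43 per leg, 8 lumbar) in `muscles_nominal_3d.csv`; a
16-muscle planar set (8 per leg: iliopsoas, gluteus maximus, hamstrings,
rectus femoris, vasti, gastrocnemius, soleus, tibialis anterior) ships for
the reduced model. Reference musculotendon lengths are calibrated at load
time so each fiber sits at its optimal length with a slack tendon in the
preset's reference crouch (knee flexion 69 degrees) — a choice that avoids
shipping fragile absolute path lengths.

## Ski and snow

The ski is split into 18 rigid segments joined by 17 revolute bending
joints with rotational spring-dampers whose neutral angles reproduce the
camber arc; `ski_chain_model()` exposes the chain as a multibody model for
bench tests (static deflection, conservative free oscillation). Torsion is
neglected. The side-cut edge is a circular arc of radius 18 m.

Snow contact acts at ski contact points: the penetration force follows a
two-branch incremental (hypoplastic) law — virgin loading stiffness
`k_load = 1.5e4 N/m` per point while the depth exceeds the memory depth,
and a four-times-stiffer unloading/reloading branch anchored at the memory
point otherwise, so compressed snow stays compressed and re-penetrating the
groove is easier than virgin snow. The memory depth is an explicit state
advanced by its own residual row (a softplus-rectified running maximum), so
the optimizer sees a fully state-defined smooth system. A rate term
(`1.5e3 N s/m`) adds penetration-speed dissipation, an edging-angle factor
(`0.3 + 0.7 cos`) narrows the bearing band of an edged ski, and the total
is floored at zero through a one-sided C1 quadratic blend whose tail is
exactly zero — airborne segments carry literally no force. The stiffness
values are order-of-magnitude estimates (about 1 cm penetration under a
loaded ski) and are flagged as such in the configuration; no laboratory
identification ships with the package.

Friction is `mu N` antiparallel to the segment velocity with a 1e-3 m/s
saturated-viscous regularization; shear resistance is proportional to edge
penetration depth and orthogonal to the edge in the tangent plane.

# The tracking optimizer

The optimal control problem is transcribed by direct collocation with the
implicit Euler formula: decision variables are states and controls at every
mesh node, and each interval contributes the defect
`f(x_{k+1}, (x_{k+1}-x_k)/h, u_{k+1}) = 0`. The objective integral uses the
right-endpoint rectangle rule on the same nodes; `xdot` and `udot` in the
regularization use the same backward differences as the defects. Tracking
errors are normalized per channel by fixed characteristic scales (10
degrees for angles, 0.1 m for translations) rather than data-dependent
scaling, so the objective is reproducible. The weights `w2 = 10` and the
effort exponent `p = 2` are the nominal settings; `w1 = 1` and `w3 = 1e-3`
are package defaults chosen once so the three terms sit within about two
orders of magnitude on the synthetic case.

The NLP is solved by a sparse sequential-quadratic-programming iteration
written for this package: a Gauss-Newton Hessian of the least-squares
objective, exact-sparsity defect Jacobians evaluated by one batched
finite-difference call on the vectorized planar residual, a KKT solve per
iteration with Levenberg damping in a per-variable scaled metric, an l1
merit line search with a second-order correction, an active-set freeze for
variables held on their bounds, and a final feasibility restoration by
forward simulation (the defect manifold is exactly parameterized by the
initial state and the controls). Convergence is declared at a scaled defect
infinity-norm of 1e-6. Departures from common practice worth noting: the
Jacobians are finite-difference rather than symbolically exact (the
batched evaluation makes them cheap and the sparse structure is exact), and
bounds are handled by projection plus the active-set freeze rather than an
interior point — adequate here because solutions sit mostly strictly inside
the bounds.

Two initial guesses are implemented. The *schussing* guess simulates a
straight glide in the reference crouch, independent of the reference data
(with a second pass whose tonic feedforward is re-estimated from the
measured dynamic joint moments of the first). The *PD-tracking* guess
adopts the reference kinematics node by node — the perfect-tracking limit
of a PD follower — recovers the required joint moments from the muscle-free
residual, and populates activations, excitations and isometric fiber states
by a per-node static muscle-redundancy solve (minimum sum of squared
activations subject to moment match and bounds).

# Synthetic study conditions

`generate_reference_turn()` produces the tracking reference by closed-loop
forward simulation of the reduced skier: a reflex controller (joint PD
mapped onto muscles through their moment arms, a trunk-pitch ankle
strategy, and a static-redundancy feedforward) holds a schussing crouch,
targets are re-anchored at the settled equilibrium, and the turn's loading
cycle deepens knee and hip flexion by 0.22 rad between 0.55 s and 1.55 s
with extra excitation bumps on the outside-leg extensors (the excitation
schedule template, tuned once and versioned). Entry speed is 12 m/s, rising
to about 15 m/s over the window — the gliding regime of the course
geometry. Outside-knee flexion stays above 60 degrees through the steering
phase. The recorded mesh trajectory satisfies the implicit-Euler defects to
about 1e-8 (it is produced by the same discretization), so the reference is
exactly feasible for the tracker at the nominal mesh, and the stored
excitations are ground truth for recovery checks. Fixtures are regenerable
from (configuration, seed) alone; nothing binary is stored.

Channel noise is Gaussian per sample (defaults 0.5 degrees / 1 cm,
comparable to the few-millimetre-to-centimetre accuracy of surveyed video
reconstruction), optionally followed by a cross-validated smoothing-spline
pass; the implementation uses cubic smoothing splines with GCV rather than
quintic splines, which matters only above the fourth derivative and is
documented here as a deliberate simplification. Synthetic EMG envelopes are
`gain * activation + noise`, rectified, with random per-muscle gains in
[0.5, 2] because EMG amplitude is scale-free; comparisons rescale each
envelope to the maximum of the estimated activation.

For the three-dimensional knee-load pathway,
`generate_carved_turn_kinematics()` prescribes a left carved turn of the
nominal skier (yaw rate integrated into heading and path so curvature peaks
at 1/10.7 m^-1 without ramp acceleration spikes; inclination follows the
centripetal balance angle capped at 0.65 rad; the inside knee more flexed
than the outside). Ground reaction forces are constructed from whole-body
force balance and split 62/38 between the outside and inside ski; the hip
ab/adduction angulation is solved so the quasi-static external frontal
knee moment peaks at a realistic 35 N·m (abduction) on the outside knee and
25 N·m (adduction) on the inside knee. The fixture satisfies force balance
but not the full whole-body moment balance — sufficient for the distal
Newton–Euler recursion that produces the knee loads, and documented as a
synthetic stand-in, not a dynamic solution.

# Knee loads and the ACL model

Intersegmental knee loads are computed by the Newton–Euler recursion over
the segments distal to the knee (ski, boot/foot, shank) with segment
accelerations taken from the same backward differences as the implicit
integration, and are expressed in the tibia frame (x anterior, y flexion
axis, z proximal). The ligamentous anteroposterior shear subtracts the
anterior components of the knee-crossing muscle forces: quadriceps through
the patellar-tendon angle table (sign change near 70 degrees flexion),
hamstrings and gastrocnemius along constant posterior-inclined lines.

The ACL force is the sum of three nonnegative components: sagittal — a
tabulated flexion-dependent proportion of the anterior ligamentous shear
(zero for posterior shear); frontal — exponential in the external abduction
moment and decaying with flexion, zero for adduction-side moments; and
transverse — the analogue for internal-rotation moments. The regression
coefficients that calibrate these curves come from cadaver experiments that
are not publicly redistributable, so the shipped
`acl_coefficients.yaml` contains synthetic literature-scale defaults
(clearly labelled in the file) chosen to give about 215 N at 35 N·m
abduction and 66 degrees flexion; plane moments are clamped at a 60 N·m
calibration cap because the exponentials are meaningless outside the
fitted range. Absolute ACL numbers from this package are therefore
coefficient-dependent; the qualitative structure (outside-leg peak, frontal
dominance under deep flexion, small sagittal contribution when hamstrings
co-activate and the ground reaction pushes the tibia backwards) is the
scientifically meaningful output. Tibiofemoral compression does not enter
the sagittal term in the default model.

# Numerical choices and degenerate inputs

* Implicit Euler everywhere (integration and transcription): first-order,
  strongly damped, robust for the stiff contact dynamics; the step-doubling
  test verifies order one.
* Slip and shear regularization 1e-3 m/s; contact smoothing width 1 mm of
  depth; hypoplastic memory rate `50 softplus(d - m)` with a 0.5 mm
  softplus width. All smooth approximations have their exact (branchy)
  counterparts in `penetration_force()` etc., which define the reference
  semantics for the property tests.
* Zero-length or locked chains, empty muscle sets and airborne phases are
  all legal inputs; validation errors are classed
  (`skiturn_validation_error`, `skiturn_structural_error`,
  `skiturn_integration_error`, ...).
* Problem sizes in the shipped tests and the acceptance script: the
  reduced planar model (9 DOF, 16 muscles, 6 contact points, 56 states) on
  a 75-point mesh — about 5400 decision variables and 4100 defects; the
  weight sweep runs at 21 mesh points with warm starts. These sizes were
  chosen as the package's desk-scale study conditions.

# Known limitations

* The planar reduced model cannot produce lateral skidding, edging dynamics
  or frontal-plane knee loading; the 3D pathway is exercised on prescribed
  kinematics, not a 3D optimal-control solution.
* Muscle paths are polynomial surrogates without wrapping geometry, and the
  Hill-curve shape constants are standard literature values, so absolute
  muscle forces carry model uncertainty well beyond the solver tolerances.
* Ski-chain bending is modelled for the bench (static deflection, free
  oscillation) but the skis are rigid in the skier simulations.
* The hypoplastic hardness, spring-damper and ACL regression parameters are
  synthetic defaults; all live in editable configuration files.
* The SQP solver is a local method with two documented initial guesses; no
  global search is attempted.
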
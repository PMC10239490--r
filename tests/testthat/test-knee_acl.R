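test_that("static horizontal shank: knee load equals the closed form", {
  ## a single 'shank' segment hanging horizontally from a planar base, with
  ## a distal load W at distance d: knee force = (m g + W) up, knee moment =
  ## m g d_com + W d about the flexion axis
  m <- 3; dcom <- 0.2; dW <- 0.4; W <- 50
  cfg <- list(name = "limb", segments = list(
    list(name = "base", parent = "world",
         joint = list(name = "base", kind = "planar3"),
         origin = c(0, 0, 0), mass = 1, com = c(0, 0, 0),
         inertia = c(0.01, 0.01, 0.01)),
    list(name = "shank_r", parent = "base",
         joint = list(name = "knee_r", kind = "revolute1", axis = c(0, 1, 0)),
         origin = c(0, 0, -0.1), mass = m, com = c(0, 0, -dcom),
         inertia = c(0.02, 0.02, 0.002))))
  mdl <- build_skier_model(cfg)
  b <- ski_bundle(mdl, NULL)
  n <- 5
  Q <- matrix(0, mdl$n_q, n)
  Q[4, ] <- pi / 2                  # shank horizontal
  ext <- lapply(seq_len(n), function(k)
    list(list(segment = "shank_r", force = c(0, 0, -W),
              point = c(-dW, 0, -0.1))))
  loads <- intersegmental_loads(b, list(time = seq(0, 1, length.out = n),
                                        Q = Q), "right", ext)
  k <- 3
  ## knee force in the world z direction = (m g + W) upward; the tibia frame
  ## at 90 deg flexion maps world +z onto the anterior axis
  Fw <- loads$force[, k]
  expect_equal(sum(Fw^2), (m * 9.81 + W)^2, tolerance = 1e-6)
  expect_equal(abs(loads$moment["flexion", k]),
               m * 9.81 * dcom + W * dW, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("knee flexion moment matches the generalized-force projection", {
  ## two independent load paths: the Newton-Euler recursion over the distal
  ## segments versus the muscle joint moment that the knee coordinate row of
  ## the system residual implies on a dynamically consistent trajectory
  fx <- turn_fixture(75)
  b <- planar_bundle()
  L <- b$layout
  traj <- fx$trajectory
  loads <- intersegmental_loads(b, traj, "right")
  N <- ncol(traj$X)
  h <- traj$dt
  Xd <- cbind((traj$X[, 2] - traj$X[, 1]) / h,
              (traj$X[, -1] - traj$X[, -N]) / h)
  out <- planar_residual(b, traj$X, Xd, traj$U, forces = TRUE)
  cn <- b$model$coord_names
  st <- b$planar
  knee_q <- match("knee_r", cn)
  mus_mom <- rep(0, N)
  for (m in seq_len(L$n_m)) {
    qi <- st$mus_q[[m]]
    for (j in seq_along(qi)) if (qi[j] == knee_q) {
      arm <- arm_poly_eval(st$mus_arms[[m]][[j]], traj$X[L$idx_q[knee_q], ])
      mus_mom <- mus_mom + arm * out$f_tendon[m, ]
    }
  }
  ## recursion moment about the flexion axis (y, sign of the knee axis)
  rec <- loads$moment["flexion", ]
  ks <- 3:(N - 1)
  expect_lt(max(abs(rec[ks] - mus_mom[ks])) / max(abs(mus_mom[ks])), 1e-4)
})

test_that("airborne distal chain reduces to inertia plus gravity", {
  m <- 3; dcom <- 0.2
  cfg <- list(name = "limb", segments = list(
    list(name = "base", parent = "world",
         joint = list(name = "base", kind = "planar3"),
         origin = c(0, 0, 0), mass = 1, com = c(0, 0, 0),
         inertia = c(0.01, 0.01, 0.01)),
    list(name = "shank_r", parent = "base",
         joint = list(name = "knee_r", kind = "revolute1", axis = c(0, 1, 0)),
         origin = c(0, 0, -0.1), mass = m, com = c(0, 0, -dcom),
         inertia = c(0.02, 0.02, 0.002))))
  mdl <- build_skier_model(cfg)
  b <- ski_bundle(mdl, NULL)
  n <- 9
  time <- seq(0, 0.8, length.out = n)
  Q <- matrix(0, mdl$n_q, n)
  Q[2, ] <- -0.5 * 9.81 * time^2     # free fall of the base
  loads <- intersegmental_loads(b, list(time = time, Q = Q), "right",
                                external = lapply(seq_len(n), function(k) list()))
  ## accelerating downward at g: the knee transmits no force
  expect_lt(max(abs(loads$force[, 4:6])), 1e-4)
})

test_that("tibia-frame loads are invariant under a global yaw rotation", {
  fx3 <- carved_turn()
  loads0 <- intersegmental_loads(fx3$bundle, fx3$traj, "right", fx3$external)
  ## extract extrinsic Z-X-Y angles (a, b, c) with R = Ry(c) Rx(b) Rz(a)
  euler_zxy_inv <- function(M) c(atan2(M[2, 1], M[2, 2]), asin(-M[2, 3]),
                                 atan2(M[1, 3], M[3, 3]))
  for (yaw in c(0.7, -1.3)) {
    Rz <- rot_z(yaw)
    tr <- fx3$traj
    xy <- rbind(tr$Q["pelvis_tx", ], tr$Q["pelvis_ty", ])
    tr$Q["pelvis_tx", ] <- cos(yaw) * xy[1, ] - sin(yaw) * xy[2, ]
    tr$Q["pelvis_ty", ] <- sin(yaw) * xy[1, ] + cos(yaw) * xy[2, ]
    for (k in seq_len(ncol(tr$Q))) {
      R0 <- skiturn:::euler_zxy(tr$Q["pelvis_tilt", k],
                                tr$Q["pelvis_list", k],
                                tr$Q["pelvis_rot", k])
      ang <- euler_zxy_inv(Rz %*% R0)
      tr$Q["pelvis_tilt", k] <- ang[1]
      tr$Q["pelvis_list", k] <- ang[2]
      tr$Q["pelvis_rot", k] <- ang[3]
    }
    ext <- lapply(fx3$external, function(lk) lapply(lk, function(ld) {
      ld$force <- as.numeric(Rz %*% ld$force)
      ld$point <- as.numeric(Rz %*% ld$point)
      ld
    }))
    loads1 <- intersegmental_loads(fx3$bundle, tr, "right", ext)
    ## the rotated trajectory is stored in re-decomposed Euler angles, whose
    ## time finite-differences parameterize the same motion only to O(h^2);
    ## frame errors would appear at the 100 percent level, discretization
    ## artifacts stay at the percent level
    ks <- 10:65
    expect_lt(max(abs(loads1$force[, ks] - loads0$force[, ks])) /
                max(abs(loads0$force[, ks])), 0.02)
    expect_lt(max(abs(loads1$moment[, ks] - loads0$moment[, ks])) /
                max(abs(loads0$moment[, ks])), 0.06)
  }
})

test_that("ligamentous shear: passthrough, hamstrings, patellar tendon", {
  co <- read_acl_coefficients()
  shear0 <- c(100, 50, -20)
  flex <- c(0.8, 1.0, 1.2)
  ## zero muscle forces: passthrough
  expect_equal(ligamentous_shear(shear0, NULL, flex, co), shear0)
  ## hamstring force (posterior line) reduces the anterior shear
  mf <- matrix(200, 1, 3, dimnames = list("hamstrings_r", NULL))
  sh <- ligamentous_shear(shear0, mf, flex, co)
  expect_true(all(sh < shear0))
  ## patellar-tendon contribution flips sign across ~70 deg flexion
  mq <- matrix(500, 1, 2, dimnames = list("vasti_r", NULL))
  sh2 <- ligamentous_shear(c(0, 0), mq, deg2rad(c(20, 80)), co)
  expect_gt(sh2[1], 0)   # anterior tendon angle at 20 deg -> anterior shear
  expect_lt(sh2[2], 0)   # posterior at 80 deg
  ## missing line-of-action entry
  bad <- matrix(10, 1, 2, dimnames = list("mystery_r", NULL))
  expect_error(ligamentous_shear(c(0, 0), bad, c(1, 1), co),
               class = "skiturn_validation_error")
})

test_that("ACL model: zeros, gating, additivity, nonnegativity, monotonicity", {
  co <- read_acl_coefficients()
  z <- acl_force(0, 0, 0, 1.1, co)
  expect_equal(z$total, 0)
  ## posterior shear and adduction-side moments load nothing
  z2 <- acl_force(-300, -40, -20, 1.1, co)
  expect_equal(z2$total, 0)
  ## additivity and nonnegativity on a random grid
  set.seed(12)
  sh <- rnorm(200, 0, 200); mf <- rnorm(200, 0, 30); mt <- rnorm(200, 0, 15)
  fl <- runif(200, 0.9, 1.5)
  a <- acl_force(sh, mf, mt, fl, co)
  expect_equal(a$total, a$sagittal + a$frontal + a$transverse)
  expect_true(all(a$sagittal >= 0 & a$frontal >= 0 & a$transverse >= 0))
  ## frontal component: increasing in abduction moment (below the
  ## calibration cap), nonincreasing in flexion
  ms <- seq(0, 55, by = 5)
  f1 <- acl_force(0, ms, 0, 1.1, co)$frontal
  expect_true(all(diff(f1) > 0))
  fls <- seq(0.8, 1.6, by = 0.1)
  f2 <- acl_force(0, 35, 0, fls, co)$frontal
  expect_true(all(diff(f2) <= 0))
})

test_that("body-weight normalization", {
  expect_equal(body_weight_normalize(211, 72), 0.299, tolerance = 1e-3)
  expect_equal(body_weight_normalize(0, 72), 0)
  expect_equal(body_weight_normalize(72 * 9.81, 72), 1)
  expect_error(body_weight_normalize(100, 0),
               class = "skiturn_validation_error")
})

test_that("carved-turn fixture: outside-leg peak with frontal dominance", {
  fx3 <- carved_turn()
  co <- read_acl_coefficients()
  right <- acl_time_series(fx3$bundle, fx3$traj, "right", co,
                           external = fx3$external)
  left <- acl_time_series(fx3$bundle, fx3$traj, "left", co,
                          external = fx3$external)
  expect_gt(max(right$acl$total), max(left$acl$total))
  k <- which.max(right$acl$total)
  expect_gt(right$acl$frontal[k], right$acl$sagittal[k])
  expect_gt(right$acl$frontal[k], right$acl$transverse[k])
  ## deeply flexed regime throughout
  expect_true(all(right$loads$flexion > deg2rad(60)))
})

test_that("missing coefficient file fails with a named i/o error", {
  expect_error(read_acl_coefficients("/nonexistent/acl.yaml"),
               class = "skiturn_io_error")
})
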
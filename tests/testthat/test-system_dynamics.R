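test_that("free fall: the residual vanishes at gravitational acceleration", {
  b <- bare_planar_bundle()
  L <- b$layout
  q <- rep(0, L$n_q); q[2] <- 8      # far above the snow
  x <- numeric(L$n_x); x[L$idx_q] <- q
  xd <- numeric(L$n_x)
  xd[L$idx_qd[2]] <- -9.81           # vertical acceleration only
  r <- system_residual(x, xd, numeric(0), b)
  expect_lt(max(abs(r[c(L$idx_q, L$idx_qd)])), 1e-10)
})

test_that("planar residual equals the symbolic Lagrangian dynamics", {
  b <- bare_planar_bundle()
  L <- b$layout
  f <- lagrangian_eom()
  set.seed(21)
  for (rep in 1:5) {
    q <- rnorm(L$n_q, 0, 0.5); q[2] <- 6
    qd <- rnorm(L$n_q); qdd <- rnorm(L$n_q)
    x <- numeric(L$n_x); x[L$idx_q] <- q; x[L$idx_qd] <- qd
    xd <- numeric(L$n_x); xd[L$idx_q] <- qd; xd[L$idx_qd] <- qdd
    r <- system_residual(x, xd, numeric(0), b)[L$idx_qd] / b$scales[L$idx_qd]
    e <- f(q, qd, qdd)
    expect_lt(max(abs(r - e)) / max(abs(e)), 1e-8)
  }
})

test_that("planar and generic engines agree on the full muscled bundle", {
  b <- planar_bundle()
  L <- b$layout
  set.seed(2)
  x0 <- bundle_initial_state(b, c(pelvis_tz = 0.85, pelvis_pitch = 0.4,
                                  hip_r = 1.1, hip_l = 1.1, knee_r = 1.2,
                                  knee_l = 1.2, ankle_r = 0.285,
                                  ankle_l = 0.285),
                             qd = c(pelvis_tx = 11.7, pelvis_tz = -2.5))
  for (rep in 1:3) {
    x <- x0 + rnorm(L$n_x, 0, 0.01) * pmax(abs(x0), 0.05)
    x[L$idx_a] <- pmin(pmax(x[L$idx_a], 0.01), 0.99)
    x[L$idx_mem] <- abs(x[L$idx_mem])
    xd <- rnorm(L$n_x, 0, 0.5)
    u <- runif(L$n_u)
    rp <- as.numeric(planar_residual(b, matrix(x), matrix(xd), matrix(u)))
    rg <- generic_residual(x, xd, u, b)
    expect_lt(max(abs(rp - rg)), 1e-6)
  }
})

test_that("residual rejects malformed input", {
  b <- planar_bundle()
  L <- b$layout
  expect_error(system_residual(numeric(3), numeric(3), numeric(L$n_u), b),
               class = "skiturn_validation_error")
  x <- numeric(L$n_x); x[1] <- NaN
  expect_error(system_residual(x, numeric(L$n_x), numeric(L$n_u), b),
               class = "skiturn_numeric_error")
})

test_that("passive settling: dissipative limbs come to rest", {
  ## skier hanging in the air with zero excitation: the boot damping and
  ## fiber damping drain the kinetic energy of perturbed joint motion
  b <- planar_bundle()
  L <- b$layout
  x0 <- bundle_initial_state(b, c(pelvis_tz = 8, pelvis_pitch = 0.3,
                                  hip_r = 1.0, hip_l = 1.1, knee_r = 1.1,
                                  knee_l = 1.3, ankle_r = 0.28, ankle_l = 0.28),
                             a0 = 0.01)
  cn <- b$model$coord_names
  ia <- match("ankle_r", cn)
  x0[L$idx_qd[ia]] <- 2            # kick the boot-damped ankle
  tr <- forward_simulate(b, x0, rep(0, L$n_u), T = 0.8, dt = 0.004)
  ## the boot spring-damper drains the ankle motion
  expect_lt(abs(tr$X[L$idx_qd[ia], ncol(tr$X)]), 0.1 * 2)
  ## and no joint motion grows
  ke_joint <- function(k) sum(tr$X[L$idx_qd[3:9], k]^2)
  expect_lt(ke_joint(ncol(tr$X)), 1.2 * ke_joint(2))
})

test_that("symmetric schuss stays symmetric", {
  ## analog of a straight glide staying on track: with identical legs and a
  ## symmetric start, left and right joint angles remain identical
  fx <- turn_fixture(75)
  b <- planar_bundle()
  cn <- b$model$coord_names
  L <- b$layout
  tr <- fx$trajectory
  ## during the pre-bump window (first 0.5 s) legs loaded identically
  ks <- 1:19
  expect_lt(max(abs(tr$X[L$idx_q[match("hip_r", cn)], ks] -
                      tr$X[L$idx_q[match("hip_l", cn)], ks])), 1e-6)
  expect_lt(max(abs(tr$X[L$idx_q[match("knee_r", cn)], ks] -
                      tr$X[L$idx_q[match("knee_l", cn)], ks])), 1e-6)
})

test_that("implicit Euler is first-order accurate (step doubling)", {
  b <- planar_bundle()
  L <- b$layout
  ff <- skiturn:::static_feedforward(b, c(pelvis_pitch = 0.40, hip_r = 1.10,
                                          hip_l = 1.10, knee_r = 1.20,
                                          knee_l = 1.20, ankle_r = 0.285,
                                          ankle_l = 0.285), 12, trim = FALSE)
  x0 <- bundle_initial_state(b, c(pelvis_pitch = 0.40, hip_r = 1.10,
                                  hip_l = 1.10, knee_r = 1.20, knee_l = 1.20,
                                  ankle_r = 0.285, ankle_l = 0.285,
                                  pelvis_tz = ff$tz),
                             qd = c(pelvis_tx = 11.7, pelvis_tz = -2.56),
                             a0 = pmax(ff$u_ff, 0.02))
  u <- pmax(ff$u_ff, 0.02)
  ref <- forward_simulate(b, x0, u, T = 0.2, dt = 0.0025)
  e <- sapply(c(0.02, 0.01, 0.005), function(hh) {
    tr <- forward_simulate(b, x0, u, T = 0.2, dt = hh)
    max(abs(tr$X[L$idx_q, ncol(tr$X)] - ref$X[L$idx_q, ncol(ref$X)]))
  })
  ## halving dt shrinks the error by roughly half (order one)
  expect_lt(e[2] / e[1], 0.7)
  expect_lt(e[3] / e[2], 0.7)
})

test_that("energy audit closes within 1 percent of peak power", {
  b <- planar_bundle()
  L <- b$layout
  ff <- skiturn:::static_feedforward(b, c(pelvis_pitch = 0.40, hip_r = 1.10,
                                          hip_l = 1.10, knee_r = 1.20,
                                          knee_l = 1.20, ankle_r = 0.285,
                                          ankle_l = 0.285), 12, trim = FALSE)
  x0 <- bundle_initial_state(b, c(pelvis_pitch = 0.40, hip_r = 1.10,
                                  hip_l = 1.10, knee_r = 1.20, knee_l = 1.20,
                                  ankle_r = 0.285, ankle_l = 0.285,
                                  pelvis_tz = ff$tz),
                             qd = c(pelvis_tx = 11.7, pelvis_tz = -2.56),
                             a0 = pmax(ff$u_ff, 0.02))
  tr <- forward_simulate(b, x0, pmax(ff$u_ff, 0.02), T = 0.4, dt = 0.002)
  au <- energy_audit(b, tr)
  expect_lt(au$rel_error, 0.01)
})

test_that("scalar implicit-Euler step has the closed-form root", {
  x1 <- implicit_euler_root(function(x, xd, u) xd + x, 1, NULL, 0.1)
  expect_equal(x1, 1 / 1.1, tolerance = 1e-12)
})
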
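test_that("objective parts take their closed forms", {
  b <- planar_bundle()
  L <- b$layout
  grid <- collocation_grid(11, 2)
  ## reference equal to a constant trajectory
  N <- grid$n_mesh
  X <- matrix(0, L$n_x, N)
  X[L$idx_q[2], ] <- 1
  U <- matrix(0, L$n_u, N)
  ref <- list(channels = X[L$idx_q, , drop = FALSE],
              names = b$model$coord_names,
              is_angle = !grepl("_t[xz]$", b$model$coord_names))
  ref$scales <- ifelse(ref$is_angle, deg2rad(10), 0.1)
  class(ref) <- "reference_data"
  spec <- objective_spec()

  ## perfect tracking, zero activation, constant states -> J = 0
  ot <- objective_terms(X, U, ref, spec, grid, b)
  expect_equal(ot$J, 0)

  ## single channel offset by a constant error e (normalized)
  X2 <- X; X2[L$idx_q[3], ] <- X2[L$idx_q[3], ] + deg2rad(10)  # e = 1 scale
  ot2 <- objective_terms(X2, U, ref, spec, grid, b)
  expect_equal(ot2$tracking, spec$w1 * 1 / L$n_q, tolerance = 1e-12)
  expect_equal(ot2$J, ot2$tracking + ot2$effort + ot2$regularization)

  ## constant activations 0.5, p = 2 -> effort = w2 * 0.25
  X3 <- X; X3[L$idx_a, ] <- 0.5
  ot3 <- objective_terms(X3, U, ref, spec, grid, b)
  expect_equal(ot3$effort, spec$w2 * 0.25, tolerance = 1e-12)
  expect_equal(ot3$tracking, 0)

  ## parts are nonnegative and sum to J on a random trajectory
  set.seed(3)
  X4 <- matrix(rnorm(L$n_x * N, 0, 0.1), L$n_x, N)
  X4[L$idx_a, ] <- abs(X4[L$idx_a, ])
  U4 <- matrix(runif(L$n_u * N), L$n_u, N)
  ot4 <- objective_terms(X4, U4, ref, spec, grid, b)
  expect_true(all(c(ot4$tracking, ot4$effort, ot4$regularization) >= 0))
  expect_equal(ot4$J, ot4$tracking + ot4$effort + ot4$regularization)
})

test_that("collocation defects vanish on a simulated trajectory", {
  fx <- turn_fixture(75)
  b <- planar_bundle()
  grid <- collocation_grid(75, 2)
  D <- discretize_dynamics(fx$trajectory$X, fx$trajectory$U, grid, b)
  expect_lt(max(abs(D)), 1e-6)
})

test_that("NLP dimensions and bounds checks", {
  b <- planar_bundle()
  fx <- turn_fixture(75)
  grid <- collocation_grid(2, 2)
  ref <- reference_data(fx, grid)
  prob <- assemble_nlp(b, ref, objective_spec(), grid)
  L <- b$layout
  expect_equal(prob$n_z, 2 * (L$n_x + L$n_u))
  expect_equal(prob$n_c, 1 * L$n_x)
  bad <- b
  bad$bounds$x_lower[1] <- 10; bad$bounds$x_upper[1] <- -10
  expect_error(assemble_nlp(bad, ref, objective_spec(), grid),
               class = "skiturn_validation_error")
})

test_that("sparse defect Jacobian matches a dense finite-difference oracle", {
  b <- planar_bundle()
  fx <- turn_fixture(75)
  grid <- collocation_grid(4, 2)
  ref <- reference_data(fx, grid)
  prob <- assemble_nlp(b, ref, objective_spec(), grid)
  set.seed(4)
  t0 <- seq(0, 2, length.out = 75)
  X <- apply(fx$trajectory$X, 1, function(y) approx(t0, y, grid$times)$y)
  U <- apply(fx$trajectory$U, 1, function(y) approx(t0, y, grid$times)$y)
  z <- prob$pack(t(X), t(U)) + rnorm(prob$n_z, 0, 1e-3)
  z <- pmin(pmax(z, prob$lower), prob$upper)
  ## keep activations strictly interior: the effort residual has a designed
  ## kink at a = 0 that finite differences would straddle
  s0 <- prob$unpack(z)
  s0$X[b$layout$idx_a, ] <- pmax(s0$X[b$layout$idx_a, ], 0.02)
  s0$U <- pmin(pmax(s0$U, 0.02), 0.98)
  z <- prob$pack(s0$X, s0$U)
  df <- skiturn:::nlp_defects(prob, z)
  ## dense one-variable-at-a-time central differences, independent of the
  ## batched perturbation path
  J_dense <- matrix(0, prob$n_c, prob$n_z)
  hh <- 1e-6
  for (j in seq_len(prob$n_z)) {
    zp <- z; zp[j] <- zp[j] + hh
    zm <- z; zm[j] <- zm[j] - hh
    J_dense[, j] <- (skiturn:::nlp_defects(prob, zp, jacobian = FALSE)$c -
                       skiturn:::nlp_defects(prob, zm, jacobian = FALSE)$c) / (2 * hh)
  }
  expect_lt(max(abs(as.matrix(df$J) - J_dense)) / max(abs(J_dense)), 1e-3)
  ## objective Jacobian: analytic vs directional finite differences
  ob <- skiturn:::nlp_objective_residual(prob, z)
  for (rep in 1:10) {
    set.seed(rep)
    v <- rnorm(prob$n_z); v <- v / sqrt(sum(v^2))
    rp <- skiturn:::nlp_objective_residual(prob, z + hh * v, jacobian = FALSE)$r
    rm <- skiturn:::nlp_objective_residual(prob, z - hh * v, jacobian = FALSE)$r
    expect_lt(max(abs((rp - rm) / (2 * hh) - as.numeric(ob$J %*% v))), 1e-4)
  }
})

test_that("initial guesses respect the bounds and the schuss stays straight", {
  sol75 <- nominal_tracking()
  prob <- sol75$prob
  g <- make_initial_guess("schuss", prob)
  b <- planar_bundle()
  expect_true(all(g$U >= 0 & g$U <= 1))
  expect_true(all(g$X >= b$bounds$x_lower - 1e-12 &
                    g$X <= b$bounds$x_upper + 1e-12))
  ## straight glide: joint angles drift by only a few degrees over the grid
  L <- b$layout
  cn <- b$model$coord_names
  for (cc in c("hip_r", "knee_r", "ankle_r")) {
    i <- L$idx_q[match(cc, cn)]
    expect_lt(diff(range(g$X[i, ])), deg2rad(8))
  }
})

test_that("pd-tracking guess recovers the primary-muscle activations", {
  sol75 <- nominal_tracking()
  prob <- sol75$prob
  g <- make_initial_guess("pd_tracking", prob)
  expect_true(all(g$U >= 0 & g$U <= 1))
  fx <- turn_fixture(75)
  b <- planar_bundle()
  L <- b$layout
  nm <- b$muscles$names
  for (m in c("vasti_r", "glutmax_r")) {
    i <- match(m, nm)
    r <- cor(g$X[L$idx_a[i], ], fx$truth_a[i, ])
    expect_gt(r, 0.7)
  }
})

test_that("nominal tracking solve is feasible and tracks the reference", {
  sol75 <- nominal_tracking()
  sol <- sol75$sol
  expect_equal(sol$status, "solved")
  expect_lt(sol$constraint_violation, 1e-6)
  ## solution defects re-evaluated outside the NLP against system_residual
  b <- planar_bundle()
  D <- discretize_dynamics(sol$X, sol$U, sol75$grid, b)
  expect_lt(max(abs(D)), 1e-5)
  ## excitation bounds hold
  expect_true(all(sol$U >= -1e-12 & sol$U <= 1 + 1e-12))
  rms <- angle_rmsd(sol, sol75$ref, b)
  expect_lt(max(rms), 2.5)
})

test_that("w2 sweep trades tracking against effort monotonically", {
  sw <- w2_sweep_data()
  expect_true(all(sw$status == "solved"))
  expect_true(all(diff(sw$track) > -1e-8))
  expect_true(all(diff(sw$effort) < 1e-8))
})

test_that("zero-weight degeneracies behave as expected", {
  b <- planar_bundle()
  L <- b$layout
  fx <- turn_fixture(75)
  grid <- collocation_grid(75, 2)
  ref <- reference_data(fx, grid)
  ## w1 = 0: nothing to track, activations fall toward the lower bound
  prob <- assemble_nlp(b, ref, objective_spec(w1 = 0, w2 = 10), grid)
  g <- list(X = fx$trajectory$X, U = fx$trajectory$U)
  sol <- solve_tracking(prob, g, control = list(max_iter = 80))
  ## a local solver heads toward the all-slack minimum; expect a clear drop
  expect_lt(mean(sol$X[L$idx_a, ]), 0.5 * mean(fx$trajectory$X[L$idx_a, ]))

  ## w2 = w3 = 0 with a feasible reference: tracking part driven to ~0
  prob2 <- assemble_nlp(b, ref, objective_spec(w2 = 0, w3 = 0), grid)
  sol2 <- solve_tracking(prob2, g, control = list(max_iter = 10))
  expect_lt(sol2$parts$tracking, 1e-6)
})

test_that("sensitivity suite bookkeeping: one row per variant", {
  b <- planar_bundle()
  fx <- turn_fixture(75)
  tab <- sensitivity_suite(b, fx, p_values = 2, w2_values = c(5, 10),
                           mesh_values = 13, guesses = "schuss",
                           control = list(max_iter = 25))
  expect_equal(nrow(tab), 2L)
  expect_false(any(duplicated(tab[, c("mesh", "guess", "p", "w2")])))
  expect_true(all(c("peak_activation", "peak_acl_N", "max_rmsd_deg")
                  %in% names(tab)))
})
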
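nominal_ski <- function() build_ski(yaml::read_yaml(ski_extdata("ski_nominal.yaml")))

test_that("ski chain: segment counts, mass, camber equilibrium", {
  ski <- nominal_ski()
  expect_equal(ski$n_segments, 18L)
  expect_length(ski$theta_camber, 17L)
  expect_equal(ski$total_mass, sum(ski$seg_mass))
  ## unloaded equilibrium: passive joint moments vanish at the camber shape
  expect_equal(ski$joint_moment(ski$theta_camber, rep(0, 17)), rep(0, 17))
  ## zero camber: straight ski is the equilibrium
  flat <- build_ski(list(n_segments = 5, length = 1.5, mass = 3, width = 0.07,
                         camber_height = 0, stiffness = 300, damping = 0.5,
                         side_cut_radius = 18))
  expect_equal(flat$theta_camber, rep(0, 4))
  expect_error(build_ski(list(n_segments = 1, length = 1, mass = 1,
                              width = 0.07, stiffness = 1, damping = 0,
                              side_cut_radius = 18)),
               class = "skiturn_validation_error")
})

test_that("tip load on a 3-segment ski matches the 2-spring torque balance", {
  ski <- build_ski(list(n_segments = 3, length = 1.5, mass = 3, width = 0.07,
                        camber_height = 0, stiffness = 400, damping = 0,
                        side_cut_radius = 18))
  F <- 20
  theta <- ski_static_deflection(ski, F)
  ## independent closed-form small-and-finite-angle balance solved by
  ## fixed-point on the 2-joint geometry
  L <- 0.5
  th <- c(0, 0)
  for (i in 1:500) {
    phi1 <- th[1]; phi2 <- th[1] + th[2]
    j1 <- c(L * cos(0), L * sin(0))
    j2 <- j1 + L * c(cos(phi1), sin(phi1))
    tip <- j2 + L * c(cos(phi2), sin(phi2))
    dirF <- F * c(-sin(phi2), cos(phi2))
    t1 <- (tip - j1)[1] * dirF[2] - (tip - j1)[2] * dirF[1]
    t2 <- (tip - j2)[1] * dirF[2] - (tip - j2)[2] * dirF[1]
    th <- 0.5 * th + 0.5 * c(t1, t2) / 400
  }
  expect_equal(theta, th, tolerance = 1e-8)
  expect_true(all(theta > 0))
})

test_that("side-cut sagitta matches the circular-segment formula", {
  ski <- nominal_ski()
  half <- 1.7 / 2
  ## at mid-ski the edge sits one full sagitta inboard of the contact line
  sag <- 18 - sqrt(18^2 - half^2)
  expect_equal(side_cut_offset(0, ski) - side_cut_offset(half, ski), -sag,
               tolerance = 1e-12)
  expect_equal(side_cut_offset(half, ski), 0, tolerance = 1e-12)
})

test_that("edging angle and contact depth follow the definitions", {
  surf <- make_snow_surface(0)
  ski <- nominal_ski()
  base <- list(R = diag(3), p = c(0, 0, 0))
  vel <- list(v = c(0, 0, 0), w = c(0, 0, 0))
  kin <- edge_contact_kinematics(base, vel, surf, ski)
  expect_equal(kin$edging_angle, 0)
  expect_equal(kin$depth, 0, tolerance = 1e-9)
  rolled <- list(R = rot_x(deg2rad(30)), p = c(0, 0, 0.05))
  kin30 <- edge_contact_kinematics(rolled, vel, surf, ski)
  expect_equal(kin30$edging_angle, deg2rad(30), tolerance = 1e-9)
})

test_that("hypoplastic law: virgin loading, unload/reload branch, hysteresis", {
  surf <- make_snow_surface(12.3)
  hd <- surf$hardness
  mk <- function(d, rate = 0) list(depth = d, rate = rate, edging_angle = 0)
  ## no contact
  out0 <- penetration_force(mk(0), list(max_depth = 0), surf)
  expect_equal(out0$force, 0)
  expect_equal(out0$state$max_depth, 0)

  ## monotone virgin ramp: force nondecreasing, memory tracks depth
  st <- list(max_depth = 0)
  depths <- seq(0, 0.02, length.out = 50)
  f_prev <- -1
  for (d in depths) {
    o <- penetration_force(mk(d), st, surf)
    expect_gte(o$force, f_prev)
    expect_equal(o$state$max_depth, d)
    f_prev <- o$force
    st <- o$state
  }

  ## load to d*, unload to d*/2, reload: branch force below virgin, rejoin
  dstar <- 0.02
  st <- list(max_depth = dstar)
  virgin_half <- hd$k_load * dstar / 2
  o_half <- penetration_force(mk(dstar / 2), st, surf)
  branch_half <- max(hd$k_load * dstar +
                       hd$unload_ratio * hd$k_load * (dstar / 2 - dstar), 0)
  expect_equal(o_half$force, branch_half)
  expect_lt(o_half$force, virgin_half)
  expect_equal(o_half$state$max_depth, dstar)   # memory persists
  o_re <- penetration_force(mk(dstar), st, surf)
  expect_equal(o_re$force, hd$k_load * dstar)   # rejoins the virgin curve

  ## closed depth cycle: work done on the snow is nonnegative
  cyc <- c(seq(0, dstar, length.out = 40), seq(dstar, 0, length.out = 40))
  st <- list(max_depth = 0)
  W <- 0
  f_prev <- 0; d_prev <- 0
  for (d in cyc) {
    o <- penetration_force(mk(d), st, surf)
    W <- W + 0.5 * (o$force + f_prev) * (d - d_prev)
    f_prev <- o$force; d_prev <- d; st <- o$state
  }
  expect_gt(W, 0)
})

test_that("shear force is depth-proportional and orthogonal to the edge", {
  surf <- make_snow_surface(12.3)
  set.seed(5)
  for (rep in 1:10) {
    e <- rnorm(3); e <- e / sqrt(sum(e^2))
    nrm <- rnorm(3); nrm <- nrm - sum(nrm * e) * e
    nrm <- nrm / sqrt(sum(nrm^2))
    v <- rnorm(3, 0, 3)
    kin <- list(depth = runif(1, 0.001, 0.03), edge_direction = e,
                normal = nrm, velocity = v)
    f1 <- shear_force(kin, 6e4)
    expect_lt(abs(sum(f1 * e)), 1e-12 * max(sqrt(sum(f1^2)), 1))
    kin2 <- kin; kin2$depth <- 2 * kin$depth
    f2 <- shear_force(kin2, 6e4)
    expect_equal(sqrt(sum(f2^2)), 2 * sqrt(sum(f1^2)), tolerance = 1e-9)
  }
  expect_equal(shear_force(list(depth = 0), 6e4), c(0, 0, 0))
})

test_that("Coulomb friction: closed form, regularization, dissipativity", {
  f <- friction_force(1000, c(10, 0, 0), mu = 0.08)
  expect_equal(f, c(-80, 0, 0), tolerance = 1e-4)
  expect_equal(friction_force(1000, c(0, 0, 0)), c(0, 0, 0))
  set.seed(6)
  for (rep in 1:20) {
    v <- rnorm(3, 0, 5)
    f <- friction_force(runif(1, 0, 2000), v, 0.08)
    expect_lte(sum(f * v), 0)
  }
})

test_that("air drag: closed form and quadratic speed scaling", {
  f <- air_drag(c(12, 0, 0))
  expect_equal(sqrt(sum(f^2)), 0.5 * 1.07 * 0.3 * 144, tolerance = 1e-12)
  expect_equal(air_drag(c(0, 0, 0)), c(0, 0, 0))
  f2 <- air_drag(c(24, 0, 0))
  expect_equal(sqrt(sum(f2^2)) / sqrt(sum(f^2)), 4, tolerance = 1e-12)
})

test_that("contact forces vanish identically on an airborne ski", {
  b <- planar_bundle()
  L <- b$layout
  x <- bundle_initial_state(b, c(pelvis_tz = 8, knee_r = 1.2, knee_l = 1.2),
                            a0 = 0.1)
  xd <- numeric(L$n_x); xd[L$idx_q] <- x[L$idx_qd]
  out <- planar_residual(b, matrix(x), matrix(xd),
                         matrix(0.1, L$n_u, 1), forces = TRUE)
  expect_equal(max(abs(out$contact_force)), 0)
})

test_that("passive ski chain conserves energy in free oscillation", {
  ## soft springs so the oscillation is slow relative to the step: the
  ## first-order integrator's numerical dissipation then stays at the
  ## percent level and shrinks linearly with the step
  ski <- build_ski(list(n_segments = 4, length = 1.6, mass = 3.2, width = 0.07,
                        camber_height = 0.004, stiffness = 10, damping = 0,
                        side_cut_radius = 18))
  mdl <- ski_chain_model(ski, damping = 0)
  b <- ski_bundle(mdl, NULL, aero = list(CdA = 0, rho = 1, wind = c(0, 0, 0)))
  L <- b$layout
  x0 <- numeric(L$n_x)
  ## smooth arc deflection: excites the slow bending mode, where the
  ## integrator's numerical dissipation is smallest
  x0[L$idx_q] <- c(0, 8, 0.2, 0.25, 0.2, 0.25)
  energy <- function(tr, k) {
    q <- tr$X[L$idx_q, k]; qd <- tr$X[L$idx_qd, k]
    KE <- 0.5 * sum(diag(mass_matrix(b$compressed, q) %*% (qd %o% qd)))
    fkc <- center_of_mass(b$compressed, q)
    PE <- b$compressed$total_mass * 9.81 * fkc$com[3]
    EL <- 0
    for (j in 1:3)
      EL <- EL + 0.5 * ski$stiffness[j] *
        (q[3 + j] - (-ski$theta_camber[j]))^2
    KE + PE + EL
  }
  ## elastic + bending-oscillation energy scale of this initial condition
  E_osc <- sum(0.5 * ski$stiffness * (x0[L$idx_q][4:6] + ski$theta_camber)^2)
  drift <- sapply(c(2e-4, 1e-4), function(hh) {
    tr <- forward_simulate(b, x0, numeric(0), T = 0.5, dt = hh)
    abs(energy(tr, ncol(tr$X)) - energy(tr, 1))
  })
  expect_lt(drift[2] / E_osc, 0.06)
  ## first-order integrator: halving dt roughly halves the drift
  expect_lt(drift[2], 0.75 * drift[1])
})
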
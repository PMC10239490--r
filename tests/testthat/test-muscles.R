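spec1 <- list(name = "m", f_max = 1000, l_opt = 0.1, l_slack = 0.2,
              pennation_opt = 0, tau_act = 0.015, tau_deact = 0.06)

test_that("activation dynamics: steady state, rise, monotone approach", {
  expect_equal(activation_residual(0.4, 0, 0.4, spec1), 0)
  ## residual==0 at a=0,u=1 demands a positive rate
  adot <- (1 - 0) * (1 / spec1$tau_act + 0)
  expect_equal(activation_residual(0, adot, 1, spec1), 0)
  expect_gt(adot, 0)

  ## step response u: 0 -> 1 via an independent fine-step ODE integration of
  ## the same residual (deSolve); a reaches 0.95 within 3 tau_act and the
  ## approach to u is monotone
  rate <- function(t, y, parms) {
    list((1 - y) * (1 / spec1$tau_act + 0))
  }
  out <- deSolve::ode(y = 0, times = seq(0, 3 * spec1$tau_act, length.out = 200),
                      func = rate, parms = NULL)
  expect_gte(out[nrow(out), 2], 0.95)
  expect_true(all(diff(out[, 2]) > 0))
  ## deactivation is slower: from a=1 with u=0
  rate0 <- function(t, y, parms) list((0 - y) * (0 + 1 / spec1$tau_deact))
  out0 <- deSolve::ode(y = 1, times = seq(0, 3 * spec1$tau_act, length.out = 50),
                       func = rate0, parms = NULL)
  expect_gt(out0[nrow(out0), 2], 1 - 0.95)   # still far from 0
})

test_that("contraction residual: isometric normalization and passive limit", {
  ## a=1, fiber at l_opt (pennation 0 -> s = l_opt), tendon elongated to the
  ## strain where its force equals f_max
  e0 <- 0.04
  l_mt <- spec1$l_opt + spec1$l_slack * (1 + e0)
  cr <- contraction_residual(list(s = spec1$l_opt, a = 1), 0, l_mt, spec1)
  expect_equal(cr$residual, 0, tolerance = 1e-12)
  expect_equal(cr$f_tendon, spec1$f_max)

  ## a=0, fiber below l_opt (passive element zero): the tendon force follows
  ## from its elongation alone, and the fiber-side force is zero
  s <- 0.95 * spec1$l_opt
  eps <- 0.02
  cr2 <- contraction_residual(list(s = s, a = 0), 0,
                              s + spec1$l_slack * (1 + eps), spec1)
  expect_equal(cr2$f_tendon, spec1$f_max * (eps / e0)^2)
  expect_equal(cr2$residual, (eps / e0)^2, tolerance = 1e-12)
})

test_that("force-velocity: concentric below and eccentric above isometric", {
  ## direct curve evaluation oracle
  fv <- function(v) {
    if (v < 0) (1 + v) / (1 - v / 0.25) else 1.5 - 0.5 / (1 + 10 * v)
  }
  e0 <- 0.04
  for (vt in c(-0.5, -0.2, 0.2, 0.5)) {
    sdot <- vt * 10 * spec1$l_opt
    ## choose the tendon strain so the residual vanishes given fV(vt)
    f_target <- fv(vt)
    eps <- if (f_target <= 1) e0 * sqrt(f_target) else
      e0 * (1 + (f_target - 1) * e0 / (2 * e0))
    l_mt <- spec1$l_opt + spec1$l_slack * (1 + eps)
    cr <- contraction_residual(list(s = spec1$l_opt, a = 1), sdot, l_mt, spec1)
    f_exp <- f_target + 0.01 * vt      # fiber damping term
    expect_equal(cr$f_tendon / spec1$f_max, f_target, tolerance = 1e-10)
    if (vt < 0) expect_lt(cr$f_tendon / spec1$f_max, 1)
    else expect_gt(cr$f_tendon / spec1$f_max, 1)
    ## residual equals tendon-minus-fiber mismatch computed independently
    expect_equal(cr$residual,
                 cr$f_tendon / spec1$f_max - f_exp, tolerance = 1e-12)
  }
})

test_that("tendon force is continuous and nonnegative on a random sweep", {
  set.seed(11)
  s <- runif(500, 0.03, 0.19)
  a <- runif(500)
  sdot <- rnorm(500, 0, 0.5)
  l_mt <- runif(500, 0.22, 0.34)
  cr <- contraction_residual(list(s = s, a = a), sdot, l_mt, spec1)
  expect_true(all(cr$f_tendon >= 0))
  ## continuity probe across the tendon toe/linear junction
  eps <- seq(0.0399, 0.0401, length.out = 101)
  f <- contraction_residual(list(s = rep(spec1$l_opt, 101), a = 1), 0,
                            spec1$l_opt + spec1$l_slack * (1 + eps),
                            spec1)$f_tendon
  expect_true(all(abs(diff(f)) < 1))
})

test_that("implicit and explicit contraction integration agree", {
  ## integrate the implicit residual by root-solving each fine step, and the
  ## same dynamics by an explicit stiff ODE solve of sdot(s); states agree
  ## within 1 percent over 1 s
  l_mt_fun <- function(t) 0.305 + 0.01 * sin(2 * pi * t)
  u <- 0.6
  sdot_of <- function(t, s, a) {
    r <- function(sd) contraction_residual(list(s = s, a = a), sd,
                                           l_mt_fun(t), spec1)$residual
    stats::uniroot(r, c(-100, 100), tol = 1e-12)$root
  }
  rate <- function(t, y, parms) {
    adot <- (u - y[2]) * (u / spec1$tau_act + (1 - u) / spec1$tau_deact)
    list(c(sdot_of(t, y[1], y[2]), adot))
  }
  ## start at the isometric equilibrium of the initial activation
  s0 <- stats::uniroot(function(s)
    contraction_residual(list(s = s, a = 0.1), 0, l_mt_fun(0),
                         spec1)$residual, c(0.02, 0.18), tol = 1e-12)$root
  y0 <- c(s0, 0.1)
  ode <- deSolve::ode(y = y0, times = seq(0, 1, by = 0.01), func = rate,
                      parms = NULL, method = "bdf")
  ## implicit path: backward-Euler root solve of the full residual pair
  h <- 0.001
  y <- y0
  for (k in seq_len(1000)) {
    t1 <- k * h
    f <- function(x, xd, uu) c(
      contraction_residual(list(s = x[1], a = x[2]), xd[1], l_mt_fun(t1),
                           spec1)$residual,
      activation_residual(x[2], xd[2], uu, spec1))
    y <- implicit_euler_root(f, y, u, h)
  }
  expect_equal(y[1], ode[nrow(ode), 2], tolerance = 0.01, ignore_attr = TRUE)
  expect_equal(y[2], ode[nrow(ode), 3], tolerance = 0.01, ignore_attr = TRUE)
})

test_that("moment arms equal minus the length gradient", {
  mset <- planar_bundle()$muscles
  mp <- build_skier_model("reduced_planar")
  for (rep in 1:5) {
    q <- random_q(mp, seed = rep)
    for (i in c(1, 3, 4, 6)) {   # includes biarticular muscles
      sp <- muscle_spec(mset, i)
      g <- muscle_tendon_length_and_moment_arms(q, sp)
      for (cc in sp$coords) {
        h <- 1e-6
        qp <- q; qp[cc] <- qp[cc] + h
        qm <- q; qm[cc] <- qm[cc] - h
        fd <- -(muscle_tendon_length_and_moment_arms(qp, sp)$l_mt -
                  muscle_tendon_length_and_moment_arms(qm, sp)$l_mt) / (2 * h)
        expect_equal(unname(g$moment_arms[cc]), fd, tolerance = 1e-6)
      }
    }
  }
  ## constant-arm muscle: l_mt linear with slope -r
  sp <- muscle_spec(mset, "vasti_r")
  q0 <- random_q(mp, seed = 9); q1 <- q0; q1["knee_r"] <- q0[["knee_r"]] + 0.3
  dl <- muscle_tendon_length_and_moment_arms(q1, sp)$l_mt -
    muscle_tendon_length_and_moment_arms(q0, sp)$l_mt
  expect_equal(dl, -(-0.045) * 0.3, tolerance = 1e-12)
  ## unspanned coordinate query
  expect_error(muscle_tendon_length_and_moment_arms(q0[1:2], sp),
               class = "skiturn_validation_error")
})

test_that("joint moments from muscles follow the transpose mapping", {
  arms <- matrix(c(0.05, -0.05), 2, 1)
  expect_equal(joint_moments_from_muscles(c(100, 0), arms), 5)
  expect_equal(joint_moments_from_muscles(c(0, 0), arms), 0)
  expect_equal(joint_moments_from_muscles(c(80, 80), arms), 0)
  expect_error(joint_moments_from_muscles(c(1, 2, 3), arms),
               class = "skiturn_validation_error")
})

test_that("higher effort exponents balance synergists", {
  ## two synergists with unequal strength sharing one moment: the activation
  ## ratio approaches 1 as the exponent grows
  tab <- data.frame(
    name = c("strong", "weak"), f_max = c(3000, 1200),
    l_opt = 0.1, l_slack = 0.0, pennation_opt = 0,
    tau_act = 0.015, tau_deact = 0.06,
    coords = "knee_r", arms = "-0.04", l_ref = 0.1)
  mset <- read_muscle_table(tab)
  q <- c(knee_r = 0)
  tau <- c(knee_r = -60)
  ratio <- sapply(c(2, 5), function(p) {
    a <- muscle_redundancy_solve(mset, q, tau, p = p)$a
    max(a) / min(a)
  })
  expect_lt(ratio[2], ratio[1])
  expect_gt(ratio[1], 1.2)
})
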
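## Synthetic study conditions: course geometry, a dynamically consistent
## reference turning motion generated by forward simulation under a
## reflex-style excitation schedule, measurement noise, and synthetic EMG
## envelopes.  These generators stand in for the original field experiment
## (video-based kinematics and surface EMG of one skier), which is not
## redistributable; every fixture is regenerable from (configuration, seed).

#' Generate the course geometry
#'
#' Inclined-plane snow surface with the gates on the stated offset lattice
#' (defaults: slope 12.3 degrees, gate displacement 8 m transverse and 16 m
#' downhill, 4 turns).
#'
#' @param spec List: \code{slope_angle_deg}, \code{gate_dx} (downhill offset,
#'   m), \code{gate_dy} (transverse offset, m), \code{n_turns}.
#' @return List with \code{surf} (a \code{snow_surface}) and \code{gates}
#'   (matrix x, y, z).
#' @export
generate_course <- function(spec = list()) {
  sp <- utils::modifyList(list(slope_angle_deg = 12.3, gate_dx = 16,
                               gate_dy = 8, n_turns = 4), spec)
  assert_that(sp$gate_dx > 0 && sp$gate_dy > 0, "gate offsets must be > 0")
  surf <- make_snow_surface(sp$slope_angle_deg)
  x <- sp$gate_dx * seq_len(sp$n_turns)
  y <- sp$gate_dy / 2 * (-1)^(seq_len(sp$n_turns))
  gates <- cbind(x = x, y = y, z = surf$height(x, y))
  list(surf = surf, gates = gates, spec = sp)
}

## reflex gains shared by the fixture generator and the initial guesses:
## low enough that the one-step feedback delay does not excite
## agonist-antagonist chatter (which would put unrecoverable co-contraction
## into the ground-truth excitations)
reflex_gains <- function() {
  list(kp = list(hip_r = 250, hip_l = 250, knee_r = 250, knee_l = 250,
                 ankle_r = 40, ankle_l = 40),
       kd = list(hip_r = 25, hip_l = 25, knee_r = 25, knee_l = 25,
                 ankle_r = 8, ankle_l = 8),
       kp_pitch = 150, kd_pitch = 35)
}

## reflex-style excitation controller: feedforward tonic levels + loading
## bumps, plus proportional-derivative joint-moment corrections distributed
## over the muscles by moment-arm direction.  Returns u(t, x) in [0, 1].
excitation_controller <- function(bundle, targets, gains, bumps = NULL) {
  L <- bundle$layout; st <- bundle$planar
  cn <- bundle$model$coord_names
  nm <- bundle$muscles$names
  tb <- bundle$muscles$table
  pitch_i <- grep("_pitch$", cn)
  function(t, x) {
    q <- x[L$idx_q]; qd <- x[L$idx_qd]
    tg <- targets(t)
    dM <- numeric(L$n_q)
    for (c in names(gains$kp)) {
      ci <- match(c, cn)
      ref <- if (c %in% names(tg)) tg[[c]] else 0
      dM[ci] <- gains$kp[[c]] * (ref - q[ci]) - gains$kd[[c]] * qd[ci]
    }
    ## trunk-pitch balance through an ankle strategy
    if (!is.null(gains$kp_pitch) && length(pitch_i)) {
      mp <- gains$kp_pitch * ((tg[["pelvis_pitch"]] %||% 0) - q[pitch_i]) -
        gains$kd_pitch * qd[pitch_i]
      for (c in grep("^ankle", cn, value = TRUE))
        dM[match(c, cn)] <- dM[match(c, cn)] + mp
    }
    u <- numeric(L$n_m)
    for (m in seq_len(L$n_m)) {
      qi <- st$mus_q[[m]]
      du <- 0
      for (j in seq_along(qi)) {
        arm <- arm_poly_eval(st$mus_arms[[m]][[j]], q[qi[j]])
        if (abs(arm) < 1e-6) next
        ## activation equivalent of the requested moment share (0.7 ~ typical
        ## force-length * pennation factor at the working posture)
        du <- du + sign(arm) * dM[qi[j]] / (tb$f_max[m] * abs(arm) * 0.7)
      }
      u[m] <- du
    }
    u <- u + (tg$u_ff %||% 0) + (tg$tonic %||% 0)
    if (!is.null(bumps)) u <- u + bumps(t)
    pmin(pmax(u, 0), 1)
  }
}

#' Generate a synthetic single-turn reference fixture
#'
#' Forward-simulates the reduced skier through a schuss entry followed by a
#' turn-style loading cycle (deepening knee and hip flexion with extra
#' loading of the outside-leg extensors, then unloading), records the
#' realized excitations and the tracked channels on the collocation mesh,
#' and verifies dynamic consistency against the system residual.  Outside-
#' leg knee flexion stays above 60 degrees throughout the steering phase,
#' matching the deeply flexed carved-turn regime.
#'
#' @param bundle A planar \code{ski_bundle}.
#' @param course Output of \code{\link{generate_course}} (its surface must
#'   match the bundle's).
#' @param template Optional overrides of the excitation-schedule parameters:
#'   \code{flex_depth} (rad of extra knee/hip flexion at mid-turn),
#'   \code{bump_peak} (extra outside-extensor excitation), \code{t_load},
#'   \code{t_unload} (s).
#' @param seed Integer seed recorded in the fixture.
#' @param n_mesh Number of mesh nodes for the recorded channels (75).
#' @param T Fixture duration, s (2).
#' @param speed Entry speed, m/s (12).
#' @return A \code{reference_fixture}: \code{trajectory}, \code{channels}
#'   (tracked-channel matrix, angles rad), \code{truth_u}, \code{truth_a},
#'   \code{seed}, \code{defect_max}.
#' @export
generate_reference_turn <- function(bundle, course = generate_course(),
                                    template = list(), seed = 1L,
                                    n_mesh = 75, T = 2, speed = 12) {
  set.seed(seed)
  tp <- utils::modifyList(list(flex_depth = 0.22, bump_peak = 0.18,
                               t_load = 0.55, t_unload = 1.55,
                               settle = 1.0), template)
  alpha <- bundle$surf$slope_angle
  posture <- c(pelvis_pitch = 0.40, hip_r = 1.10, hip_l = 1.10,
               knee_r = 1.20, knee_l = 1.20, ankle_r = 0.285, ankle_l = 0.285)
  gains <- reflex_gains()
  ff <- static_feedforward(bundle, posture, speed, trim = FALSE)
  hold <- function(t) c(as.list(posture), list(u_ff = ff$u_ff, tonic = 0.01))
  ctrl_hold <- excitation_controller(bundle, hold, gains)
  x0 <- bundle_initial_state(bundle,
          c(posture, pelvis_tz = ff$tz),
          qd = c(pelvis_tx = speed * cos(alpha), pelvis_tz = -speed * sin(alpha)),
          a0 = pmax(ff$u_ff, 0.02))
  h <- T / (n_mesh - 1)
  ## settle into a quasi-steady schuss before the recorded window, then
  ## re-anchor the posture targets at the settled equilibrium (removes the
  ## steady-state PD demand) and settle again briefly
  xs <- simulate_closed_loop(bundle, x0, ctrl_hold, T = tp$settle, dt = h)
  x_start <- xs$X[, ncol(xs$X)]
  qset <- stats::setNames(x_start[bundle$layout$idx_q], bundle$model$coord_names)
  posture <- qset[names(posture)]
  ## re-estimate the feedforward from the *measured* dynamic joint moments
  ## of the settled glide (the static estimate over-states the hip demand,
  ## which would bake minimum-effort-inconsistent co-contraction into the
  ## ground truth), then settle again on the corrected feedforward
  tau_dyn <- measured_required_moments(bundle, xs)
  u_ff <- muscle_redundancy_solve(bundle$muscles, qset, tau_dyn, p = 2)$a
  hold <- function(t) c(as.list(posture), list(u_ff = u_ff, tonic = 0.01))
  ctrl_hold <- excitation_controller(bundle, hold, gains)
  xs <- simulate_closed_loop(bundle, x_start, ctrl_hold, T = tp$settle / 2, dt = h)
  x_start <- xs$X[, ncol(xs$X)]
  qset <- stats::setNames(x_start[bundle$layout$idx_q], bundle$model$coord_names)
  posture <- qset[names(posture)]

  ## turn phase: deepen flexion between t_load and t_unload, with extra
  ## excitation bumps on the outside-leg (right) hip/knee extensors
  bump <- function(t) {
    s <- bump_shape(t, tp$t_load, tp$t_unload)
    u <- numeric(bundle$layout$n_m)
    nm <- bundle$muscles$names
    u[grep("vasti_r|glutmax_r", nm)] <- tp$bump_peak * s
    u[grep("hamstrings_r", nm)] <- 0.4 * tp$bump_peak * s
    u[grep("vasti_l|glutmax_l", nm)] <- 0.45 * tp$bump_peak * s
    u
  }
  turn_targets <- function(t) {
    s <- bump_shape(t, tp$t_load, tp$t_unload)
    tg <- as.list(posture + tp$flex_depth * s *
                    c(pelvis_pitch = 0.5, hip_r = 1, hip_l = 1,
                      knee_r = 1, knee_l = 1, ankle_r = 0.25, ankle_l = 0.25))
    tg$u_ff <- u_ff
    tg$tonic <- 0.01
    tg
  }
  ctrl_turn <- excitation_controller(bundle, turn_targets, gains, bump)
  sim <- simulate_closed_loop(bundle, x_start, ctrl_turn, T = T, dt = h)

  L <- bundle$layout
  ## dynamic-consistency check of the recorded mesh trajectory
  defect_max <- max_defect(bundle, sim)
  ch <- tracked_channels(bundle, sim)
  if (min(sim$X[L$idx_q[match("knee_r", bundle$model$coord_names)],
                bump_shape(sim$time, tp$t_load, tp$t_unload) > 0.5]) < deg2rad(60))
    warning("outside-leg knee flexion dropped below 60 deg in the steering phase")
  ## fall detection: pelvis clearance above the slope surface
  clearance <- sim$X[L$idx_q[2], ] -
    bundle$surf$height(sim$X[L$idx_q[1], ], 0)
  if (min(clearance) < 0.35)
    ski_stop("fixture generation unstable: pelvis height collapsed",
             "skiturn_generation_error")
  structure(list(trajectory = sim, channels = ch$channels,
                 channel_names = ch$names, angle_channels = ch$is_angle,
                 truth_u = sim$U, truth_a = sim$X[L$idx_a, , drop = FALSE],
                 seed = seed, template = tp, defect_max = defect_max,
                 n_mesh = n_mesh, T = T),
            class = "reference_fixture")
}

#' @export
print.reference_fixture <- function(x, ...) {
  cat(sprintf("<reference_fixture>: %d nodes, T = %.2f s, max defect %.2e, seed %d\n",
              x$n_mesh, x$T, x$defect_max, x$seed))
  invisible(x)
}

## smooth loading bump in [0, 1] between t0 and t1 (cosine ramps)
bump_shape <- function(t, t0, t1, ramp = 0.35) {
  up <- pmin(pmax((t - t0) / ramp, 0), 1)
  dn <- pmin(pmax((t1 - t) / ramp, 0), 1)
  (0.5 - 0.5 * cos(pi * up)) * (0.5 - 0.5 * cos(pi * dn))
}

## static feedforward: required joint moments at the posture (muscles
## removed, weight carried by the contact at the equilibrium height), solved
## into activations by the muscle-redundancy criterion
static_feedforward <- function(bundle, posture, speed = 12, p = 2,
                               trim = TRUE) {
  alpha <- bundle$surf$slope_angle
  bq <- ski_bundle(bundle$model, NULL, bundle$surf, bundle$ski, bundle$aero)
  cn <- bundle$model$coord_names
  ## generalized-force balance of the gliding skier: the root translations
  ## (tx, tz) accelerate freely down the slope; the pitch row and the joint
  ## rows are the moments the posture / the muscles must supply
  rho_at <- function(pst) {
    tz <- equilibrium_height(bq, pst)
    x <- bundle_initial_state(bq, c(pst, pelvis_tz = tz),
           qd = c(pelvis_tx = speed * cos(alpha),
                  pelvis_tz = -speed * sin(alpha)))
    xd <- numeric(bq$layout$n_x)
    xd[bq$layout$idx_q] <- x[bq$layout$idx_qd]
    rho0 <- system_residual(x, xd, numeric(0), bq)[bq$layout$idx_qd] /
      bq$scales[bq$layout$idx_qd]
    M <- mass_matrix(bq$compressed, x[bq$layout$idx_q])
    ti <- grep("_tx$|_tz$", cn)
    a_free <- solve(M[ti, ti], -rho0[ti])
    rho <- rho0 + as.numeric(M[, ti] %*% a_free)
    list(rho = rho, tz = tz, x = x)
  }
  ## fore-aft trim: shift the feet under the body (hip flexion + compensating
  ## ankle so the ski stays flat) until the static pitch moment vanishes
  if (trim) {
    hips <- grep("^hip", cn, value = TRUE)
    ankles <- grep("^ankle", cn, value = TRUE)
    pj <- grep("_pitch$|_tilt$", cn)[1]
    f <- function(d) {
      pst <- posture
      pst[hips] <- pst[hips] + d; pst[ankles] <- pst[ankles] - d
      rho_at(pst)$rho[pj]
    }
    d <- tryCatch(stats::uniroot(f, c(-0.25, 0.25), tol = 1e-8)$root,
                  error = function(e) 0)
    posture[hips] <- posture[hips] + d
    posture[ankles] <- posture[ankles] - d
  }
  r <- rho_at(posture)
  ji <- grep("^(hip|knee|ankle)", cn)
  tau <- stats::setNames(r$rho[ji], cn[ji])
  qn <- stats::setNames(r$x[bq$layout$idx_q], cn)
  sol <- muscle_redundancy_solve(bundle$muscles, qn, tau, p = p)
  list(u_ff = sol$a, tau = tau, tz = r$tz, posture = posture)
}

## pelvis height at which the total contact normal force carries the weight
equilibrium_height <- function(bundle, posture) {
  tz0 <- pelvis_height_on_snow(bundle, posture)
  hd <- bundle$surf$hardness
  alpha <- bundle$surf$slope_angle
  W <- bundle$model$total_mass * 9.81
  f <- function(dz) {
    L <- bundle$layout
    q <- stats::setNames(rep(0, L$n_q), bundle$model$coord_names)
    for (nm in names(posture)) q[nm] <- posture[[nm]]
    q[grep("_tz$", bundle$model$coord_names)[1]] <- tz0 + dz
    pc <- planar_contact_geometry(bundle, matrix(q, ncol = 1))
    Nf <- penetration_force_smooth(pc$depth[, 1], 0, pmax(pc$depth[, 1], 0),
                                   0, hd)
    sum(Nf) * (cos(alpha) + hd$mu * sin(alpha)) - W
  }
  dz <- tryCatch(stats::uniroot(f, c(-0.02, 0.02), tol = 1e-10)$root,
                 error = function(e) 0)
  tz0 + dz
}

## required muscle generalized moments measured along a simulated window:
## residual rows of the muscle-free system on the same (q, qd, mem)
## trajectory give the moments the muscles must have supplied
measured_required_moments <- function(bundle, traj, window = NULL,
                                      average = TRUE) {
  bq <- ski_bundle(bundle$model, NULL, bundle$surf, bundle$ski, bundle$aero)
  L <- bundle$layout; Lq <- bq$layout
  N <- ncol(traj$X)
  ks <- if (is.null(window)) seq(max(2, N - 12), N) else window
  h <- traj$dt
  cn <- bundle$model$coord_names
  ji <- grep("^(hip|knee|ankle)", cn)
  acc <- matrix(0, length(ji), length(ks))
  for (w in seq_along(ks)) {
    k <- ks[w]
    x <- numeric(Lq$n_x)
    x[Lq$idx_q] <- traj$X[L$idx_q, k]
    x[Lq$idx_qd] <- traj$X[L$idx_qd, k]
    x[Lq$idx_mem] <- traj$X[L$idx_mem, k]
    xd <- numeric(Lq$n_x)
    xd[Lq$idx_q] <- traj$X[L$idx_qd, k]
    xd[Lq$idx_qd] <- (traj$X[L$idx_qd, k] - traj$X[L$idx_qd, k - 1]) / h
    xd[Lq$idx_mem] <- (traj$X[L$idx_mem, k] - traj$X[L$idx_mem, k - 1]) / h
    rho <- system_residual(x, xd, numeric(0), bq)[Lq$idx_qd] /
      bq$scales[Lq$idx_qd]
    acc[, w] <- rho[ji]
  }
  if (average) return(stats::setNames(rowMeans(acc), cn[ji]))
  rownames(acc) <- cn[ji]
  list(tau = acc, nodes = ks)
}

## pelvis height that puts the skis just at the surface for a posture
pelvis_height_on_snow <- function(bundle, posture) {
  L <- bundle$layout
  q <- stats::setNames(rep(0, L$n_q), bundle$model$coord_names)
  for (nm in names(posture)) q[nm] <- posture[[nm]]
  pc <- planar_contact_geometry(bundle, matrix(q, ncol = 1))
  ## raising the pelvis by dz reduces the depth by dz cos(slope); choose dz
  ## so the deepest point keeps ~1 mm of penetration
  cosa <- cos(bundle$surf$slope_angle)
  (max(pc$depth[, 1]) - 0.001) / cosa
}

## closed-loop implicit-Euler simulation with u = ctrl(t, x_k) held over the
## step (excitations are decided from the last known state, like a reflex
## acting on proprioceptive feedback one step behind)
simulate_closed_loop <- function(bundle, x0, ctrl, T, dt, tol = 1e-8,
                                 u_smooth = 0.35) {
  L <- bundle$layout
  nstep <- round(T / dt)
  time <- seq(0, by = dt, length.out = nstep + 1)
  X <- matrix(0, L$n_x, nstep + 1); X[, 1] <- x0
  U <- matrix(0, L$n_u, nstep + 1)
  U[, 1] <- ctrl(0, x0)
  for (k in seq_len(nstep)) {
    ## one-pole smoothing of the reflex output suppresses step-delay chatter
    uk <- u_smooth * ctrl(time[k + 1], X[, k]) + (1 - u_smooth) * U[, k]
    U[, k + 1] <- uk
    one <- forward_simulate(bundle, X[, k], uk, T = dt, dt = dt, tol = tol)
    X[, k + 1] <- one$X[, 2]
  }
  structure(list(time = time, X = X, U = U, dt = dt, layout = L,
                 bundle_name = bundle$model$name),
            class = "ski_trajectory")
}

## maximum scaled implicit-Euler defect of a mesh trajectory
max_defect <- function(bundle, traj) {
  N <- ncol(traj$X)
  Xn <- traj$X[, -1, drop = FALSE]
  Xd <- (traj$X[, -1, drop = FALSE] - traj$X[, -N, drop = FALSE]) / traj$dt
  R <- planar_residual(bundle, Xn, Xd, traj$U[, -1, drop = FALSE])
  max(abs(R))
}

## tracked channels: all generalized coordinates, flagged angle vs translation
tracked_channels <- function(bundle, traj) {
  cn <- bundle$model$coord_names
  is_angle <- !grepl("_t[xyz]$", cn)
  list(channels = traj$X[bundle$layout$idx_q, , drop = FALSE],
       names = cn, is_angle = is_angle)
}

#' Synthetic carved-turn kinematics and loads for the 3D skier
#'
#' Prescribes a left carved turn of the full 3D skier: the pelvis follows a
#' circular arc in the slope plane at the given speed, inclining into the
#' turn with knee/hip angulation, the outside (right) leg more extended and
#' the inside knee deeper flexed; ground reaction forces are constructed
#' from whole-body force balance (sum of m(a - g) plus drag) and split
#' between the skis (outside share \code{grf_split}).  The fixture is a
#' quasi-consistent stand-in for a measured turn: forces satisfy the
#' whole-body force balance, not the full moment balance, which is
#' sufficient for the distal Newton-Euler knee-load recursion.
#'
#' @param model A \code{skier_model} ("nominal_3d" by default).
#' @param T Duration, s; \code{n} samples; \code{speed} m/s; \code{radius}
#'   turn radius, m.
#' @param grf_split Outside-leg share of the ground reaction force.
#' @return List with \code{traj} (time + Q matrix), \code{external}
#'   (per-sample load lists for \code{\link{intersegmental_loads}}),
#'   \code{bundle}.
#' @export
generate_carved_turn_kinematics <- function(model = build_skier_model("nominal_3d"),
                                            T = 2, n = 75, speed = 12,
                                            radius = 10.7, grf_split = 0.62) {
  bundle <- ski_bundle(model, NULL)
  cmp <- bundle$compressed
  cn <- model$coord_names
  time <- seq(0, T, length.out = n)
  ## the yaw rate follows the steering bump and is integrated into heading
  ## and path, so curvature peaks at 1/radius without ramp-edge
  ## acceleration spikes; inclination follows the centripetal balance angle
  ## (capped), with the remaining alignment taken up by knee angulation
  s <- bump_shape(time, 0.35, 1.65, ramp = 0.6)
  h <- time[2] - time[1]
  yaw_rate <- (speed / radius) * s
  psi <- cumsum(yaw_rate) * h
  psi <- psi - psi[which.max(s)]
  lean <- pmin(atan(speed * yaw_rate / 9.81), 0.65)
  Q <- matrix(0, model$n_q, n, dimnames = list(cn, NULL))
  Q["pelvis_tx", ] <- cumsum(speed * cos(psi)) * h
  Q["pelvis_ty", ] <- cumsum(speed * sin(psi)) * h
  Q["pelvis_tz", ] <- 0.80 - 0.05 * s
  Q["pelvis_tilt", ] <- psi                       # z-rotation (heading)
  Q["pelvis_list", ] <- -lean                     # x-rotation (into the turn)
  Q["pelvis_rot", ] <- 0.35                       # forward pitch (y)
  Q["lumbar_flex", ] <- 0.25
  Q["lumbar_add", ] <- -0.3 * s                   # counter-lean of the trunk
  ## outside (right) leg: more extended; inside leg deeper flexed; the
  ## ab/adduction angulation is solved below so the ground-reaction line
  ## passes at a realistic lever from each knee
  Q["hip_r_flex", ] <- 1.00 + 0.15 * s
  Q["hip_r_rot", ] <- 0.15 * s
  Q["knee_r", ] <- 1.10 + 0.15 * s
  Q["ankle_r", ] <- 0.285
  Q["hip_l_flex", ] <- 1.15 + 0.25 * s
  Q["knee_l", ] <- 1.30 + 0.25 * s
  Q["ankle_l", ] <- 0.30
  ## whole-body required force from segment accelerations
  h <- time[2] - time[1]
  Qd <- cbind((Q[, 2] - Q[, 1]) / h,
              (Q[, -(1:2), drop = FALSE] - Q[, 1:(n - 2), drop = FALSE]) / (2 * h),
              (Q[, n] - Q[, n - 1]) / h)
  Qdd <- cbind((Qd[, 2] - Qd[, 1]) / h,
               (Qd[, -(1:2), drop = FALSE] - Qd[, 1:(n - 2), drop = FALSE]) / (2 * h),
               (Qd[, n] - Qd[, n - 1]) / h)
  external <- vector("list", n)
  ## after compression the ski is folded into the distal foot segment; the
  ## ground reaction applies at the mid-ski contact point
  foot_r <- grep("(talus|foot|calcn)_r", names(cmp$segments), value = TRUE)[1]
  foot_l <- grep("(talus|foot|calcn)_l", names(cmp$segments), value = TRUE)[1]
  ir <- match(foot_r, names(cmp$segments))
  il <- match(foot_l, names(cmp$segments))
  cp_r <- cmp$segments[[ir]]$contact_points[, 2]
  cp_l <- cmp$segments[[il]]$contact_points[, 2]
  ## per-sample whole-body required force (on the provisional kinematics),
  ## then hip-ab/adduction angulation solved so the external frontal-plane
  ## knee moment follows a realistic profile: ~35 N·m abduction building up
  ## on the outside knee, ~25 N·m adduction on the inside knee
  tib_r <- grep("(shank|tibia)_r", names(cmp$segments))
  tib_l <- grep("(shank|tibia)_l", names(cmp$segments))
  grf <- matrix(0, 3, n)
  for (k in seq_len(n)) {
    mo <- segment_motion(cmp, Q[, k], Qd[, k], Qdd[, k])
    W <- c(0, 0, 0)
    for (i in seq_along(cmp$segments))
      W <- W + cmp$segments[[i]]$mass * (mo$a_com[, i] - GRAVITY)
    grf[, k] <- W - air_drag(rowMeans(mo$v_com), bundle$aero)
  }
  ## quasi-static frontal-plane knee moment: thigh-on-shank moment of the
  ## distal subtree (gravity of distal segments minus the ground reaction)
  ## about the anterior tibia axis
  frontal_ext <- function(qk, add_coord, add_val, foot_i, cp, tib_i, F,
                          distal) {
    qk[add_coord] <- add_val
    fk <- forward_kinematics(cmp, qk)
    pc <- as.numeric(fk$p[, foot_i] + fk$R[, , foot_i] %*% cp)
    pk <- as.numeric(fk$p[, tib_i])
    M <- -((pc - pk) %crs% F)
    for (i in distal) {
      ci <- as.numeric(fk$p[, i] + fk$R[, , i] %*% cmp$segments[[i]]$com)
      M <- M - (ci - pk) %crs% (cmp$segments[[i]]$mass * GRAVITY)
    }
    sum(fk$R[, 1, tib_i] * M)
  }
  ## solve a single peak angulation per leg at the steering-phase peak and
  ## scale it with the loading bump, keeping the profile smooth
  iar <- match("hip_r_add", cn); ial <- match("hip_l_add", cn)
  k_pk <- which.max(s)
  distal_r <- distal_segments(cmp, names(cmp$segments)[tib_r])
  distal_l <- distal_segments(cmp, names(cmp$segments)[tib_l])
  a_r <- tryCatch(stats::uniroot(function(a)
    frontal_ext(Q[, k_pk], iar, a, ir, cp_r, tib_r,
                grf_split * grf[, k_pk], distal_r) - 35,
    c(-0.7, 0.7), tol = 1e-9)$root, error = function(e) -0.3)
  a_l <- tryCatch(stats::uniroot(function(a)
    frontal_ext(Q[, k_pk], ial, a, il, cp_l, tib_l,
                (1 - grf_split) * grf[, k_pk], distal_l) + 25,
    c(-0.7, 0.7), tol = 1e-9)$root, error = function(e) 0.2)
  Q[iar, ] <- a_r * s
  Q[ial, ] <- a_l * s
  ## refresh derivatives with the solved angulation
  Qd <- cbind((Q[, 2] - Q[, 1]) / h,
              (Q[, -(1:2), drop = FALSE] - Q[, 1:(n - 2), drop = FALSE]) / (2 * h),
              (Q[, n] - Q[, n - 1]) / h)
  Qdd <- cbind((Qd[, 2] - Qd[, 1]) / h,
               (Qd[, -(1:2), drop = FALSE] - Qd[, 1:(n - 2), drop = FALSE]) / (2 * h),
               (Qd[, n] - Qd[, n - 1]) / h)
  for (k in seq_len(n)) {
    mo <- segment_motion(cmp, Q[, k], Qd[, k], Qdd[, k])
    W <- c(0, 0, 0)
    for (i in seq_along(cmp$segments))
      W <- W + cmp$segments[[i]]$mass * (mo$a_com[, i] - GRAVITY)
    W <- W - air_drag(rowMeans(mo$v_com), bundle$aero)
    pr <- as.numeric(mo$fk$p[, ir] + mo$fk$R[, , ir] %*% cp_r)
    pl <- as.numeric(mo$fk$p[, il] + mo$fk$R[, , il] %*% cp_l)
    external[[k]] <- list(
      list(segment = foot_r, force = grf_split * W, point = pr),
      list(segment = foot_l, force = (1 - grf_split) * W, point = pl))
  }
  list(traj = list(time = time, Q = Q), external = external, bundle = bundle)
}

#' Add measurement noise to tracked channels
#'
#' Independent Gaussian noise per sample (different standard deviations for
#' angle and translation channels), optionally followed by a smoothing-
#' spline pass (generalized cross-validation) emulating the spline smoothing
#' applied to reconstructed keypoint data.
#'
#' @param channels Channel matrix (rows = channels, columns = samples).
#' @param is_angle Logical per row; \code{angle_sd} degrees;
#'   \code{position_sd} m.
#' @param smooth Logical: apply the smoothing pass.
#' @param seed Integer seed.
#' @return Noisy (optionally smoothed) channel matrix.
#' @export
add_measurement_noise <- function(channels, is_angle, angle_sd = 0.5,
                                  position_sd = 0.01, smooth = FALSE,
                                  seed = 1L) {
  assert_that(angle_sd >= 0 && position_sd >= 0, "noise sd must be >= 0")
  set.seed(seed)
  out <- channels
  n <- ncol(channels)
  for (i in seq_len(nrow(channels))) {
    sd_i <- if (is_angle[i]) deg2rad(angle_sd) else position_sd
    out[i, ] <- channels[i, ] + stats::rnorm(n, 0, sd_i)
    if (smooth && sd_i > 0)
      out[i, ] <- stats::smooth.spline(seq_len(n), out[i, ])$y
  }
  out
}

#' Synthesize surface-EMG envelopes from ground-truth activations
#'
#' Envelope = gain * activation + noise, rectified, with a random per-muscle
#' gain in [0.5, 2] (EMG amplitude is scale-free; comparisons rescale to the
#' maximum of the estimated activation).
#'
#' @param activations Matrix (muscles x samples) of ground-truth activations.
#' @param muscle_names Rows to synthesize (default: all).
#' @param noise_sd Additive noise SD; \code{seed} integer seed.
#' @return Matrix of envelopes with rownames \code{muscle_names}.
#' @export
synthesize_emg <- function(activations, muscle_names = rownames(activations),
                           noise_sd = 0.02, seed = 1L) {
  assert_that(!is.null(rownames(activations)),
              "activations must have muscle rownames")
  miss <- setdiff(muscle_names, rownames(activations))
  assert_that(length(miss) == 0,
              paste("missing activation channels:", paste(miss, collapse = ", ")))
  set.seed(seed)
  out <- matrix(0, length(muscle_names), ncol(activations),
                dimnames = list(muscle_names, NULL))
  for (i in seq_along(muscle_names)) {
    g <- stats::runif(1, 0.5, 2)
    out[i, ] <- abs(g * activations[muscle_names[i], ] +
                      stats::rnorm(ncol(activations), 0, noise_sd))
  }
  out
}
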
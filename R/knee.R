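## Intersegmental knee loads by Newton-Euler recursion over the distal
## segments (ski -> foot -> shank), and the data-driven three-plane ACL
## force model: a sagittal component proportional to the anterior
## ligamentous shear, and frontal/transverse components exponential in the
## respective plane moments, decaying with knee flexion.

#' Read ACL / knee model coefficients
#'
#' Loads the coefficient file: the sagittal shear-to-ACL proportion table
#' over knee flexion, the frontal/transverse exponential coefficients, the
#' patellar-tendon angle table, and constant line-of-action angles for the
#' non-quadriceps knee muscles.  Shipped defaults are synthetic literature-
#' scale values (see the file header); absolute ACL forces are
#' coefficient-dependent.
#'
#' @param path YAML file (default: shipped \code{acl_coefficients.yaml}).
#' @return A \code{knee_coefficients} object.
#' @export
read_acl_coefficients <- function(path = ski_extdata("acl_coefficients.yaml")) {
  if (!file.exists(path))
    ski_stop(sprintf("ACL coefficient file not found: '%s'", path),
             "skiturn_io_error")
  cf <- yaml::read_yaml(path)
  sp <- cf$sagittal_proportion
  assert_that(all(unlist(sp$proportion) >= 0) && all(unlist(sp$proportion) <= 1),
              "sagittal proportion must lie in [0, 1]")
  assert_that(cf$frontal$scale_N >= 0 && cf$transverse$scale_N >= 0,
              "exponential scales must be >= 0")
  structure(list(
    sagittal = list(flexion = deg2rad(unlist(sp$flexion_deg)),
                    proportion = unlist(sp$proportion)),
    frontal = cf$frontal, transverse = cf$transverse,
    pt_angle = list(flexion = deg2rad(unlist(cf$patellar_tendon_angle$flexion_deg)),
                    angle = deg2rad(unlist(cf$patellar_tendon_angle$angle_deg))),
    muscle_lines = lapply(cf$muscle_lines, deg2rad)),
    class = "knee_coefficients")
}

interp_clamped <- function(x, xs, ys) {
  stats::approx(xs, ys, xout = pmin(pmax(x, min(xs)), max(xs)), rule = 2)$y
}

#' Patellar tendon angle at a knee flexion angle
#' @param flexion rad; \code{coeffs} a \code{knee_coefficients}.
#' @return Anterior tendon angle, rad (sign change near 70 deg flexion).
#' @export
patellar_tendon_angle <- function(flexion, coeffs) {
  interp_clamped(flexion, coeffs$pt_angle$flexion, coeffs$pt_angle$angle)
}

## distal subtree of a joint in a compressed model
distal_segments <- function(cmp, joint_child) {
  n <- length(cmp$segments)
  out <- logical(n)
  ci <- match(joint_child, names(cmp$segments))
  assert_that(!is.na(ci), sprintf("segment '%s' not in model", joint_child))
  for (i in seq_len(n)) {
    j <- i
    while (j != 0L) { if (j == ci) { out[i] <- TRUE; break }; j <- cmp$parent[j] }
  }
  which(out)
}

#' Intersegmental knee loads by Newton-Euler recursion
#'
#' Solves the Newton-Euler equations of the segments distal to the knee
#' (shank, foot with boot, ski) per time sample: the knee force and moment
#' are the net load the thigh applies to the shank, computed from segment
#' accelerations (finite differences of the coordinate trajectory), gravity
#' and the external (ski-snow contact and other) forces.  Results are
#' expressed in the tibia anatomical frame: x anterior, y the knee
#' flexion axis (to the left), z proximal along the shank.
#'
#' @param bundle A \code{ski_bundle} (planar or 3D).
#' @param traj A \code{ski_trajectory}, or a list with \code{time} and
#'   \code{Q} (coordinate matrix) for prescribed kinematics.
#' @param leg "right" or "left".
#' @param external Optional external loads: list per sample of lists
#'   \code{list(segment =, force = 3-vec, point = 3-vec world)}; if NULL and
#'   the bundle is planar, the ski-snow contact forces are recomputed from
#'   the trajectory.
#' @return An \code{intersegmental_loads} object: matrices \code{force} and
#'   \code{moment} (3 x N, tibia frame), \code{flexion} (rad), \code{time}.
#' @export
intersegmental_loads <- function(bundle, traj, leg = c("right", "left"),
                                 external = NULL) {
  leg <- match.arg(leg)
  sfx <- if (leg == "right") "_r" else "_l"
  cmp <- bundle$compressed
  L <- bundle$layout
  shank <- grep(paste0("^(shank|tibia)", sfx), names(cmp$segments), value = TRUE)
  assert_that(length(shank) == 1, "cannot identify the shank segment")
  distal <- distal_segments(cmp, shank)
  si <- match(shank, names(cmp$segments))

  if (inherits(traj, "ski_trajectory")) {
    ## trajectories from the implicit-Euler integrator: use the same
    ## backward differences as the integration, so the recursion is exactly
    ## consistent with the system residual at every node
    Q <- traj$X[L$idx_q, , drop = FALSE]
    Qd <- traj$X[L$idx_qd, , drop = FALSE]
    time <- traj$time
    N <- ncol(Q)
    h <- time[2] - time[1]
    Qdd <- cbind((Qd[, 2] - Qd[, 1]) / h,
                 (Qd[, -1, drop = FALSE] - Qd[, -N, drop = FALSE]) / h)
  } else {
    Q <- traj$Q; time <- traj$time
    N <- ncol(Q)
    h <- time[2] - time[1]
    Qd <- cbind((Q[, 2] - Q[, 1]) / h,
                (Q[, -(1:2), drop = FALSE] - Q[, 1:(N - 2), drop = FALSE]) / (2 * h),
                (Q[, N] - Q[, N - 1]) / h)
    Qdd <- cbind((Qd[, 2] - Qd[, 1]) / h,
                 (Qd[, -(1:2), drop = FALSE] - Qd[, 1:(N - 2), drop = FALSE]) / (2 * h),
                 (Qd[, N] - Qd[, N - 1]) / h)
  }

  ## external contact forces from the planar engine if not supplied
  if (is.null(external) && bundle$engine == "planar" &&
      inherits(traj, "ski_trajectory")) {
    Xd <- cbind((traj$X[, 2] - traj$X[, 1]) / h,
                (traj$X[, -1, drop = FALSE] - traj$X[, -N, drop = FALSE]) / h)
    out <- planar_residual(bundle, traj$X, Xd, traj$U, forces = TRUE)
    slope <- bundle$surf$slope_angle
    nxs <- sin(slope); nzs <- cos(slope)
    hd <- bundle$surf$hardness
    st <- bundle$planar
    kin <- out$kin
    external <- lapply(seq_len(N), function(k) list())
    for (kk in seq_along(bundle$contact_points)) {
      cp <- bundle$contact_points[[kk]]
      pt <- planar_point(kin, st, cp$seg, cp$local[1], cp$local[3])
      Nf <- out$contact_force[kk, ]
      vn <- sqrt(pt$vx^2 + pt$vz^2 + 1e-6)
      Fx <- Nf * nxs - hd$mu * Nf * pt$vx / vn
      Fz <- Nf * nzs - hd$mu * Nf * pt$vz / vn
      segname <- names(cmp$segments)[cp$seg]
      for (k in seq_len(N)) {
        external[[k]][[length(external[[k]]) + 1L]] <-
          list(segment = segname, force = c(Fx[k], 0, Fz[k]),
               point = c(pt$x[k], 0, pt$z[k]))
      }
    }
  }

  force <- matrix(0, 3, N); moment <- matrix(0, 3, N); flex <- numeric(N)
  knee_coord <- match(paste0("knee", sfx), bundle$model$coord_names)
  for (k in seq_len(N)) {
    mo <- segment_motion(cmp, Q[, k], Qd[, k], Qdd[, k])
    pk <- mo$fk$p[, si]                       # knee centre (shank origin)
    Fsum <- c(0, 0, 0); Msum <- c(0, 0, 0)
    for (i in distal) {
      seg <- cmp$segments[[i]]
      Ri <- mo$fk$R[, , i]
      ci <- mo$fk$p[, i] + Ri %*% seg$com
      fi <- seg$mass * (mo$a_com[, i] - GRAVITY)
      Iw <- Ri %*% seg$inertia %*% t(Ri)
      mi <- Iw %*% mo$wdot[, i] + mo$w[, i] %crs% as.numeric(Iw %*% mo$w[, i])
      Fsum <- Fsum + fi
      Msum <- Msum + as.numeric(ci - pk) %crs% as.numeric(fi) + as.numeric(mi)
    }
    if (!is.null(external) && length(external[[k]])) {
      for (ld in external[[k]]) {
        i <- match(ld$segment, names(cmp$segments))
        if (!(i %in% distal)) next
        Fsum <- Fsum - ld$force
        Msum <- Msum - as.numeric(ld$point - pk) %crs% as.numeric(ld$force) -
          (ld$moment %||% c(0, 0, 0))
      }
    }
    ## tibia frame = shank segment frame
    Rsh <- mo$fk$R[, , si]
    force[, k] <- as.numeric(t(Rsh) %*% Fsum)
    moment[, k] <- as.numeric(t(Rsh) %*% Msum)
    flex[k] <- Q[knee_coord, k]
  }
  rownames(force) <- c("anterior", "lateral", "proximal")
  rownames(moment) <- c("frontal", "flexion", "transverse")
  structure(list(force = force, moment = moment, flexion = flex,
                 time = time, leg = leg), class = "intersegmental_loads")
}

#' Anteroposterior ligamentous shear at the knee
#'
#' Ligamentous shear = intersegmental anterior shear minus the anterior
#' components of the knee-crossing muscle forces: the quadriceps act through
#' the patellar tendon whose angle is a tabulated function of knee flexion
#' (anterior at low flexion, posterior above ~70 deg), hamstrings and
#' gastrocnemius pull along constant posterior-inclined lines.
#'
#' @param loads An \code{intersegmental_loads} (or anterior shear vector).
#' @param muscle_forces Matrix (muscles x N, N) of knee-crossing muscle
#'   tendon forces with rownames.
#' @param flexion Knee flexion angles, rad.
#' @param coeffs A \code{knee_coefficients}.
#' @return Anterior ligamentous shear series, N (positive anterior).
#' @export
ligamentous_shear <- function(loads, muscle_forces, flexion, coeffs) {
  shear <- if (inherits(loads, "intersegmental_loads"))
    loads$force["anterior", ] else loads
  if (is.null(muscle_forces) || nrow(muscle_forces) == 0) return(shear)
  assert_that(!is.null(rownames(muscle_forces)),
              "muscle_forces must carry muscle rownames")
  for (m in rownames(muscle_forces)) {
    ang <- if (grepl("vas|recfem|rectfem|quad", m)) {
      patellar_tendon_angle(flexion, coeffs)
    } else {
      key <- if (grepl("ham|bflh|bfsh|semi", m)) "hamstrings"
             else if (grepl("gas", m)) "gastroc"
             else NA_character_
      if (is.na(key) || is.null(coeffs$muscle_lines[[key]]))
        ski_stop(sprintf("no line-of-action entry for knee muscle '%s'", m),
                 "skiturn_validation_error")
      rep(coeffs$muscle_lines[[key]], length(flexion))
    }
    shear <- shear - muscle_forces[m, ] * sin(-ang)
  }
  shear
}

#' Three-plane ACL force
#'
#' Sagittal component: tabulated proportion (function of flexion) of the
#' anterior ligamentous shear, zero for posterior shear.  Frontal component:
#' exponential in the external abduction moment, decaying with flexion, and
#' zero for adduction-side moments (direction gating).  Transverse component:
#' analogous for internal-rotation moments.  All components are nonnegative
#' and sum exactly to the total.
#'
#' @param shear Anterior ligamentous shear, N (positive anterior).
#' @param frontal_moment External abduction moment on the analyzed knee, N·m
#'   (positive = abduction / ACL-loading side).
#' @param transverse_moment External internal-rotation moment, N·m (positive
#'   = ACL-loading side).
#' @param flexion Knee flexion, rad.
#' @param coeffs A \code{knee_coefficients}.
#' @return An \code{acl_components} list of series: \code{sagittal},
#'   \code{frontal}, \code{transverse}, \code{total} (N).
#' @export
acl_force <- function(shear, frontal_moment, transverse_moment, flexion,
                      coeffs) {
  prop <- interp_clamped(flexion, coeffs$sagittal$flexion,
                         coeffs$sagittal$proportion)
  sag <- prop * pmax(shear, 0)
  ## the exponential regressions are only valid inside the cadaver-loading
  ## range; plane moments are clamped at the calibration limit
  cap <- coeffs$moment_cap_Nm %||% 60
  fr <- coeffs$frontal
  mfr <- pmin(pmax(frontal_moment, 0), cap)
  frontal <- fr$scale_N * (exp(fr$moment_rate_per_Nm * mfr) - 1) *
    exp(-fr$flexion_rate_per_rad * pmax(flexion, 0))
  tv <- coeffs$transverse
  mtv <- pmin(pmax(transverse_moment, 0), cap)
  transverse <- tv$scale_N * (exp(tv$moment_rate_per_Nm * mtv) - 1) *
    exp(-tv$flexion_rate_per_rad * pmax(flexion, 0))
  structure(list(sagittal = sag, frontal = frontal, transverse = transverse,
                 total = sag + frontal + transverse),
            class = "acl_components")
}

#' Normalize a force to body-weight multiples
#' @param force N; \code{subject_mass} kg (> 0).
#' @return Force in BW (body weight = mass * 9.81 m/s²).
#' @export
body_weight_normalize <- function(force, subject_mass) {
  assert_that(subject_mass > 0, "subject mass must be > 0")
  force / (subject_mass * 9.81)
}

#' ACL force time series for one leg of a solved trajectory
#'
#' Convenience pipeline: intersegmental loads (Newton-Euler), knee muscle
#' tendon forces from the trajectory states, ligamentous shear, and the
#' three-plane ACL model.  On the planar reduced model the frontal and
#' transverse moments are identically zero; the sagittal pathway is
#' exercised in full.
#'
#' @param bundle A \code{ski_bundle}; \code{traj} a \code{ski_trajectory}.
#' @param leg "right" or "left"; \code{coeffs} a \code{knee_coefficients}.
#' @return List with \code{acl} (an \code{acl_components}), \code{loads},
#'   \code{shear}.
#' @export
acl_time_series <- function(bundle, traj, leg = "right",
                            coeffs = read_acl_coefficients(),
                            external = NULL) {
  loads <- intersegmental_loads(bundle, traj, leg, external)
  sfx <- if (leg == "right") "_r" else "_l"
  L <- bundle$layout
  ## tendon forces of knee-crossing muscles from the trajectory states
  mf <- NULL
  if (!is.null(bundle$muscles) && bundle$engine == "planar" &&
      inherits(traj, "ski_trajectory")) {
    N <- ncol(traj$X)
    h <- traj$time[2] - traj$time[1]
    Xd <- cbind((traj$X[, 2] - traj$X[, 1]) / h,
                (traj$X[, -1, drop = FALSE] - traj$X[, -N, drop = FALSE]) / h)
    out <- planar_residual(bundle, traj$X, Xd, traj$U, forces = TRUE)
    knee_c <- paste0("knee", sfx)
    knee_mus <- which(vapply(bundle$muscles$coords,
                             function(cc) knee_c %in% cc, TRUE))
    mf <- out$f_tendon[knee_mus, , drop = FALSE]
    rownames(mf) <- bundle$muscles$names[knee_mus]
  }
  shear <- ligamentous_shear(loads, mf, loads$flexion, coeffs)
  ## plane moments on the ACL-loading side: the recursion returns the
  ## thigh-on-shank moment in the tibia frame (x anterior, y to the left, z
  ## proximal); for the right knee the external abduction moment maps to
  ## +x and the external internal-rotation moment to -z, mirrored for the
  ## left knee
  sgn <- if (leg == "right") 1 else -1
  abd <- sgn * loads$moment["frontal", ]
  irot <- -sgn * loads$moment["transverse", ]
  acl <- acl_force(shear, abd, irot, loads$flexion, coeffs)
  list(acl = acl, loads = loads, shear = shear,
       abduction_moment = abd, internal_rotation_moment = irot)
}
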
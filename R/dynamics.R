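## Full implicit system dynamics f(x, xdot, u) = 0 of skier + skis + muscles
## + contact, and the implicit-Euler forward-simulation oracle.
##
## The residual stacks (i) qdot-consistency rows, (ii) multibody rows
## (inertial generalized forces minus muscle, boot, contact, drag and gravity
## contributions), (iii) muscle contraction rows, (iv) activation rows and
## (v) hypoplastic contact-memory rows.  Two backends share these semantics:
## the vectorized planar engine (planar_engine.R) and the generic
## Jacobian-composition engine below, valid for any joint set.

#' Implicit system residual
#'
#' Evaluates f(x, xdot, u) for a bundle; zero exactly on dynamically
#' consistent trajectories.  Dispatches to the vectorized planar backend when
#' available, otherwise uses the generic engine.
#'
#' @param x,xdot State \code{[q, qdot, s, a, mem]} and its time derivative.
#' @param u Muscle excitations.
#' @param bundle A \code{ski_bundle}.
#' @param external_loads Optional list of per-segment wrenches for the
#'   generic backend: each \code{list(segment =, force =, moment =, point =)}
#'   with \code{point} in world coordinates.
#' @return Scaled residual vector of length \code{bundle$layout$n_x}.
#' @export
system_residual <- function(x, xdot, u, bundle, external_loads = NULL) {
  L <- bundle$layout
  assert_that(length(x) == L$n_x && length(xdot) == L$n_x,
              sprintf("state must have length %d", L$n_x))
  assert_that(length(u) == L$n_u, sprintf("u must have length %d", L$n_u))
  if (any(!is.finite(x)) || any(!is.finite(xdot)) || any(!is.finite(u)))
    ski_stop("non-finite state or control", "skiturn_numeric_error")
  if (bundle$engine == "planar" && is.null(external_loads)) {
    return(as.numeric(planar_residual(bundle, matrix(x), matrix(xdot),
                                      matrix(u, ncol = 1))))
  }
  generic_residual(x, xdot, u, bundle, external_loads)
}

generic_residual <- function(x, xdot, u, bundle, external_loads = NULL) {
  L <- bundle$layout; mdl <- bundle$compressed
  q <- x[L$idx_q]; qd <- x[L$idx_qd]; qdd <- xdot[L$idx_qd]
  res <- numeric(L$n_x)
  res[L$idx_q] <- xdot[L$idx_q] - qd

  J <- segment_jacobians(mdl, q)
  mo <- segment_motion(mdl, q, qd, qdd)
  nseg <- length(mdl$segments)
  rho <- numeric(L$n_q)
  for (i in seq_len(nseg)) {
    seg <- mdl$segments[[i]]
    Ri <- J$fk$R[, , i]
    Iw <- Ri %*% seg$inertia %*% t(Ri)
    fi <- seg$mass * (mo$a_com[, i] - GRAVITY)
    mi <- Iw %*% mo$wdot[, i] + mo$w[, i] %crs% (Iw %*% mo$w[, i])
    rho <- rho + as.numeric(t(J$Jv[, , i]) %*% fi + t(J$Jw[, , i]) %*% mi)
  }

  qn <- stats::setNames(q, bundle$model$coord_names)
  ## muscles
  if (L$n_m > 0) {
    s <- x[L$idx_s]; a <- x[L$idx_a]
    for (m in seq_len(L$n_m)) {
      sp <- muscle_spec(bundle$muscles, m)
      g <- muscle_tendon_length_and_moment_arms(qn, sp)
      cr <- contraction_residual(list(s = s[m], a = a[m]),
                                 xdot[L$idx_s[m]], g$l_mt, sp)
      res[L$idx_s[m]] <- cr$residual
      res[L$idx_a[m]] <- activation_residual(a[m], xdot[L$idx_a[m]], u[m], sp)
      ci <- match(sp$coords, bundle$model$coord_names)
      rho[ci] <- rho[ci] - g$moment_arms * cr$f_tendon
    }
  }
  ## boot at ankle coordinates (revolute joints of foot-like segments), and
  ## passive spring-damper joints (ski bending chain)
  segnames <- names(bundle$compressed$segments)
  for (i in seq_len(nseg)) {
    seg <- bundle$compressed$segments[[i]]
    if (seg$kind != "revolute1") next
    qi <- bundle$compressed$dof_start[i]
    if (grepl("foot|talus", segnames[i]))
      rho[qi] <- rho[qi] - boot_moment(q[qi], qd[qi], bundle$model$boot)
    if (!is.null(seg$passive))
      rho[qi] <- rho[qi] + seg$passive$stiffness * (q[qi] - seg$passive$neutral) +
        seg$passive$damping * qd[qi]
  }
  ## contact (penetration + friction + shear) at the bundle's contact points
  if (L$n_c > 0) {
    hd <- bundle$surf$hardness
    mem <- x[L$idx_mem]
    for (k in seq_len(L$n_c)) {
      cp <- bundle$contact_points[[k]]
      i <- cp$seg
      Ri <- J$fk$R[, , i]
      ptw <- J$fk$p[, i] + Ri %*% cp$local
      g <- bundle$surf$grad(ptw[1], ptw[2])
      nrm <- c(-g$gx, -g$gy, 1); nrm <- nrm / sqrt(sum(nrm^2))
      d <- (bundle$surf$height(ptw[1], ptw[2]) - ptw[3]) /
        sqrt(1 + g$gx^2 + g$gy^2)
      vpt <- mo$v[, i] + mo$w[, i] %crs% as.numeric(Ri %*% cp$local)
      drate <- -sum(vpt * nrm)
      edging <- acos(pmin(pmax(abs(sum(Ri[, 3] * nrm)), -1), 1))
      Nf <- penetration_force_smooth(d, drate, mem[k], edging, hd)
      F <- Nf * nrm + friction_force(Nf, vpt, hd$mu)
      ## lateral shear orthogonal to the edge, only meaningful in 3D
      kin3 <- list(depth = max(d, 0), edge_direction = as.numeric(Ri[, 1]),
                   normal = nrm, velocity = vpt)
      F <- F + shear_force(kin3, hd$shear_coeff)
      rho <- rho - point_wrench(J, mdl, i, ptw, F)
      res[L$idx_mem[k]] <- xdot[L$idx_mem[k]] - memory_rate(d, mem[k])
    }
  }
  ## drag at the root segment COM
  croot <- J$fk$p[, 1] + J$fk$R[, , 1] %*% bundle$compressed$segments[[1]]$com
  vroot <- mo$v_com[, 1]
  Fd <- air_drag(vroot, bundle$aero)
  rho <- rho - point_wrench(J, mdl, 1L, as.numeric(croot), Fd)
  ## user-supplied external loads
  if (!is.null(external_loads)) {
    for (ld in external_loads) {
      i <- if (is.character(ld$segment)) match(ld$segment, segnames) else ld$segment
      rho <- rho - point_wrench(J, mdl, i, ld$point %||% as.numeric(J$fk$p[, i]),
                                ld$force %||% c(0, 0, 0),
                                ld$moment %||% c(0, 0, 0))
    }
  }
  res[L$idx_qd] <- rho
  res * bundle$scales
}

## generalized force of a wrench applied at world point p on segment i:
## shift the COM linear Jacobian to the application point by the angular
## Jacobian cross term
point_wrench <- function(J, mdl, i, p, force, moment = c(0, 0, 0)) {
  nq <- dim(J$Jv)[2]
  com_w <- as.numeric(J$fk$p[, i] + J$fk$R[, , i] %*% mdl$segments[[i]]$com)
  r <- as.numeric(p) - com_w
  out <- numeric(nq)
  for (j in seq_len(nq)) {
    Jpj <- J$Jv[, j, i] + J$Jw[, j, i] %crs% r
    out[j] <- sum(Jpj * force) + sum(J$Jw[, j, i] * moment)
  }
  out
}

#' One implicit-Euler step of a generic implicit residual
#'
#' Root-solves \code{f(x1, (x1 - x0)/h, u) = 0} for the next state of a
#' (small, dense) implicit system by damped Newton with finite-difference
#' Jacobian.  This is the elementary step underlying both the forward
#' simulator and the collocation defects; e.g. for the scalar test dynamics
#' \code{f(x, xd, u) = xd + x} and h = 0.1 from x0 = 1 it returns
#' 1/1.1.
#'
#' @param f Function(x, xdot, u) returning a residual vector.
#' @param x0 Current state; \code{u} input held over the step; \code{h} step.
#' @return The next state x1.
#' @export
implicit_euler_root <- function(f, x0, u = NULL, h) {
  n <- length(x0)
  x1 <- x0
  for (it in 1:50) {
    r <- f(x1, (x1 - x0) / h, u)
    if (max(abs(r)) < 1e-12) break
    J <- matrix(0, n, n)
    fd <- 1e-7
    for (j in seq_len(n)) {
      e <- numeric(n); e[j] <- fd
      J[, j] <- (f(x1 + e, (x1 + e - x0) / h, u) - r) / fd
    }
    x1 <- x1 - solve(J, r)
  }
  x1
}

#' Forward simulation by implicit Euler
#'
#' Integrates the implicit residual with a first-order implicit stepper: at
#' each step the root of \code{f(x_{k+1}, (x_{k+1}-x_k)/dt, u_{k+1}) = 0} is
#' found by a damped Newton iteration with a finite-difference Jacobian
#' (vectorized on the planar backend).
#'
#' @param bundle A \code{ski_bundle}.
#' @param x0 Initial state (see \code{\link{bundle_initial_state}}).
#' @param u Excitation schedule: function(t) returning a vector, a constant
#'   vector, or an n_u x (n_steps+1) matrix of node values.
#' @param T Horizon, s; \code{dt} step, s.
#' @param tol Scaled residual tolerance per step.
#' @return A \code{ski_trajectory}: \code{time}, \code{X} (n_x columns per
#'   node), \code{U}.
#' @export
forward_simulate <- function(bundle, x0, u, T, dt, tol = 1e-8) {
  assert_that(dt > 0 && T > 0, "T and dt must be positive")
  L <- bundle$layout
  nstep <- round(T / dt)
  time <- seq(0, by = dt, length.out = nstep + 1)
  Ufun <- if (is.function(u)) u
          else if (is.matrix(u)) { um <- u; function(t) um[, min(1 + round(t / dt), ncol(um))] }
          else function(t) rep_len(u, L$n_u)
  X <- matrix(0, L$n_x, nstep + 1); X[, 1] <- x0
  U <- matrix(0, max(L$n_u, 1), nstep + 1); if (L$n_u > 0) U[, 1] <- Ufun(0)
  resfun <- function(Xc, Xd, Uc) {
    if (bundle$engine == "planar") planar_residual(bundle, Xc, Xd, Uc)
    else matrix(system_residual(Xc[, 1], Xd[, 1], Uc[, 1], bundle))
  }
  Jfd <- function(xk, xn, uk) {
    h <- 1e-6
    n <- L$n_x
    Xp <- matrix(xn, n, n + 1)
    Xp[, seq_len(n) + 1] <- Xp[, seq_len(n) + 1] + diag(h, n)
    Xd <- (Xp - xk) / dt
    Uc <- matrix(uk, length(uk), n + 1)
    R <- resfun(Xp, Xd, Uc)
    (R[, -1, drop = FALSE] - R[, 1]) / h
  }
  for (k in seq_len(nstep)) {
    xk <- X[, k]
    uk <- if (L$n_u > 0) Ufun(time[k + 1]) else numeric(0)
    if (L$n_u > 0) U[, k + 1] <- uk
    xn <- xk
    ok <- FALSE
    for (it in 1:25) {
      r <- resfun(matrix(xn), matrix((xn - xk) / dt), matrix(uk, ncol = 1))[, 1]
      if (max(abs(r)) < tol) { ok <- TRUE; break }
      Jm <- Jfd(xk, xn, uk)
      dx <- tryCatch(-solve(Jm, r), error = function(e)
        -solve(Jm + diag(1e-8, length(r)), r))
      ## damped update: accept the first step length that reduces the residual
      step <- 1
      for (half in 1:10) {
        xt <- xn + step * dx
        rt <- resfun(matrix(xt), matrix((xt - xk) / dt),
                     matrix(uk, ncol = 1))[, 1]
        if (all(is.finite(rt)) && max(abs(rt)) < max(abs(r))) break
        step <- step / 2
      }
      xn <- xn + step * dx
    }
    if (!ok) {
      r <- resfun(matrix(xn), matrix((xn - xk) / dt), matrix(uk, ncol = 1))[, 1]
      if (max(abs(r)) > 1e3 * tol)
        ski_stop(sprintf("implicit step %d failed to converge (residual %.2e)",
                         k, max(abs(r))), "skiturn_integration_error")
    }
    X[, k + 1] <- xn
  }
  structure(list(time = time, X = X, U = U, dt = dt,
                 layout = L, bundle_name = bundle$model$name),
            class = "ski_trajectory")
}

#' @export
print.ski_trajectory <- function(x, ...) {
  cat(sprintf("<ski_trajectory>: %d nodes, T = %.3f s, %d states\n",
              length(x$time), max(x$time), nrow(x$X)))
  invisible(x)
}

#' Mechanical energy audit of a planar simulation
#'
#' Checks that d/dt(kinetic + gravitational potential) matches the total
#' power injected by muscles (joint-moment power), the boot, contact forces
#' and drag along a planar trajectory.  Returns the worst absolute mismatch
#' relative to the peak power flow.
#'
#' @param bundle A planar \code{ski_bundle}; \code{traj} a
#'   \code{ski_trajectory} from \code{\link{forward_simulate}}.
#' @return List with \code{rel_error}, \code{energy}, \code{power} series.
#' @export
energy_audit <- function(bundle, traj) {
  assert_that(bundle$engine == "planar", "energy audit uses the planar backend")
  L <- bundle$layout; st <- bundle$planar
  N <- ncol(traj$X)
  Q <- traj$X[L$idx_q, , drop = FALSE]; Qd <- traj$X[L$idx_qd, , drop = FALSE]
  kin <- planar_kinematics(bundle, Q, Qd)
  KE <- rep(0, N); PE <- rep(0, N)
  for (i in seq_len(st$n_seg)) {
    w <- rot2v(kin$th[[i]], st$com_x[i], st$com_z[i])
    vx <- kin$Vx[[i]] + kin$thd[[i]] * w$z
    vz <- kin$Vz[[i]] - kin$thd[[i]] * w$x
    KE <- KE + 0.5 * st$mass[i] * (vx^2 + vz^2) + 0.5 * st$Iy[i] * kin$thd[[i]]^2
    PE <- PE + st$mass[i] * 9.81 * (kin$Pz[[i]] + w$z)
  }
  ## applied power: evaluate the same force models used by the residual
  Xd <- cbind((traj$X[, -1] - traj$X[, -N]) / traj$dt, 0)
  out <- planar_residual(bundle, traj$X, Xd, traj$U, forces = TRUE)
  P <- rep(0, N)
  ## muscle joint power
  if (L$n_m > 0) {
    for (m in seq_len(L$n_m)) {
      qi <- st$mus_q[[m]]
      for (j in seq_along(qi)) {
        arm <- arm_poly_eval(st$mus_arms[[m]][[j]], Q[qi[j], ])
        P <- P + arm * out$f_tendon[m, ] * Qd[qi[j], ]
      }
    }
  }
  for (k in seq_along(st$ankle_q)) {
    qi <- st$ankle_q[k]
    P <- P + boot_moment(Q[qi, ], Qd[qi, ], bundle$model$boot) * Qd[qi, ]
  }
  slope <- bundle$surf$slope_angle
  nxs <- sin(slope); nzs <- cos(slope); hd <- bundle$surf$hardness
  for (k in seq_len(L$n_c)) {
    cp <- bundle$contact_points[[k]]
    pt <- planar_point(kin, st, cp$seg, cp$local[1], cp$local[3])
    Nf <- out$contact_force[k, ]
    vn <- sqrt(pt$vx^2 + pt$vz^2 + 1e-6)
    Fx <- Nf * nxs - hd$mu * Nf * pt$vx / vn
    Fz <- Nf * nzs - hd$mu * Nf * pt$vz / vn
    P <- P + Fx * pt$vx + Fz * pt$vz
  }
  wc <- rot2v(kin$th[[1]], st$com_x[1], st$com_z[1])
  vrx <- kin$Vx[[1]] + kin$thd[[1]] * wc$z
  vrz <- kin$Vz[[1]] - kin$thd[[1]] * wc$x
  vmag <- sqrt(vrx^2 + vrz^2)
  cda <- 0.5 * bundle$aero$rho * bundle$aero$CdA
  P <- P - cda * vmag * (vrx^2 + vrz^2)
  E <- KE + PE
  dEdt <- (E[-1] - E[-N]) / traj$dt
  Pmid <- P[-1]
  list(rel_error = max(abs(dEdt - Pmid)) / max(abs(P)),
       energy = E, power = P)
}
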
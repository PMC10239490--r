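## Vectorized planar dynamics backend.  For models whose articulated joints
## are a planar (x, z, pitch) root plus revolute joints about +/- y, the
## implicit residual is evaluated analytically and vectorized across
## evaluation columns, which makes finite-difference Jacobians of the
## collocation defects cheap (one vectorized call per perturbation batch).
## The generic engine in dynamics.R is the reference semantics; the two are
## cross-checked in the test suite.

planar_compatible <- function(b) {
  segs <- b$compressed$segments
  ok <- TRUE
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    if (s$kind == "planar3" && all(s$signs == 1)) next
    if (s$kind == "revolute1" && abs(abs(s$axis[2]) - 1) < 1e-12) next
    ok <- FALSE
  }
  ok && segs[[1]]$kind == "planar3"
}

## rot2(theta) acts on (x, z) pairs exactly as R_y restricted to the plane
rot2v <- function(theta, vx, vz) {
  ct <- cos(theta); st <- sin(theta)
  list(x = ct * vx + st * vz, z = -st * vx + ct * vz)
}
## K = d(rot2)/dtheta composed: K (wx, wz) = (wz, -wx)

planar_structure <- function(b) {
  cmp <- b$compressed
  segs <- cmp$segments
  n <- length(segs)
  st <- list(n_seg = n, parent = cmp$parent,
             mass = vapply(segs, `[[`, 0, "mass"),
             Iy = vapply(segs, function(s) s$inertia[2, 2], 0),
             com_x = vapply(segs, function(s) s$com[1], 0),
             com_z = vapply(segs, function(s) s$com[3], 0),
             org_x = vapply(segs, function(s) s$origin[1], 0),
             org_z = vapply(segs, function(s) s$origin[3], 0),
             sign = vapply(segs, function(s)
               if (s$kind == "revolute1") s$axis[2] * s$signs[1] else 1, 0),
             kind = vapply(segs, `[[`, "", "kind"))
  ## rotation coordinate (global q index) of each segment's own joint
  st$rot_q <- vapply(seq_len(n), function(i) {
    di <- seq.int(cmp$dof_start[i], length.out = cmp$dof_count[i])
    if (st$kind[i] == "planar3") di[3] else di[1]
  }, 0L)
  ## ancestor-or-self incidence: affects[i, j] = does rotation coord of
  ## segment j move segment i
  aff <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    j <- i
    while (j != 0L) { aff[i, j] <- TRUE; j <- cmp$parent[j] }
  }
  st$affects <- aff
  ## ankle coordinates for the boot moment: revolute joints whose child
  ## segment has 'foot' in the name
  st$ankle_q <- st$rot_q[grepl("foot|talus", names(segs)) &
                           st$kind == "revolute1"]
  st$ankle_sign <- st$sign[match(st$ankle_q, st$rot_q)]
  ## revolute joints with passive spring-damper elements (ski bending chain)
  st$passive <- Filter(Negate(is.null), lapply(seq_len(n), function(i) {
    p <- segs[[i]]$passive
    if (is.null(p) || st$kind[i] != "revolute1") return(NULL)
    c(list(q = st$rot_q[i]), p)
  }))
  ## muscle coordinate mapping: per muscle, global q indices + polynomials
  if (!is.null(b$muscles)) {
    cn <- b$model$coord_names
    st$mus_q <- lapply(b$muscles$coords, function(cc) match(cc, cn))
    st$mus_arms <- b$muscles$arms
  }
  st
}

## kinematics pass shared by the residual and the force/report paths;
## Q is n_q x N, Qd/Qdd may be NULL for position-only queries
planar_kinematics <- function(b, Q, Qd = NULL, Qdd = NULL) {
  st <- b$planar; n <- st$n_seg; N <- ncol(Q)
  zero <- matrix(0, 1, N)
  th <- vector("list", n); thd <- th; thdd <- th
  Px <- th; Pz <- th; Vx <- th; Vz <- th; Ax <- th; Az <- th
  vel <- !is.null(Qd); acc <- !is.null(Qdd)
  for (i in seq_len(n)) {
    p <- st$parent[i]
    if (p == 0L) {
      di <- st$rot_q[i]                 # planar3: q = (tx, tz, pitch)
      th[[i]] <- st$sign[i] * Q[di, , drop = FALSE]
      Px[[i]] <- st$org_x[i] + Q[di - 2L, , drop = FALSE]
      Pz[[i]] <- st$org_z[i] + Q[di - 1L, , drop = FALSE]
      if (vel) {
        thd[[i]] <- st$sign[i] * Qd[di, , drop = FALSE]
        Vx[[i]] <- Qd[di - 2L, , drop = FALSE]
        Vz[[i]] <- Qd[di - 1L, , drop = FALSE]
      }
      if (acc) {
        thdd[[i]] <- st$sign[i] * Qdd[di, , drop = FALSE]
        Ax[[i]] <- Qdd[di - 2L, , drop = FALSE]
        Az[[i]] <- Qdd[di - 1L, , drop = FALSE]
      }
    } else {
      w <- rot2v(th[[p]], st$org_x[i], st$org_z[i])
      di <- st$rot_q[i]
      th[[i]] <- th[[p]] + st$sign[i] * Q[di, , drop = FALSE]
      Px[[i]] <- Px[[p]] + w$x
      Pz[[i]] <- Pz[[p]] + w$z
      if (vel) {
        thd[[i]] <- thd[[p]] + st$sign[i] * Qd[di, , drop = FALSE]
        Vx[[i]] <- Vx[[p]] + thd[[p]] * w$z
        Vz[[i]] <- Vz[[p]] - thd[[p]] * w$x
      }
      if (acc) {
        thdd[[i]] <- thdd[[p]] + st$sign[i] * Qdd[di, , drop = FALSE]
        Ax[[i]] <- Ax[[p]] + thdd[[p]] * w$z - thd[[p]]^2 * w$x
        Az[[i]] <- Az[[p]] - thdd[[p]] * w$x - thd[[p]]^2 * w$z
      }
    }
  }
  list(th = th, thd = thd, thdd = thdd, Px = Px, Pz = Pz,
       Vx = Vx, Vz = Vz, Ax = Ax, Az = Az, N = N)
}

## world position/velocity of a point fixed in segment i
planar_point <- function(kin, st, i, lx, lz, vel = TRUE) {
  w <- rot2v(kin$th[[i]], lx, lz)
  out <- list(x = kin$Px[[i]] + w$x, z = kin$Pz[[i]] + w$z, wx = w$x, wz = w$z)
  if (vel && !is.null(kin$Vx[[i]])) {
    out$vx <- kin$Vx[[i]] + kin$thd[[i]] * w$z
    out$vz <- kin$Vz[[i]] - kin$thd[[i]] * w$x
  }
  out
}

## depth/rate of all contact points (used for memory init and reporting)
planar_contact_geometry <- function(b, Q, Qd = NULL) {
  kin <- planar_kinematics(b, Q, Qd)
  st <- b$planar
  slope <- b$surf$slope_angle
  nx <- sin(slope); nz <- cos(slope)
  nc <- length(b$contact_points); N <- ncol(Q)
  depth <- matrix(0, nc, N); rate <- matrix(0, nc, N)
  for (k in seq_len(nc)) {
    cp <- b$contact_points[[k]]
    pt <- planar_point(kin, st, cp$seg, cp$local[1], cp$local[3],
                       vel = !is.null(Qd))
    depth[k, ] <- -(pt$x * nx + pt$z * nz)
    if (!is.null(Qd)) rate[k, ] <- -(pt$vx * nx + pt$vz * nz)
  }
  list(depth = depth, rate = rate)
}

#' Implicit system residual (vectorized planar backend)
#'
#' Evaluates the full implicit residual f(x, xdot, u) = 0 of the planar
#' bundle on a batch of evaluation points (columns): qdot-consistency rows,
#' multibody rows (inertial minus applied generalized forces, including
#' muscle moments, boot moment, ski-snow contact, drag and gravity),
#' contraction and activation rows, and hypoplastic-memory rows.  Rows are
#' scaled by \code{bundle$scales}.
#'
#' @param bundle A planar \code{ski_bundle}.
#' @param X,Xdot n_x x N state and state-derivative columns.
#' @param U n_u x N excitation columns.
#' @param forces If TRUE, also return tendon forces and per-point contact
#'   forces.
#' @return n_x x N residual matrix (or a list when \code{forces}).
#' @export
planar_residual <- function(bundle, X, Xdot, U, forces = FALSE) {
  L <- bundle$layout; st <- bundle$planar
  N <- ncol(X)
  Q <- X[L$idx_q, , drop = FALSE]; Qd <- X[L$idx_qd, , drop = FALSE]
  Qdd <- Xdot[L$idx_qd, , drop = FALSE]
  kin <- planar_kinematics(bundle, Q, Qd, Qdd)
  n <- st$n_seg; nq <- L$n_q
  gz <- -9.81
  RES <- matrix(0, L$n_x, N)
  ## (i) qdot-consistency
  RES[L$idx_q, ] <- Xdot[L$idx_q, , drop = FALSE] - Qd

  ## (ii) multibody rows: start from inertial terms of each segment
  rho <- matrix(0, nq, N)
  comx <- vector("list", n); comz <- vector("list", n)
  acx <- vector("list", n); acz <- vector("list", n)
  for (i in seq_len(n)) {
    w <- rot2v(kin$th[[i]], st$com_x[i], st$com_z[i])
    comx[[i]] <- kin$Px[[i]] + w$x
    comz[[i]] <- kin$Pz[[i]] + w$z
    acx[[i]] <- kin$Ax[[i]] + kin$thdd[[i]] * w$z - kin$thd[[i]]^2 * w$x
    acz[[i]] <- kin$Az[[i]] - kin$thdd[[i]] * w$x - kin$thd[[i]]^2 * w$z
  }
  root_rq <- st$rot_q[1]
  for (i in seq_len(n)) {
    fx <- st$mass[i] * acx[[i]]
    fz <- st$mass[i] * (acz[[i]] - gz)
    rho[root_rq - 2L, ] <- rho[root_rq - 2L, ] + fx
    rho[root_rq - 1L, ] <- rho[root_rq - 1L, ] + fz
    for (j in seq_len(n)) {
      if (!st$affects[i, j]) next
      jq <- st$rot_q[j]
      ## d(com_i)/d(q_jq) = sign_j * K (com_i - P_j); K(w) = (wz, -wx)
      dx <- st$sign[j] * (comz[[i]] - kin$Pz[[j]])
      dz <- -st$sign[j] * (comx[[i]] - kin$Px[[j]])
      rho[jq, ] <- rho[jq, ] + dx * fx + dz * fz +
        st$sign[j] * st$Iy[i] * kin$thdd[[i]]
    }
  }

  ## applied generalized forces: muscles (vectorized across the muscle set:
  ## parameter vectors recycle down the rows of n_m x N matrices)
  f_tendon <- NULL
  if (L$n_m > 0) {
    S <- X[L$idx_s, , drop = FALSE]; A <- X[L$idx_a, , drop = FALSE]
    Sdot <- Xdot[L$idx_s, , drop = FALSE]; Adot <- Xdot[L$idx_a, , drop = FALSE]
    tb <- bundle$muscles$table
    LMT <- matrix(tb$l_ref, L$n_m, N)
    for (m in seq_len(L$n_m)) {
      qi <- st$mus_q[[m]]
      for (j in seq_along(qi))
        LMT[m, ] <- LMT[m, ] - arm_poly_integral(st$mus_arms[[m]][[j]], Q[qi[j], ])
    }
    cr <- contraction_residual(list(s = S, a = A), Sdot, LMT,
                               list(f_max = tb$f_max, l_opt = tb$l_opt,
                                    l_slack = tb$l_slack,
                                    pennation_opt = tb$pennation_opt))
    RES[L$idx_s, ] <- cr$residual
    f_tendon <- cr$f_tendon
    RES[L$idx_a, ] <- activation_residual(
      A, Adot, U, list(tau_act = tb$tau_act, tau_deact = tb$tau_deact))
    for (m in seq_len(L$n_m)) {
      qi <- st$mus_q[[m]]
      for (j in seq_along(qi)) {
        arm <- arm_poly_eval(st$mus_arms[[m]][[j]], Q[qi[j], ])
        rho[qi[j], ] <- rho[qi[j], ] - arm * f_tendon[m, ]
      }
    }
  }

  ## boot passive ankle moments
  for (k in seq_along(st$ankle_q)) {
    qi <- st$ankle_q[k]
    rho[qi, ] <- rho[qi, ] - boot_moment(Q[qi, ], Qd[qi, ], bundle$model$boot)
  }
  ## joint spring-damper elements (e.g. ski bending joints)
  for (p in st$passive) {
    qi <- p$q
    rho[qi, ] <- rho[qi, ] +
      p$stiffness * (Q[qi, ] - p$neutral) + p$damping * Qd[qi, ]
  }

  ## contact forces + memory rows
  slope <- bundle$surf$slope_angle
  nxs <- sin(slope); nzs <- cos(slope)
  hd <- bundle$surf$hardness
  cforce <- if (forces) matrix(0, L$n_c, N) else NULL
  if (L$n_c > 0) {
    MEM <- X[L$idx_mem, , drop = FALSE]
    MEMd <- Xdot[L$idx_mem, , drop = FALSE]
    for (k in seq_len(L$n_c)) {
      cp <- bundle$contact_points[[k]]
      pt <- planar_point(kin, st, cp$seg, cp$local[1], cp$local[3])
      d <- -(pt$x * nxs + pt$z * nzs)
      drate <- -(pt$vx * nxs + pt$vz * nzs)
      Nf <- penetration_force_smooth(d, drate, MEM[k, ], 0, hd)
      if (forces) cforce[k, ] <- Nf
      ## normal + regularized Coulomb friction on the full point velocity
      vn <- sqrt(pt$vx^2 + pt$vz^2 + 1e-6)
      Fx <- Nf * nxs - hd$mu * Nf * pt$vx / vn
      Fz <- Nf * nzs - hd$mu * Nf * pt$vz / vn
      rho <- rho - planar_point_wrench(st, kin, cp$seg, pt, Fx, Fz, root_rq, nq)
      RES[L$idx_mem[k], ] <- MEMd[k, ] - memory_rate(d, MEM[k, ])
    }
  }

  ## air drag at the root (pelvis) centre of mass
  wc <- rot2v(kin$th[[1]], st$com_x[1], st$com_z[1])
  vrx <- kin$Vx[[1]] + kin$thd[[1]] * wc$z - bundle$aero$wind[1]
  vrz <- kin$Vz[[1]] - kin$thd[[1]] * wc$x - bundle$aero$wind[3]
  vmag <- sqrt(vrx^2 + vrz^2)
  cda <- 0.5 * bundle$aero$rho * bundle$aero$CdA
  Fdx <- -cda * vmag * vrx; Fdz <- -cda * vmag * vrz
  ptd <- list(x = comx[[1]], z = comz[[1]])
  rho <- rho - planar_point_wrench(st, kin, 1L, ptd, Fdx, Fdz, root_rq, nq)

  RES[L$idx_qd, ] <- rho
  RES <- RES * bundle$scales
  if (forces) list(residual = RES, f_tendon = f_tendon, contact_force = cforce,
                   kin = kin)
  else RES
}

## generalized force J^T F of a point force (Fx, Fz) applied at world point
## pt on segment i (n_q x N, positive = applied to the system)
planar_point_wrench <- function(st, kin, i, pt, Fx, Fz, root_rq, nq) {
  N <- kin$N
  out <- matrix(0, nq, N)
  out[root_rq - 2L, ] <- Fx
  out[root_rq - 1L, ] <- Fz
  for (j in seq_len(st$n_seg)) {
    if (!st$affects[i, j]) next
    jq <- st$rot_q[j]
    dx <- st$sign[j] * (pt$z - kin$Pz[[j]])
    dz <- -st$sign[j] * (pt$x - kin$Px[[j]])
    out[jq, ] <- dx * Fx + dz * Fz
  }
  out
}
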
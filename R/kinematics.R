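## Tree-recursive kinematics of the skier model: segment poses, Jacobians,
## velocities and accelerations.  Poses are exact; velocity-level quantities
## are obtained by high-order finite differencing of the pose map, which keeps
## the implementation generic over joint types (Euler-sequence ball joints,
## free joints, hinges) without joint-specific rate matrices.

joint_transform <- function(seg, jq) {
  if (length(jq)) jq <- jq * seg$signs
  switch(seg$kind,
    free6 = list(R = euler_zxy(jq[4], jq[5], jq[6]), p = jq[1:3]),
    ball3 = list(R = euler_zxy(jq[1], jq[2], jq[3]), p = c(0, 0, 0)),
    planar3 = list(R = rot_y(jq[3]), p = c(jq[1], 0, jq[2])),
    revolute1 = list(R = rot_axis(seg$axis, jq), p = c(0, 0, 0)),
    locked = list(R = seg$fixed_R, p = c(0, 0, 0)))
}

#' Forward kinematics of the skier model
#'
#' Composes joint transforms tree-recursively from the root (pelvis) and
#' returns the world pose of every segment.
#'
#' @param model A \code{skier_model}.
#' @param q Generalized coordinates (length \code{model$n_q}); rotations in
#'   rad, translations in m.
#' @return A list with \code{R} (3x3xN array of orientations), \code{p}
#'   (3xN segment-origin positions) and \code{joint_p} (world positions of
#'   the joints, equal to the segment origins).
#' @export
forward_kinematics <- function(model, q) {
  assert_that(length(q) == model$n_q,
              sprintf("q has length %d, model has %d coordinates",
                      length(q), model$n_q))
  n <- length(model$segments)
  R <- array(0, c(3, 3, n)); p <- matrix(0, 3, n)
  for (i in seq_len(n)) {
    seg <- model$segments[[i]]
    di <- joint_dof_indices(model, i)
    tf <- joint_transform(seg, q[di])
    pi_ <- model$parent[i]
    if (pi_ == 0L) {
      Rp <- diag(3); pp <- c(0, 0, 0)
    } else {
      Rp <- R[, , pi_]; pp <- p[, pi_]
    }
    R[, , i] <- Rp %*% tf$R
    p[, i] <- pp + Rp %*% (seg$origin + tf$p)
  }
  dimnames(p) <- list(NULL, names(model$segments))
  list(R = R, p = p, joint_p = p)
}

#' World position of segment centres of mass and the whole-body COM
#' @param model A \code{skier_model}.
#' @param q Generalized coordinates.
#' @return List with \code{com} (3-vector, m) and \code{segment_com} (3xN).
#' @export
center_of_mass <- function(model, q) {
  fk <- forward_kinematics(model, q)
  n <- length(model$segments)
  sc <- matrix(0, 3, n)
  m <- vapply(model$segments, `[[`, 0, "mass")
  for (i in seq_len(n))
    sc[, i] <- fk$p[, i] + fk$R[, , i] %*% model$segments[[i]]$com
  list(com = as.numeric(sc %*% m) / sum(m), segment_com = sc)
}

## Pose of all segments flattened to a single vector (for differentiation)
fk_flat <- function(model, q) {
  fk <- forward_kinematics(model, q)
  list(fk = fk, vec = c(fk$p, fk$R))
}

#' Segment rigid-body motion from (q, qd, qdd)
#'
#' Linear and angular velocity and acceleration of every segment frame and
#' centre of mass, computed by central finite differencing of the exact pose
#' map along the coordinate velocity (step \code{h}).  Accuracy is O(h^2) per
#' differentiation level (~1e-8 relative for smooth joint maps).
#'
#' @param model A \code{skier_model}.
#' @param q,qd,qdd Coordinates and their first/second time derivatives.
#' @param h Finite-difference step.
#' @return List of 3xN matrices: \code{v}, \code{a} (segment origin), \code{w},
#'   \code{wdot} (angular, world frame), \code{v_com}, \code{a_com}, plus the
#'   pose \code{fk}.
#' @export
segment_motion <- function(model, q, qd, qdd, h = 1e-5) {
  n <- length(model$segments)
  fk0 <- forward_kinematics(model, q)

  pose_rate <- function(qq, dq) {
    ## time derivative of (p, R) along coordinate rate dq at coordinates qq
    fp <- forward_kinematics(model, qq + h * dq)
    fm <- forward_kinematics(model, qq - h * dq)
    list(pd = (fp$p - fm$p) / (2 * h), Rd = (fp$R - fm$R) / (2 * h))
  }
  r1 <- pose_rate(q, qd)                       # velocity level
  ## acceleration level: d/dt of the velocity map = qd-transport + qdd term
  h2 <- 1e-4
  rp <- pose_rate(q + h2 * qd, qd)
  rm <- pose_rate(q - h2 * qd, qd)
  r2qd <- list(pd = (rp$pd - rm$pd) / (2 * h2), Rd = (rp$Rd - rm$Rd) / (2 * h2))
  rqdd <- pose_rate(q, qdd)
  pdd <- r2qd$pd + rqdd$pd
  Rdd <- r2qd$Rd + rqdd$Rd

  v <- r1$pd; a <- pdd
  w <- matrix(0, 3, n); wdot <- matrix(0, 3, n)
  v_com <- matrix(0, 3, n); a_com <- matrix(0, 3, n)
  for (i in seq_len(n)) {
    Ri <- fk0$R[, , i]
    Wd <- r1$Rd[, , i] %*% t(Ri)              # skew(w)
    w[, i] <- vee(Wd)
    ## d/dt(skew(w)) = Rdd R^T + Rd Rd^T' ... use skew(wdot) = Rdd R^T + Rd (Rd)^T
    Wdd <- Rdd[, , i] %*% t(Ri) + r1$Rd[, , i] %*% t(r1$Rd[, , i])
    wdot[, i] <- vee(Wdd)
    ci <- Ri %*% model$segments[[i]]$com
    v_com[, i] <- v[, i] + w[, i] %crs% ci
    a_com[, i] <- a[, i] + wdot[, i] %crs% ci + w[, i] %crs% (w[, i] %crs% ci)
  }
  list(fk = fk0, v = v, a = a, w = w, wdot = wdot, v_com = v_com, a_com = a_com)
}

## cross product helper
`%crs%` <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

#' Geometric Jacobians of every segment
#'
#' Columns are the world-frame linear (at segment COM) and angular velocity
#' per unit coordinate rate, by central differences of the pose map.
#'
#' @param model A \code{skier_model}; \code{q} coordinates.
#' @return List of arrays \code{Jv} (3 x n_q x N, COM linear) and \code{Jw}
#'   (3 x n_q x N, angular).
#' @export
segment_jacobians <- function(model, q, h = 1e-6) {
  n <- length(model$segments); nq <- model$n_q
  Jv <- array(0, c(3, nq, n)); Jw <- array(0, c(3, nq, n))
  fk0 <- forward_kinematics(model, q)
  com_w <- function(fk) {
    sapply(seq_len(n), function(i) fk$p[, i] + fk$R[, , i] %*% model$segments[[i]]$com)
  }
  for (j in seq_len(nq)) {
    e <- numeric(nq); e[j] <- h
    fp <- forward_kinematics(model, q + e)
    fm <- forward_kinematics(model, q - e)
    dcom <- (com_w(fp) - com_w(fm)) / (2 * h)
    for (i in seq_len(n)) {
      Jv[, j, i] <- dcom[, i]
      dR <- (fp$R[, , i] - fm$R[, , i]) / (2 * h)
      Jw[, j, i] <- vee(dR %*% t(fk0$R[, , i]))
    }
  }
  list(Jv = Jv, Jw = Jw, fk = fk0)
}

#' Joint-space mass matrix M(q)
#'
#' Assembled from segment Jacobians as
#' \eqn{M = \sum_i J_{v,i}^T m_i J_{v,i} + J_{\omega,i}^T I_i^w J_{\omega,i}}.
#' @param model A \code{skier_model}; \code{q} coordinates.
#' @return n_q x n_q symmetric matrix, kg·m² / kg.
#' @export
mass_matrix <- function(model, q) {
  J <- segment_jacobians(model, q)
  nq <- model$n_q
  M <- matrix(0, nq, nq)
  for (i in seq_along(model$segments)) {
    seg <- model$segments[[i]]
    Ri <- J$fk$R[, , i]
    Iw <- Ri %*% seg$inertia %*% t(Ri)
    M <- M + seg$mass * crossprod(J$Jv[, , i]) +
      t(J$Jw[, , i]) %*% Iw %*% J$Jw[, , i]
  }
  (M + t(M)) / 2
}
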
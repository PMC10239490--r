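## Segmented-ski model: a chain of rigid segments joined by revolute joints
## with rotational spring-damper elements, a configured camber shape, and the
## side-cut edge geometry used by the contact model.

#' Build a segmented ski
#'
#' Splits the ski into \code{n_segments} rigid segments connected by
#' \code{n_segments - 1} revolute (bending) joints, each carrying a
#' rotational spring-damper \eqn{M_j = -k(\theta_j - \theta_{camber}) -
#' c\dot\theta_j}.  The unloaded equilibrium reproduces the configured camber
#' arc.  Torsion is neglected.
#'
#' @param spec List: \code{n_segments} (>= 2), \code{length} (total, m),
#'   \code{mass} (total, kg), \code{width} (m), \code{camber_height} (m),
#'   \code{stiffness} (N·m/rad per joint), \code{damping} (N·m·s/rad),
#'   \code{side_cut_radius} (m).
#' @return A \code{ski_chain}: segment table, camber joint angles, and the
#'   passive joint-moment function \code{$joint_moment(theta, thetadot)}.
#' @export
build_ski <- function(spec) {
  assert_that(!is.null(spec$n_segments) && spec$n_segments >= 2,
              "ski must have at least 2 segments")
  assert_that(spec$stiffness >= 0 && spec$damping >= 0,
              "ski joint stiffness and damping must be nonnegative")
  assert_that(spec$side_cut_radius > 0, "side_cut_radius must be > 0")
  n <- as.integer(spec$n_segments)
  seg_len <- spec$length / n
  seg_mass <- spec$mass / n
  ## camber arc: chord L, sagitta h -> total turning angle L/R = 8h/L spread
  ## uniformly over the internal joints
  h <- spec$camber_height %||% 0
  total_turn <- if (h > 0) 8 * h / spec$length else 0
  theta_camber <- rep(total_turn / max(n - 1, 1), n - 1)
  k <- spec$stiffness; cdamp <- spec$damping
  structure(list(
    spec = spec, n_segments = n,
    seg_length = rep(seg_len, n), seg_mass = rep(seg_mass, n),
    width = spec$width, side_cut_radius = spec$side_cut_radius,
    theta_camber = theta_camber,
    stiffness = rep(k, n - 1), damping = rep(cdamp, n - 1),
    total_mass = spec$mass,
    joint_moment = function(theta, thetadot)
      -k * (theta - theta_camber) - cdamp * thetadot),
    class = "ski_chain")
}

#' @export
print.ski_chain <- function(x, ...) {
  cat(sprintf("<ski_chain>: %d segments, %.2f m, %.2f kg, side cut %.0f m\n",
              x$n_segments, sum(x$seg_length), x$total_mass, x$side_cut_radius))
  invisible(x)
}

#' Multibody model of a free ski chain
#'
#' Builds a planar rigid-body model of the segmented ski alone: segment 1
#' carries the planar free joint, the remaining segments attach through
#' revolute bending joints with the chain's spring-damper elements as
#' passive joint moments (neutral angles reproduce the camber shape).  Used
#' for bench tests of the chain dynamics (free oscillation, energy audits).
#'
#' @param ski A \code{ski_chain}; \code{damping} optionally overrides the
#'   joint damping (e.g. 0 for conservative tests).
#' @return A \code{skier_model} of the chain.
#' @export
ski_chain_model <- function(ski, damping = NULL) {
  n <- ski$n_segments
  segs <- vector("list", n)
  Iy <- function(m, l) m * l^2 / 12
  for (i in seq_len(n)) {
    li <- ski$seg_length[i]; mi <- ski$seg_mass[i]
    segs[[i]] <- list(
      name = paste0("seg", i),
      parent = if (i == 1) "world" else paste0("seg", i - 1),
      joint = if (i == 1) list(name = "base", kind = "planar3") else
        list(name = paste0("bend", i - 1), kind = "revolute1",
             axis = c(0, 1, 0),
             passive = list(stiffness = ski$stiffness[i - 1],
                            damping = if (is.null(damping))
                              ski$damping[i - 1] else damping,
                            neutral = -ski$theta_camber[i - 1])),
      origin = if (i == 1) c(0, 0, 0) else c(li, 0, 0),
      mass = mi,
      com = c(li / 2, 0, 0),
      inertia = c(1e-5, Iy(mi, li), Iy(mi, li)))
  }
  build_skier_model(list(name = "ski_chain", segments = segs,
                         subject = list(mass_kg = ski$total_mass)))
}

#' Static bending equilibrium of a ski chain
#'
#' Solves the nonlinear static torque balance of the spring chain clamped at
#' segment 1 under point loads applied at segment endpoints (perpendicular to
#' each segment), by damped fixed-point iteration on the joint angles.
#'
#' @param ski A \code{ski_chain}.
#' @param tip_load Transverse load at the free tip, N (positive = towards the
#'   camber side).
#' @return Joint angles theta (rad) at equilibrium.
#' @export
ski_static_deflection <- function(ski, tip_load) {
  n <- ski$n_segments
  theta <- ski$theta_camber
  for (it in 1:200) {
    ## geometry: cumulative angles and joint positions along the chain
    phi <- cumsum(c(0, theta))
    ends <- matrix(0, 2, n + 1)
    for (i in 1:n)
      ends[, i + 1] <- ends[, i] + ski$seg_length[i] * c(cos(phi[i]), sin(phi[i]))
    tip <- ends[, n + 1]
    ## load perpendicular to the last segment
    dirF <- c(-sin(phi[n]), cos(phi[n])) * tip_load
    tau <- vapply(1:(n - 1), function(j) {
      r <- tip - ends[, j + 1]
      r[1] * dirF[2] - r[2] * dirF[1]
    }, 0)
    theta_new <- ski$theta_camber + tau / ski$stiffness
    if (max(abs(theta_new - theta)) < 1e-12) { theta <- theta_new; break }
    theta <- theta + 0.5 * (theta_new - theta)
  }
  theta
}

#' Side-cut lateral edge offset
#'
#' Lateral position of the running edge relative to the waist, from the
#' circular side-cut arc of radius \code{side_cut_radius}: the edge bulges by
#' the circular sagitta towards tip and tail.
#'
#' @param x Longitudinal station from mid-ski, m.
#' @param ski A \code{ski_chain} or list with \code{side_cut_radius} and
#'   \code{spec$length}.
#' @return Outward lateral offset of the edge relative to mid-ski, m.
#' @export
side_cut_offset <- function(x, ski) {
  R <- ski$side_cut_radius
  half <- sum(ski$seg_length) / 2
  ## sagitta of the arc between the contact points, measured from the waist
  (R - sqrt(pmax(R^2 - x^2, 0))) - (R - sqrt(R^2 - half^2))
}

## ---- snow surface ----------------------------------------------------------

#' Construct a snow surface
#'
#' Height function z = s(x, y) over the world frame (x downhill-horizontal,
#' y transverse, z up) plus the hardness parameters of the hypoplastic
#' penetration law.  The default synthetic surface is an inclined plane
#' \code{z = -tan(slope) * x}, optionally perturbed by smooth bumps.
#'
#' @param slope_angle_deg Slope angle, degrees.
#' @param hardness List: \code{k_load} (virgin loading stiffness, N/m of
#'   depth per contact point), \code{unload_ratio} (unloading/reloading
#'   stiffness ratio, >= 1), \code{rate_coeff} (N·s/m), \code{shear_coeff}
#'   (N/m of depth), \code{mu} (Coulomb friction coefficient).
#' @param bumps Optional function(x, y) added to the plane height, m.
#' @return A \code{snow_surface} with \code{$height(x,y)}, \code{$grad(x,y)}
#'   and \code{$hardness}.
#' @export
make_snow_surface <- function(slope_angle_deg = 12.3,
                              hardness = list(),
                              bumps = NULL) {
  hd <- utils::modifyList(list(k_load = 1.5e4, unload_ratio = 4,
                               rate_coeff = 1.5e3, shear_coeff = 6e4,
                               mu = 0.08), hardness)
  assert_that(hd$k_load > 0 && hd$unload_ratio >= 1,
              "loading stiffness must be > 0 and unloading ratio >= 1")
  assert_that(slope_angle_deg > 0 - 1e-9 && slope_angle_deg < 45,
              "slope angle must lie in [0, 45) degrees")
  slope <- deg2rad(slope_angle_deg)
  tn <- tan(slope)
  height <- function(x, y) {
    z <- -tn * x
    if (!is.null(bumps)) z <- z + bumps(x, y)
    z
  }
  grad <- function(x, y) {
    gx <- rep(-tn, length(x)); gy <- rep(0, length(x))
    if (!is.null(bumps)) {
      h <- 1e-5
      gx <- gx + (bumps(x + h, y) - bumps(x - h, y)) / (2 * h)
      gy <- gy + (bumps(x, y + h) - bumps(x, y - h)) / (2 * h)
    }
    list(gx = gx, gy = gy)
  }
  structure(list(slope_angle = slope, height = height, grad = grad,
                 hardness = hd), class = "snow_surface")
}

#' Contact kinematics of a ski segment edge
#'
#' Locates the loaded edge point from the side-cut profile, and computes the
#' edging angle (between ski base plane and surface tangent plane), the
#' penetration depth of the edge into the snow along the surface normal
#' (clamped at zero out of contact), the penetration rate, and the edge
#' direction.
#'
#' @param pose List with \code{R} (3x3 ski-segment orientation; x along the
#'   ski, y towards the left edge, z base-normal up) and \code{p} (3-vector
#'   segment reference point, m).
#' @param vel List with \code{v} (3-vector m/s) and \code{w} (3-vector rad/s)
#'   of the segment.
#' @param surf A \code{snow_surface}.
#' @param ski A \code{ski_chain} (side-cut geometry).
#' @param station Longitudinal station of this segment from mid-ski, m.
#' @param edge_side +1 for the left edge (+y), -1 for the right edge.
#' @return A \code{contact_kinematics} list: \code{depth}, \code{rate},
#'   \code{edging_angle}, \code{edge_direction}, \code{point},
#'   \code{velocity}, \code{normal}.
#' @export
edge_contact_kinematics <- function(pose, vel, surf, ski, station = 0,
                                    edge_side = -1) {
  y_off <- (ski$width / 2 + side_cut_offset(station, ski)) * edge_side
  pt_local <- c(0, y_off, 0)
  pt <- as.numeric(pose$p + pose$R %*% pt_local)
  g <- surf$grad(pt[1], pt[2])
  nrm <- c(-g$gx, -g$gy, 1); nrm <- nrm / sqrt(sum(nrm^2))
  zski <- pose$R[, 3]
  ca <- sum(zski * nrm)
  edging <- acos(pmin(pmax(abs(ca), -1), 1))
  vpt <- as.numeric(vel$v + vel$w %crs% (pose$R %*% pt_local))
  d <- (surf$height(pt[1], pt[2]) - pt[3]) / sqrt(1 + g$gx^2 + g$gy^2)
  structure(list(depth = max(d, 0), rate = -sum(vpt * nrm),
                 edging_angle = edging,
                 edge_direction = as.numeric(pose$R[, 1]),
                 point = pt, velocity = vpt, normal = nrm,
                 in_contact = d > 0),
            class = "contact_kinematics")
}
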
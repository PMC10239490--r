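## Ski-snow contact forces: hypoplastic penetration normal force with
## loading/unloading memory, edge-orthogonal shear, regularized Coulomb
## friction, and air drag.  Exact (branchy) forms here are the reference
## semantics; the collocation engine uses smooth counterparts (suffix
## `_smooth`) with the same parameters.

## smooth ramp 0..1 over depth scale d_eps (contact engagement)
contact_gate <- function(d, d_eps = 1e-3) {
  dp <- softplus(d, beta = 2 / d_eps)
  dp / (dp + d_eps)
}

## edging-angle reduction of the bearing stiffness: an edged ski presents a
## narrower bearing band, lowering the force at equal depth
edging_factor <- function(edging_angle) 0.3 + 0.7 * cos(edging_angle)

#' Hypoplastic penetration force
#'
#' Normal snow reaction at a ski-segment edge.  The elastic part follows a
#' two-branch incremental law: virgin loading with stiffness \code{k_load}
#' while the depth exceeds the maximum previously compressed depth (the
#' hypoplastic memory, which then updates), and a stiffer
#' unloading/reloading branch of slope \code{unload_ratio * k_load} anchored
#' at the memory point otherwise — once compressed, the snow stays
#' compressed, so re-penetrating the groove is easier than virgin snow.  A
#' rate term \code{rate_coeff * rate} adds penetration-speed dissipation; the
#' total is floored at zero and scaled by a smooth edging-angle factor.
#'
#' @param kin A \code{contact_kinematics} (or list with \code{depth},
#'   \code{rate}, \code{edging_angle}).
#' @param state Hypoplastic memory: list with \code{max_depth} (m, >= 0).
#' @param surf A \code{snow_surface} (hardness parameters).
#' @return List with \code{force} (N, >= 0, acting along the surface normal),
#'   \code{state} (updated memory), \code{branch} ("virgin" or "reload").
#' @export
penetration_force <- function(kin, state, surf) {
  hd <- surf$hardness
  d <- kin$depth; m <- max(state$max_depth, 0)
  if (d <= 0)
    return(list(force = 0, state = state, branch = "none"))
  k <- hd$k_load; ku <- hd$unload_ratio * k
  f_el <- min(k * d, k * m + ku * (d - m))
  f_el <- max(f_el, 0)
  f <- max(f_el * edging_factor(kin$edging_angle) + hd$rate_coeff * kin$rate, 0)
  list(force = f,
       state = list(max_depth = max(m, d)),
       branch = if (d >= m) "virgin" else "reload")
}

## vectorized smooth penetration force for the collocation engine; memory m
## is carried as a state variable and advanced by its own residual row.
## Smoothing uses algebraic (sqrt) blends whose tails vanish like 1/x, so
## forces are numerically zero when the ski is clearly airborne.
smin_alg <- function(a, b, eps) 0.5 * (a + b - sqrt((a - b)^2 + eps^2))
## one-sided C1 floor: exactly zero for x <= 0, quadratic blend to x - eps/2
smax0_q <- function(x, eps) {
  lo <- (x > 0) & (x < eps)
  lo * x^2 / (2 * eps) + (x >= eps) * (x - eps / 2)
}

penetration_force_smooth <- function(d, rate, m, edging, hd, d_eps = 1e-3) {
  k <- hd$k_load; ku <- hd$unload_ratio * k
  eps <- k * d_eps
  ## smooth min of the two branches, floored at 0 with a one-sided blend so
  ## airborne segments carry exactly zero force
  a <- k * d
  b <- k * m + ku * (d - m)
  f_el <- smax0_q(smin_alg(a, b, eps), eps)
  smax0_q(f_el * edging_factor(edging) +
            hd$rate_coeff * rate * contact_gate(d, d_eps), eps)
}

## residual row advancing the hypoplastic memory state: mdot tracks the
## running maximum of the depth, rising only while d > m
memory_rate <- function(d, m, beta_mem = 50) beta_mem * softplus(d - m, beta = 2000)

#' Edge-orthogonal shear force
#'
#' Resistance against lateral skidding: magnitude proportional to the
#' penetration depth, directed orthogonal to the ski edge within the surface
#' tangent plane, opposing the lateral velocity component, with a
#' saturated-viscous regularization near zero slip.
#'
#' @param kin A \code{contact_kinematics}.
#' @param shear_coefficient N per m of penetration depth.
#' @param v_eps Slip-speed regularization, m/s.
#' @return Force 3-vector, N.
#' @export
shear_force <- function(kin, shear_coefficient, v_eps = 1e-3) {
  assert_that(shear_coefficient >= 0, "shear coefficient must be >= 0")
  if (kin$depth <= 0) return(c(0, 0, 0))
  t_lat <- kin$edge_direction %crs% kin$normal
  nl <- sqrt(sum(t_lat^2))
  if (nl < 1e-12) return(c(0, 0, 0))
  t_lat <- t_lat / nl
  v_lat <- sum(kin$velocity * t_lat)
  mag <- shear_coefficient * kin$depth
  -mag * t_lat * v_lat / sqrt(v_lat^2 + v_eps^2)
}

#' Regularized Coulomb friction
#'
#' Magnitude \code{mu * normal_force}, antiparallel to the segment velocity,
#' smoothly regularized below a small slip speed so the force vanishes at
#' zero velocity and the model stays differentiable.
#'
#' @param normal_force N (>= 0).
#' @param segment_velocity 3-vector, m/s.
#' @param mu Friction coefficient (snow default 0.08).
#' @param v_eps Regularization speed, m/s.
#' @return Force 3-vector, N; always dissipative (force · v <= 0).
#' @export
friction_force <- function(normal_force, segment_velocity, mu = 0.08,
                           v_eps = 1e-3) {
  assert_that(normal_force >= 0, "normal force must be >= 0")
  v <- segment_velocity
  -mu * normal_force * v / sqrt(sum(v^2) + v_eps^2)
}

#' Aerodynamic drag on the skier
#'
#' Quadratic drag \eqn{F = \tfrac12 \rho C_dA \|v_{rel}\|^2} antiparallel to
#' the velocity relative to the wind, applied at the pelvis-segment centre of
#' mass (the segment closest to the whole-body COM).
#'
#' @param com_velocity 3-vector, m/s.
#' @param params List: \code{CdA} (m², default 0.3), \code{rho} (kg/m³,
#'   default 1.07), \code{wind} (3-vector m/s, default zero).
#' @return Force 3-vector, N.
#' @export
air_drag <- function(com_velocity, params = list()) {
  p <- utils::modifyList(list(CdA = 0.3, rho = 1.07, wind = c(0, 0, 0)), params)
  assert_that(p$CdA >= 0 && p$rho > 0, "CdA must be >= 0 and rho > 0")
  vrel <- com_velocity - p$wind
  -0.5 * p$rho * p$CdA * sqrt(sum(vrel^2)) * vrel
}
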
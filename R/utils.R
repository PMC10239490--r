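#' @keywords internal
"_PACKAGE"

## Small numeric and validation helpers shared across the package.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Stop with a classed error
#'
#' All user-facing validation failures carry a class so callers (and the
#' pipeline runner) can distinguish validation errors from structural or
#' numeric errors.
#' @noRd
ski_stop <- function(msg, class) {
  stop(structure(class = c(class, "skiturn_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_that <- function(ok, msg, class = "skiturn_validation_error") {
  if (!isTRUE(ok)) ski_stop(msg, class)
  invisible(TRUE)
}

## Smooth regularizations used to keep the collocation residual continuously
## differentiable: a softplus with sharpness beta and a smoothed |x|.
softplus <- function(x, beta = 50) {
  # numerically safe: softplus(x) = max(x,0) + log1p(exp(-|beta x|))/beta
  pmax(x, 0) + log1p(exp(-abs(beta * x))) / beta
}

smooth_abs <- function(x, eps = 1e-3) sqrt(x * x + eps * eps)

## Rotation matrices (world frame: x downhill-horizontal, y transverse, z up)
rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}
rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}
rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

#' Extrinsic Z-X-Y Euler rotation (tilt, list, rotation)
#'
#' Pelvis and ball joints use an extrinsic Z-X-Y sequence: first a rotation
#' about the fixed z axis, then about fixed x, then about fixed y, i.e.
#' \code{R = Ry(c) Rx(b) Rz(a)}.
#' @noRd
euler_zxy <- function(a, b, c) rot_y(c) %*% rot_x(b) %*% rot_z(a)

## Rodrigues rotation about a unit axis
rot_axis <- function(axis, a) {
  ca <- cos(a); sa <- sin(a)
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * ca + sa * K + (1 - ca) * (u %o% u)
}

vee <- function(W) c(W[3, 2], W[1, 3], W[2, 1])
skew <- function(v) matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)

## gravity constant, m/s^2, +z up world frame
GRAVITY <- c(0, 0, -9.81)

#' Path to a shipped configuration or coefficient file
#' @param file File name under the package's \code{extdata} directory.
#' @return Absolute path to the file.
#' @export
ski_extdata <- function(file) {
  p <- system.file("extdata", file, package = "skiturn")
  if (!nzchar(p)) ski_stop(sprintf("shipped file '%s' not found", file),
                           "skiturn_io_error")
  p
}
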
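## Model bundle: skier model + muscle set + snow surface + ski + aerodynamic
## parameters, with the state-vector layout x = [q, qdot, s, a] plus the
## per-contact-point hypoplastic memory variables, and bounds for the
## optimizer.

#' Assemble a simulation bundle
#'
#' Combines the rigid-body model, the muscle set, the snow surface, the ski
#' geometry and aerodynamic parameters into a single object carrying the
#' state layout used by the implicit dynamics: \code{x = [q, qdot, s, a,
#' mem]}, where \code{s} are projected fiber lengths, \code{a} activations
#' and \code{mem} the hypoplastic contact-memory depths (one per contact
#' point), advanced as ordinary states so the optimizer sees a fully
#' state-defined system.
#'
#' @param model A \code{skier_model} (or preset name).
#' @param muscles A \code{muscle_set}, path to a muscle table, or NULL.
#' @param surf A \code{snow_surface} (default: 12.3 degree plane).
#' @param ski A \code{ski_chain} or spec list (default: shipped nominal ski).
#' @param aero List with \code{CdA}, \code{rho}, \code{wind}.
#' @return A \code{ski_bundle}.
#' @export
ski_bundle <- function(model, muscles = NULL,
                       surf = make_snow_surface(),
                       ski = NULL,
                       aero = list(CdA = 0.3, rho = 1.07, wind = c(0, 0, 0))) {
  if (is.character(model)) model <- build_skier_model(model)
  if (is.character(muscles)) muscles <- read_muscle_table(muscles)
  if (!is.null(muscles)) {
    qref <- stats::setNames(rep(0, model$n_q), model$coord_names)
    rp <- model$config$reference_posture
    if (!is.null(rp)) for (nm in names(rp)) qref[nm] <- rp[[nm]]
    muscles <- calibrate_muscle_lengths(muscles, qref)
    miss <- setdiff(unique(unlist(muscles$coords)), model$coord_names)
    assert_that(length(miss) == 0,
                paste("muscle table spans unknown coordinates:",
                      paste(miss, collapse = ", ")))
  }
  if (is.null(ski)) ski <- build_ski(yaml::read_yaml(ski_extdata("ski_nominal.yaml")))
  if (is.list(ski) && !inherits(ski, "ski_chain")) ski <- build_ski(ski)
  cmp <- compress_model(model)
  ## contact points live on compressed segments
  cps <- list()
  for (i in seq_along(cmp$segments)) {
    cp <- cmp$segments[[i]]$contact_points
    if (!is.null(cp))
      for (k in seq_len(ncol(cp)))
        cps[[length(cps) + 1L]] <- list(seg = i, local = cp[, k],
                                        station = cp[1, k])
  }
  n_m <- if (is.null(muscles)) 0L else muscles$n
  n_q <- model$n_q
  n_c <- length(cps)
  layout <- list(
    n_q = n_q, n_m = n_m, n_c = n_c,
    idx_q = seq_len(n_q), idx_qd = n_q + seq_len(n_q),
    idx_s = 2L * n_q + seq_len(n_m),
    idx_a = 2L * n_q + n_m + seq_len(n_m),
    idx_mem = 2L * n_q + 2L * n_m + seq_len(n_c),
    n_x = 2L * n_q + 2L * n_m + n_c, n_u = n_m)
  b <- structure(list(model = model, compressed = cmp, muscles = muscles,
                      surf = surf, ski = ski, aero = aero,
                      contact_points = cps, layout = layout),
                 class = "ski_bundle")
  b$engine <- if (planar_compatible(b)) "planar" else "generic"
  if (b$engine == "planar") b$planar <- planar_structure(b)
  b$bounds <- default_bounds(b)
  b$scales <- residual_scales(b)
  b
}

#' @export
print.ski_bundle <- function(x, ...) {
  cat(sprintf("<ski_bundle>: %d DOF, %d muscles, %d contact points, engine '%s'\n",
              x$layout$n_q, x$layout$n_m, x$layout$n_c, x$engine))
  invisible(x)
}

## state bounds for the NLP: generous anatomical coordinate ranges, fiber
## lengths in (0.3, 1.7) l_opt (projected), activations/excitations in [0,1]
default_bounds <- function(b) {
  L <- b$layout
  lb <- numeric(L$n_x); ub <- numeric(L$n_x)
  lb[L$idx_q] <- -50; ub[L$idx_q] <- 50
  isang <- !grepl("_t[xyz]$|_tz$", b$model$coord_names)
  lb[L$idx_q][isang] <- -pi; ub[L$idx_q][isang] <- pi
  lb[L$idx_qd] <- -100; ub[L$idx_qd] <- 100
  if (L$n_m > 0) {
    ## projected fiber length: wide enough that slack muscles can shorten
    ## below the force-producing range without pinning the contraction
    ## equality on the bound
    lo <- b$muscles$table$l_opt
    cp <- cos(b$muscles$table$pennation_opt)
    lb[L$idx_s] <- 0.05 * lo * cp; ub[L$idx_s] <- 2.0 * lo
    lb[L$idx_a] <- 0; ub[L$idx_a] <- 1
  }
  if (L$n_c > 0) { lb[L$idx_mem] <- 0; ub[L$idx_mem] <- 1 }
  list(x_lower = lb, x_upper = ub,
       u_lower = rep(0, L$n_u), u_upper = rep(1, L$n_u))
}

## row scaling of the implicit residual, so a scaled defect tolerance of
## 1e-6 has comparable meaning across equation blocks
residual_scales <- function(b) {
  L <- b$layout
  s <- numeric(L$n_x)
  s[L$idx_q] <- 1
  s[L$idx_qd] <- 1 / (b$model$total_mass * 9.81)
  if (L$n_m > 0) { s[L$idx_s] <- 1; s[L$idx_a] <- 0.05 }
  if (L$n_c > 0) s[L$idx_mem] <- 0.1
  s
}

#' Dynamically consistent initial state
#'
#' Builds x0 = [q, qdot, s, a, mem] at a given posture and downhill speed:
#' fiber states solved so the contraction residual vanishes isometrically at
#' the baseline activation, memory set to current penetration depth.
#'
#' @param bundle A \code{ski_bundle}.
#' @param posture Named coordinate values (rad / m); unnamed coordinates 0.
#' @param qd Named coordinate velocities (default all zero).
#' @param a0 Baseline activation.
#' @return Numeric state vector of length \code{bundle$layout$n_x}.
#' @export
bundle_initial_state <- function(bundle, posture = NULL, qd = NULL, a0 = 0.02) {
  L <- bundle$layout; mdl <- bundle$model
  q <- stats::setNames(rep(0, L$n_q), mdl$coord_names)
  if (!is.null(posture)) for (nm in names(posture)) q[nm] <- posture[[nm]]
  qdv <- stats::setNames(rep(0, L$n_q), mdl$coord_names)
  if (!is.null(qd)) for (nm in names(qd)) qdv[nm] <- qd[[nm]]
  x <- numeric(L$n_x)
  x[L$idx_q] <- q; x[L$idx_qd] <- qdv
  if (L$n_m > 0) {
    a0 <- rep_len(a0, L$n_m)
    for (i in seq_len(L$n_m)) {
      sp <- muscle_spec(bundle$muscles, i)
      g <- muscle_tendon_length_and_moment_arms(q, sp)
      f <- function(s) contraction_residual(list(s = s, a = a0[i]), 0, g$l_mt, sp)$residual
      lo <- 0.31 * sp$l_opt * cos(sp$pennation_opt); hi <- 1.69 * sp$l_opt
      s0 <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root,
                     error = function(e) sp$l_opt * cos(sp$pennation_opt))
      x[L$idx_s[i]] <- s0
      x[L$idx_a[i]] <- a0[i]
    }
  }
  if (L$n_c > 0 && bundle$engine == "planar") {
    pc <- planar_contact_geometry(bundle, matrix(x[L$idx_q], ncol = 1),
                                  matrix(x[L$idx_qd], ncol = 1))
    x[L$idx_mem] <- pmax(pc$depth[, 1], 0)
  }
  x
}
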
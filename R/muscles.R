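## Three-element Hill-type muscles in the implicit formulation: the
## contraction state is the projected fiber length s (contractile-element
## length along the tendon line), activation follows first-order dynamics
## from the neural excitation u, and both dynamics are expressed as residuals
## f(state, state-dot, input) = 0 for use inside an implicit integrator or a
## collocation transcription.

HILL <- list(
  fl_width   = 0.45,   # Gaussian active force-length width (normalized)
  v_max      = 10,     # maximal shortening velocity, optimal lengths / s
  af         = 0.25,   # Hill force-velocity curvature (concentric)
  f_ecc      = 1.5,    # eccentric force asymptote (normalized)
  k_ecc      = 10,     # eccentric curvature, matches concentric slope at v=0
  pe_strain  = 0.6,    # passive element: strain at normalized force 1
  t_strain   = 0.04,   # tendon strain at f_max (end of quadratic toe)
  damping    = 0.01)   # normalized fiber damping, guarantees solvability at a=0

#' Read a muscle table
#'
#' Loads a delimited muscle table (one row per muscle) into a
#' \code{muscle_set}.  Columns: \code{name}, \code{f_max} (N), \code{l_opt}
#' (m), \code{l_slack} (m), \code{pennation_opt} (rad), \code{tau_act},
#' \code{tau_deact} (s), \code{coords} (semicolon-separated spanned
#' generalized-coordinate names) and \code{arms} (semicolon-separated
#' per-coordinate moment-arm polynomials, space-separated coefficients in m,
#' constant term first).  The optional \code{l_ref} column gives the
#' musculotendon length at the model's zero configuration; if absent it is
#' calibrated with \code{\link{calibrate_muscle_lengths}}.
#'
#' @param path CSV file path, or a data.frame with the same columns.
#' @return A \code{muscle_set} object.
#' @export
read_muscle_table <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "f_max", "l_opt", "l_slack", "pennation_opt",
            "tau_act", "tau_deact", "coords", "arms")
  assert_that(all(need %in% names(df)),
              paste("muscle table must have columns:", paste(need, collapse = ", ")))
  assert_that(all(df$f_max > 0) && all(df$l_opt > 0) && all(df$l_slack >= 0),
              "f_max and l_opt must be > 0 and l_slack >= 0")
  assert_that(all(df$tau_act > 0) && all(df$tau_act <= df$tau_deact),
              "time constants must satisfy 0 < tau_act <= tau_deact")
  coords <- strsplit(df$coords, ";", fixed = TRUE)
  arms <- lapply(strsplit(df$arms, ";", fixed = TRUE), function(polys)
    lapply(polys, function(p) as.numeric(strsplit(trimws(p), "\\s+")[[1]])))
  for (i in seq_len(nrow(df)))
    assert_that(length(coords[[i]]) == length(arms[[i]]),
                sprintf("muscle '%s': coords and arms disagree", df$name[i]))
  structure(list(
    table = df, n = nrow(df), names = df$name,
    coords = coords, arms = arms,
    l_ref = if ("l_ref" %in% names(df)) df$l_ref else rep(NA_real_, nrow(df))),
    class = "muscle_set")
}

#' @export
print.muscle_set <- function(x, ...) {
  cat(sprintf("<muscle_set>: %d Hill-type muscles\n", x$n)); invisible(x)
}

#' Number of muscles in a set
#' @param mset A \code{muscle_set}.
#' @export
muscle_count <- function(mset) mset$n

## antiderivative of a moment-arm polynomial, evaluated at angle q
arm_poly_integral <- function(coef, q) {
  s <- 0
  for (k in seq_along(coef)) s <- s + coef[k] * q^k / k
  s
}
arm_poly_eval <- function(coef, q) {
  s <- 0
  for (k in seq_along(coef)) s <- s + coef[k] * q^(k - 1)
  s
}

#' Musculotendon length and moment arms of one muscle
#'
#' The path geometry is a polynomial-moment-arm surrogate: each spanned
#' coordinate carries a moment-arm polynomial r_c(q_c) (m), and the
#' musculotendon length is \eqn{l_{mt}(q) = l_{ref} - \sum_c \int_0^{q_c}
#' r_c(\xi) d\xi}, so that the moment arm equals \eqn{-\partial l_{mt} /
#' \partial q_c} identically.
#'
#' @param q Named generalized-coordinate vector (names are coordinate
#'   labels), or a plain vector with \code{coord_names} supplied.
#' @param spec One row of a \code{muscle_set} (list with \code{l_ref},
#'   \code{coords}, \code{arms}).
#' @return List with \code{l_mt} (m) and \code{moment_arms} (named, m).
#' @export
muscle_tendon_length_and_moment_arms <- function(q, spec) {
  assert_that(!is.null(names(q)), "q must be a named coordinate vector")
  miss <- setdiff(spec$coords, names(q))
  assert_that(length(miss) == 0,
              paste("coordinates not in q:", paste(miss, collapse = ", ")))
  l <- spec$l_ref
  arms <- numeric(length(spec$coords)); names(arms) <- spec$coords
  for (j in seq_along(spec$coords)) {
    qc <- q[[spec$coords[j]]]
    l <- l - arm_poly_integral(spec$arms[[j]], qc)
    arms[j] <- arm_poly_eval(spec$arms[[j]], qc)
  }
  list(l_mt = l, moment_arms = arms)
}

#' Extract one muscle's spec from a set
#' @param mset A \code{muscle_set}; \code{i} index or name.
#' @export
muscle_spec <- function(mset, i) {
  if (is.character(i)) i <- match(i, mset$names)
  r <- mset$table[i, ]
  list(name = r$name, f_max = r$f_max, l_opt = r$l_opt, l_slack = r$l_slack,
       pennation_opt = r$pennation_opt, tau_act = r$tau_act,
       tau_deact = r$tau_deact, coords = mset$coords[[i]],
       arms = mset$arms[[i]], l_ref = mset$l_ref[i])
}

#' Calibrate reference musculotendon lengths
#'
#' Sets each muscle's \code{l_ref} so that at the supplied reference posture
#' the fiber sits at its optimal length and the tendon at its slack length
#' (zero passive force), i.e. \code{l_mt(q_ref) = l_opt cos(pennation) +
#' l_slack}.  Shipped tables leave \code{l_ref} empty and are calibrated
#' against the preset's reference posture at load time.
#'
#' @param mset A \code{muscle_set}; \code{q_ref} named coordinate vector.
#' @return The calibrated \code{muscle_set}.
#' @export
calibrate_muscle_lengths <- function(mset, q_ref) {
  for (i in seq_len(mset$n)) {
    if (!is.na(mset$l_ref[i])) next
    drop <- 0
    for (j in seq_along(mset$coords[[i]])) {
      qc <- q_ref[[mset$coords[[i]][j]]]
      drop <- drop + arm_poly_integral(mset$arms[[i]][[j]], qc)
    }
    r <- mset$table[i, ]
    mset$l_ref[i] <- r$l_opt * cos(r$pennation_opt) + r$l_slack + drop
  }
  mset$table$l_ref <- mset$l_ref
  mset
}

## ---- activation dynamics ---------------------------------------------------

#' Activation-dynamics residual
#'
#' First-order lag from neural excitation u to activation a with faster
#' activation than deactivation, in implicit form:
#' \deqn{res = \dot a - (u - a)\left(\frac{u}{\tau_{act}} +
#'   \frac{1-u}{\tau_{deact}}\right)}
#' The residual is zero on trajectories of the activation dynamics; the
#' steady state is a = u.
#'
#' @param a Activation in [0,1]; \code{adot} its time derivative (1/s);
#'   \code{u} excitation in [0,1].
#' @param spec List with \code{tau_act}, \code{tau_deact} (s).  All arguments
#'   vectorized.
#' @return Residual, 1/s.
#' @export
activation_residual <- function(a, adot, u, spec) {
  adot - (u - a) * (u / spec$tau_act + (1 - u) / spec$tau_deact)
}

## ---- contraction dynamics --------------------------------------------------

tendon_force_norm <- function(eps, e0 = HILL$t_strain) {
  ## quadratic toe up to e0 (force 1 at e0), then linear with matched slope
  epos <- (eps + abs(eps)) / 2
  toe <- epos <= e0
  toe * (epos / e0)^2 + (!toe) * (1 + (2 / e0) * (epos - e0))
}

force_length_active <- function(ltilde) exp(-((ltilde - 1) / HILL$fl_width)^2)

force_length_passive <- function(ltilde)
  (pmax(ltilde - 1, 0) / HILL$pe_strain)^2

force_velocity <- function(vtilde) {
  neg <- vtilde < 0
  vm <- vtilde * neg; vp <- vtilde - vm
  conc <- (1 + vm) / (1 - vm / HILL$af)
  ecc <- HILL$f_ecc - (HILL$f_ecc - 1) / (1 + HILL$k_ecc * vp)
  neg * conc + (!neg) * ecc
}

#' Contraction-dynamics residual of a Hill-type muscle
#'
#' Force balance between the tendon (quadratic-toe-then-linear elastic curve,
#' strain \code{0.04} at maximal isometric force) and the fiber (Gaussian
#' active force-length, hyperbolic force-velocity, quadratic passive element,
#' constant-thickness pennation), expressed as a dimensionless residual
#' \deqn{res = f_t / f_{max} - \cos\phi\,(a f_L f_V + f_{PE} + d\,\tilde v)}
#' with a small fiber damping d = 0.01 that keeps the residual solvable for
#' \code{sdot} at zero activation.
#'
#' @param state List with \code{s} (projected fiber length, m) and \code{a}
#'   (activation); \code{sdot} m/s; \code{l_mt} musculotendon length, m.
#' @param spec Muscle spec (see \code{\link{muscle_spec}}).  All numeric
#'   arguments vectorized.
#' @return List with \code{residual} (dimensionless) and \code{f_tendon} (N,
#'   nonnegative).
#' @export
contraction_residual <- function(state, sdot, l_mt, spec) {
  s <- state$s; a <- state$a
  w <- spec$l_opt * sin(spec$pennation_opt)
  l_f <- sqrt(s^2 + w^2)
  cosp <- s / l_f
  eps <- (l_mt - s - spec$l_slack) / spec$l_slack
  ft <- tendon_force_norm(eps)
  ltilde <- l_f / spec$l_opt
  vtilde <- (cosp * sdot) / (HILL$v_max * spec$l_opt)
  fiber <- a * force_length_active(ltilde) * force_velocity(vtilde) +
    force_length_passive(ltilde) + HILL$damping * vtilde
  list(residual = ft - cosp * fiber, f_tendon = spec$f_max * ft)
}

#' Generalized joint moments from muscle forces
#'
#' @param forces Muscle forces, N (length n_m).
#' @param arms Moment-arm matrix, n_m x n_coordinates, m.
#' @return Generalized moments \code{t(arms) \%*\% forces}, N·m.
#' @export
joint_moments_from_muscles <- function(forces, arms) {
  assert_that(length(forces) == nrow(arms),
              "forces and moment-arm matrix dimensions disagree")
  as.numeric(crossprod(arms, forces))
}

#' Moment-arm matrix of a muscle set at a posture
#' @param mset A \code{muscle_set}; \code{q} named coordinates;
#'   \code{coord_names} columns of the result.
#' @return n_m x length(coord_names) matrix, m.
#' @export
moment_arm_matrix <- function(mset, q, coord_names = names(q)) {
  A <- matrix(0, mset$n, length(coord_names),
              dimnames = list(mset$names, coord_names))
  for (i in seq_len(mset$n)) {
    g <- muscle_tendon_length_and_moment_arms(q, muscle_spec(mset, i))
    A[i, names(g$moment_arms)] <- g$moment_arms
  }
  A
}

#' Static muscle-redundancy solve
#'
#' Distributes target generalized moments over the muscles by minimizing the
#' effort \eqn{\sum_m a_m^p} subject to moment matching and activation bounds
#' [0,1], with muscle strength taken as the isometric force at the current
#' posture (rigid tendon).  Solved as a sequence of increasing-penalty
#' box-constrained problems.
#'
#' @param mset A \code{muscle_set}; \code{q} named posture; \code{tau_target}
#'   named target moments (N·m) for a subset of coordinates; \code{p} effort
#'   exponent (>= 2); \code{a0} optional warm-start activations.
#' @return List with \code{a} (activations), \code{forces} (N),
#'   \code{moment_error} (N·m).
#' @export
muscle_redundancy_solve <- function(mset, q, tau_target, p = 2, a0 = NULL) {
  cn <- names(tau_target)
  A <- moment_arm_matrix(mset, q, cn)
  ## isometric strength at this posture
  fiso <- numeric(mset$n)
  for (i in seq_len(mset$n)) {
    sp <- muscle_spec(mset, i)
    g <- muscle_tendon_length_and_moment_arms(q, sp)
    lf <- max(g$l_mt - sp$l_slack, 0.31 * sp$l_opt)  # rigid tendon
    lt <- sqrt(lf^2 + (sp$l_opt * sin(sp$pennation_opt))^2) / sp$l_opt
    fiso[i] <- sp$f_max * force_length_active(lt) * (lf / (lt * sp$l_opt))
  }
  G <- A * fiso                       # n_m x n_c moment per unit activation
  scl <- pmax(apply(abs(G), 2, max), 1)
  a <- if (is.null(a0)) rep(0.1, mset$n) else pmin(pmax(a0, 0), 1)
  for (rho in c(1e2, 1e4, 1e6)) {
    obj <- function(a) sum(a^p) +
      rho * sum(((crossprod(G, a) - tau_target) / scl)^2)
    gr <- function(a) p * a^(p - 1) +
      rho * 2 * as.numeric(G %*% ((crossprod(G, a) - tau_target) / scl^2))
    a <- stats::optim(a, obj, gr, method = "L-BFGS-B", lower = 0, upper = 1,
                      control = list(maxit = 500, factr = 1e4))$par
  }
  list(a = a, forces = a * fiso,
       moment_error = as.numeric(crossprod(G, a)) - as.numeric(tau_target))
}
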
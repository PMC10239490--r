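## Rigid-body skier model: configuration parsing, tree bookkeeping, degrees of
## freedom, mass properties and the passive ski-boot ankle moment.

JOINT_NDOF <- c(free6 = 6L, ball3 = 3L, planar3 = 3L, revolute1 = 1L, locked = 0L)

coord_names_for_joint <- function(name, kind) {
  switch(kind,
    free6    = paste0(name, c("_tx", "_ty", "_tz", "_tilt", "_list", "_rot")),
    ball3    = paste0(name, c("_rot", "_add", "_flex")),
    planar3  = paste0(name, c("_tx", "_tz", "_pitch")),
    revolute1 = name,
    locked   = character(0))
}

as_inertia <- function(x) {
  x <- unlist(x)
  if (length(x) == 3) return(diag(as.numeric(x)))
  if (length(x) == 9) return(matrix(as.numeric(x), 3, 3))
  ski_stop("inertia must be a length-3 diagonal or a 3x3 matrix",
           "skiturn_validation_error")
}

parse_segment <- function(s) {
  jt <- s$joint
  kind <- match.arg(jt$kind, names(JOINT_NDOF))
  inertia <- as_inertia(s$inertia)
  if (max(abs(inertia - t(inertia))) > 1e-12)
    ski_stop(sprintf("segment '%s': inertia tensor not symmetric", s$name),
             "skiturn_validation_error")
  if (any(eigen(inertia, symmetric = TRUE, only.values = TRUE)$values < -1e-12))
    ski_stop(sprintf("segment '%s': inertia tensor not positive semidefinite", s$name),
             "skiturn_validation_error")
  if (!is.numeric(s$mass) || s$mass <= 0)
    ski_stop(sprintf("segment '%s': mass must be > 0", s$name),
             "skiturn_validation_error")
  axis <- if (!is.null(jt$axis)) {
    a <- as.numeric(unlist(jt$axis))
    assert_that(abs(sqrt(sum(a^2)) - 1) < 1e-8,
                sprintf("joint '%s': axis must have unit norm", jt$name))
    a
  } else c(0, 1, 0)
  fixed_R <- if (!is.null(jt$fixed_rotation_zxy)) {
    r <- as.numeric(unlist(jt$fixed_rotation_zxy))
    euler_zxy(r[1], r[2], r[3])
  } else diag(3)
  cp <- if (!is.null(s$contact_points)) {
    m <- do.call(cbind, lapply(s$contact_points, function(p) as.numeric(unlist(p))))
    rownames(m) <- c("x", "y", "z"); m
  } else NULL
  passive <- if (!is.null(jt$passive)) {
    p <- jt$passive
    list(stiffness = p$stiffness %||% 0, damping = p$damping %||% 0,
         neutral = p$neutral %||% 0)
  } else NULL
  signs <- if (!is.null(jt$signs)) as.numeric(unlist(jt$signs))
           else rep(1, JOINT_NDOF[[kind]])
  assert_that(length(signs) == JOINT_NDOF[[kind]] && all(abs(signs) == 1),
              sprintf("joint '%s': signs must be +/-1 per coordinate", jt$name))
  list(name = s$name, parent_name = s$parent,
       joint_name = if (!is.null(jt$name)) jt$name else paste0(s$name, "_joint"),
       kind = kind, axis = axis, fixed_R = fixed_R, passive = passive,
       signs = signs,
       origin = as.numeric(unlist(s$origin)),
       mass = as.numeric(s$mass),
       com = as.numeric(unlist(s$com)),
       inertia = inertia,
       contact_points = cp)
}

#' Build a rigid-body skier model from a configuration
#'
#' Reads a structured model configuration (a YAML file or an equivalent nested
#' list) describing segments, joints, locked coordinates and ski-boot
#' parameters, and returns the assembled multibody tree.  Two presets ship
#' with the package: \code{"nominal_3d"}, the full three-dimensional skier
#' with a free pelvis, ball hips and lumbar joint, revolute knees and ankles
#' and locked subtalar/toe joints (19 degrees of freedom), and
#' \code{"reduced_planar"}, a sagittal-plane skier with a planar pelvis joint
#' and one hip, knee and ankle hinge per leg (9 degrees of freedom) used for
#' fast simulation and optimization studies.
#'
#' Arm segments are carried with a locked shoulder joint in a typical skiing
#' posture; their mass and inertia are folded into the trunk-arm assembly by
#' \code{\link{compress_model}}, so they contribute no coordinates.
#'
#' @param config Path to a YAML model configuration, a preset name, or a
#'   nested list with elements \code{segments}, \code{boot} and
#'   \code{subject}.
#' @return An object of class \code{skier_model} with the segment tree, the
#'   generalized-coordinate layout (\code{$coord_names}, \code{$n_q}), boot
#'   parameters and subject data.
#' @examples
#' mdl <- build_skier_model("reduced_planar")
#' mdl$n_q  # 9
#' @export
build_skier_model <- function(config) {
  if (is.character(config)) {
    path <- if (file.exists(config)) config
            else ski_extdata(paste0(config, ".yaml"))
    config <- yaml::read_yaml(path)
  }
  segs <- lapply(config$segments, parse_segment)
  names(segs) <- vapply(segs, `[[`, "", "name")
  if (anyDuplicated(names(segs)))
    ski_stop("duplicate segment names", "skiturn_structural_error")

  ## resolve parents, check for a connected acyclic tree rooted at the world
  parent <- vapply(segs, `[[`, "", "parent_name")
  idx <- setNames(seq_along(segs), names(segs))
  pidx <- ifelse(parent == "world", 0L, idx[parent])
  if (anyNA(pidx))
    ski_stop("segment parent not found: disconnected graph", "skiturn_structural_error")
  if (sum(pidx == 0L) != 1L)
    ski_stop("model must have exactly one root segment attached to the world",
             "skiturn_structural_error")
  for (i in seq_along(segs)) {     # cycle / ordering check by walking up
    j <- i; seen <- integer(0)
    while (j != 0L) {
      if (j %in% seen) ski_stop("cyclic segment graph", "skiturn_structural_error")
      seen <- c(seen, j); j <- pidx[j]
      if (length(seen) > length(segs)) ski_stop("cyclic segment graph",
                                                "skiturn_structural_error")
    }
  }
  ## topological order (parents before children)
  ord <- integer(0); placed <- c(TRUE, rep(FALSE, length(segs)))  # world placed
  while (length(ord) < length(segs)) {
    ready <- which(!placed[-1] & placed[pidx + 1L])
    if (!length(ready)) ski_stop("disconnected segment graph", "skiturn_structural_error")
    ord <- c(ord, ready); placed[ready + 1L] <- TRUE
  }
  segs <- segs[ord]
  idx <- setNames(seq_along(segs), names(segs))
  pidx <- vapply(segs, function(s) if (s$parent_name == "world") 0L
                 else idx[[s$parent_name]], 0L)
  root_kind <- segs[[which(pidx == 0L)]]$kind
  if (!root_kind %in% c("free6", "planar3"))
    ski_stop("root segment must attach through a free or planar joint",
             "skiturn_structural_error")

  ## coordinate layout
  coord_names <- character(0); dof_start <- integer(length(segs))
  for (i in seq_along(segs)) {
    cn <- coord_names_for_joint(segs[[i]]$joint_name, segs[[i]]$kind)
    dof_start[i] <- length(coord_names) + 1L
    coord_names <- c(coord_names, cn)
  }
  boot <- boot_params(config$boot)
  mdl <- structure(list(
    name = if (!is.null(config$name)) config$name else "skier_model",
    segments = segs, parent = pidx,
    coord_names = coord_names, n_q = length(coord_names),
    dof_start = dof_start,
    dof_count = vapply(segs, function(s) JOINT_NDOF[[s$kind]], 0L),
    subject = config$subject, boot = boot,
    config = config), class = "skier_model")
  mdl$total_mass <- sum(vapply(segs, `[[`, 0, "mass"))
  mdl
}

#' @export
print.skier_model <- function(x, ...) {
  cat(sprintf("<skier_model '%s'>: %d segments, %d DOF, total mass %.2f kg\n",
              x$name, length(x$segments), x$n_q, x$total_mass))
  invisible(x)
}

#' Degrees of freedom of a model
#' @param model A \code{skier_model}.
#' @return Integer DOF count.
#' @export
dof_count <- function(model) model$n_q

joint_dof_indices <- function(model, i) {
  n <- model$dof_count[i]
  if (n == 0L) integer(0) else seq.int(model$dof_start[i], length.out = n)
}

#' Fold locked-joint segments into their articulated parents
#'
#' Returns a model in which every segment attached by a locked joint (arms,
#' subtalar/toe bodies, rigidly mounted skis) is merged into its nearest
#' articulated ancestor: masses add, centres of mass combine, and inertia
#' tensors transform by rotation plus the parallel-axis theorem.  Contact
#' points move into the absorbing segment's frame.  The coordinate layout is
#' unchanged.
#'
#' @param model A \code{skier_model}.
#' @return A \code{skier_model} with only articulated segments.
#' @export
compress_model <- function(model) {
  segs <- model$segments; pidx <- model$parent
  n <- length(segs)
  ## fixed transform of each segment relative to its own frame origin chain:
  ## walk segments in order; locked segments accumulate pose relative to the
  ## nearest articulated ancestor.
  target <- integer(n)    # absorbing articulated segment index
  relR <- vector("list", n); relp <- vector("list", n)
  for (i in seq_len(n)) {
    if (segs[[i]]$kind != "locked") {
      target[i] <- i; relR[[i]] <- diag(3); relp[[i]] <- c(0, 0, 0)
    } else {
      p <- pidx[i]
      stopifnot(p > 0L)
      Rp <- relR[[p]]; pp <- relp[[p]]
      relR[[i]] <- Rp %*% segs[[i]]$fixed_R
      relp[[i]] <- pp + Rp %*% segs[[i]]$origin
      target[i] <- target[p]
    }
  }
  keep <- which(target == seq_len(n))
  out <- segs[keep]
  for (k in seq_along(keep)) {
    i <- keep[k]
    members <- which(target == i)
    m_tot <- sum(vapply(segs[members], `[[`, 0, "mass"))
    com_w <- Reduce(`+`, lapply(members, function(j)
      segs[[j]]$mass * (relp[[j]] + relR[[j]] %*% segs[[j]]$com))) / m_tot
    I_tot <- matrix(0, 3, 3)
    for (j in members) {
      cj <- relp[[j]] + relR[[j]] %*% segs[[j]]$com
      Ij <- relR[[j]] %*% segs[[j]]$inertia %*% t(relR[[j]])
      d <- as.numeric(cj - com_w)
      I_tot <- I_tot + Ij + segs[[j]]$mass * (sum(d^2) * diag(3) - d %o% d)
    }
    cps <- lapply(members, function(j) {
      cp <- segs[[j]]$contact_points
      if (is.null(cp)) NULL else relR[[j]] %*% cp + as.numeric(relp[[j]])
    })
    cps <- Filter(Negate(is.null), cps)
    out[[k]]$mass <- m_tot
    out[[k]]$com <- as.numeric(com_w)
    out[[k]]$inertia <- I_tot
    out[[k]]$contact_points <- if (length(cps)) do.call(cbind, cps) else NULL
  }
  ## remap parents onto kept segments
  newidx <- integer(n); newidx[keep] <- seq_along(keep)
  new_parent <- vapply(seq_along(keep), function(k) {
    p <- pidx[keep[k]]
    if (p == 0L) 0L else newidx[target[p]]
  }, 0L)
  mdl <- model
  mdl$segments <- out
  names(mdl$segments) <- vapply(out, `[[`, "", "name")
  mdl$parent <- new_parent
  mdl$dof_start <- model$dof_start[keep]
  mdl$dof_count <- model$dof_count[keep]
  mdl$total_mass <- sum(vapply(out, `[[`, 0, "mass"))
  mdl
}

## ---- ski-boot passive ankle moment ----------------------------------------

boot_params <- function(cfg) {
  if (is.null(cfg)) cfg <- list()
  p <- list(neutral_angle = cfg$neutral_angle %||% 0,
            deadband = cfg$deadband %||% 0.03,
            stiffness = as.numeric(unlist(cfg$stiffness %||% c(60, 1500))),
            damping = cfg$damping %||% 1.5)
  assert_that(all(p$stiffness >= 0) && p$damping >= 0 && p$deadband >= 0,
              "boot stiffness, damping and deadband must be nonnegative")
  class(p) <- "boot_params"
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Passive ski-boot ankle moment
#'
#' Nonlinear passive moment of the ski boot about the ankle: an odd
#' polynomial stiffness curve in the deflection from the neutral angle with a
#' smooth deadband, plus linear damping.  The elastic part opposes deflection
#' and is odd-symmetric about the neutral angle; coefficients are
#' configuration values (\code{stiffness[k]} multiplies the (2k-1)-th power
#' of the effective deflection, N·m/rad^(2k-1)).
#'
#' @param ankle_angle Ankle angle, rad (dorsiflexion positive).
#' @param ankle_rate Ankle angular velocity, rad/s.
#' @param params A \code{boot_params} list (see model configuration).
#' @return Passive moment, N·m (vectorized over inputs).
#' @export
boot_moment <- function(ankle_angle, ankle_rate, params) {
  d <- ankle_angle - params$neutral_angle
  e <- if (params$deadband > 0) d - params$deadband * tanh(d / params$deadband) else d
  m <- 0
  for (k in seq_along(params$stiffness))
    m <- m + params$stiffness[k] * e^(2 * k - 1)
  -m - params$damping * ankle_rate
}
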
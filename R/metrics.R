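## Evaluation metrics and the end-user analysis pipeline: joint-angle RMSD,
## skier track / speed / turn radius, EMG envelope processing and
## activation-EMG comparison, and the composed run_pipeline().

#' Root mean squared difference
#' @param series_a,series_b Equal-length numeric series.
#' @return \code{sqrt(mean((a - b)^2))}.
#' @export
rmsd <- function(series_a, series_b) {
  assert_that(length(series_a) == length(series_b) && length(series_a) >= 1,
              "series must have equal length >= 1")
  sqrt(mean((series_a - series_b)^2))
}

#' Per-channel joint-angle RMSD of a tracking solution
#' @param sol An \code{nlp_solution}; \code{ref} a \code{reference_data};
#'   \code{bundle} the \code{ski_bundle}.
#' @return Named vector of RMSDs, degrees (angle channels only).
#' @export
angle_rmsd <- function(sol, ref, bundle) {
  L <- bundle$layout
  ia <- which(ref$is_angle)
  out <- vapply(ia, function(i)
    rad2deg(rmsd(sol$X[L$idx_q[i], ], ref$channels[i, ])), 0)
  stats::setNames(out, ref$names[ia])
}

#' Track, speed and turn radius of a trajectory
#'
#' The track is the path of the ankle joint centres projected onto the snow
#' surface; the speed is the whole-body COM speed; the turn radius is the
#' reciprocal curvature of the smoothed track, reported as the minimum over
#' the steering phase (where the outside-ski normal force exceeds body
#' weight), or over the whole trajectory when no such phase exists.  A
#' straight trajectory has no finite radius and reports \code{NA}.
#'
#' @param bundle A \code{ski_bundle}; \code{traj} a \code{ski_trajectory}.
#' @return List with \code{track} (per-leg list of 2-column matrices),
#'   \code{speed} (m/s per node), \code{min_turn_radius} (m or NA).
#' @export
track_metrics <- function(bundle, traj) {
  L <- bundle$layout
  cmp <- bundle$compressed
  N <- ncol(traj$X)
  ankles <- grep("^foot|^talus", names(cmp$segments))
  track <- list()
  for (ai in ankles) {
    P <- matrix(0, N, 3)
    for (k in seq_len(N)) {
      fk <- forward_kinematics(cmp, traj$X[L$idx_q, k])
      P[k, ] <- fk$p[, ai]
    }
    track[[names(cmp$segments)[ai]]] <- P
  }
  ## COM speed by central differences of the COM path
  h <- traj$time[2] - traj$time[1]
  coms <- sapply(seq_len(N), function(k)
    center_of_mass(cmp, traj$X[L$idx_q, k])$com)
  div <- h * ifelse(seq_len(N) %in% c(1, N), 1, 2)
  vcom <- (coms[, pmin(seq_len(N) + 1, N), drop = FALSE] -
             coms[, pmax(seq_len(N) - 1, 1), drop = FALSE])
  speed <- sqrt(colSums(vcom^2)) / div
  radius <- turn_radius(track[[1]][, 1], track[[1]][, 2], traj$time)
  list(track = track, speed = speed, min_turn_radius = radius)
}

#' Minimum turn radius from a planar path
#'
#' Curvature of the smoothed (x, y) path via spline derivatives,
#' \eqn{\kappa = |x'y'' - y'x''| / (x'^2+y'^2)^{3/2}}; radius = 1/max
#' curvature.  Returns NA for (near-)straight paths.
#'
#' @param x,y Path coordinates, m; \code{time} sample times, s.
#' @return Minimum radius, m, or NA.
#' @export
turn_radius <- function(x, y, time) {
  if (stats::sd(y) < 1e-6 || length(x) < 5) return(NA_real_)
  sx <- stats::smooth.spline(time, x); sy <- stats::smooth.spline(time, y)
  x1 <- stats::predict(sx, time, deriv = 1)$y
  x2 <- stats::predict(sx, time, deriv = 2)$y
  y1 <- stats::predict(sy, time, deriv = 1)$y
  y2 <- stats::predict(sy, time, deriv = 2)$y
  kap <- abs(x1 * y2 - y1 * x2) / (x1^2 + y1^2)^1.5
  if (max(kap) < 1e-4) return(NA_real_)
  1 / max(kap)
}

#' EMG envelope
#'
#' Full-wave rectification followed by a zero-lag second-order dual-pass
#' (forward-backward) Butterworth low-pass filter at the cut-off frequency.
#'
#' @param signal Raw EMG samples.
#' @param fs Sampling rate, Hz (e.g. 2000).
#' @param cutoff Low-pass cut-off, Hz (default 6).
#' @return Envelope series (same length).
#' @export
emg_envelope <- function(signal, fs, cutoff = 6) {
  assert_that(fs > 2 * cutoff, "sampling rate must exceed twice the cut-off")
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, abs(signal)))
}

#' Scale EMG envelopes to estimated activations and correlate
#'
#' Each EMG channel is scaled so its maximum equals the maximum of the
#' corresponding estimated activation (EMG amplitude is scale-free), then
#' the Pearson correlation is reported per muscle.  All-zero estimated
#' channels are skipped with a note.
#'
#' @param activations Matrix (muscles x N) with rownames; \code{emg} matrix
#'   with matching rownames (resampled to a common time base).
#' @return List with \code{scaled} (matrix), \code{correlation} (named),
#'   \code{skipped} (character).
#' @export
compare_activations <- function(activations, emg) {
  common <- intersect(rownames(activations), rownames(emg))
  assert_that(length(common) > 0, "no common muscle labels")
  scaled <- matrix(NA_real_, length(common), ncol(emg),
                   dimnames = list(common, NULL))
  corr <- stats::setNames(rep(NA_real_, length(common)), common)
  skipped <- character(0)
  for (m in common) {
    amax <- max(activations[m, ])
    emax <- max(emg[m, ])
    if (amax <= 0 || emax <= 0) { skipped <- c(skipped, m); next }
    scaled[m, ] <- emg[m, ] * amax / emax
    if (stats::sd(emg[m, ]) > 0 && stats::sd(activations[m, ]) > 0)
      corr[m] <- stats::cor(activations[m, ], emg[m, ])
  }
  list(scaled = scaled, correlation = corr, skipped = skipped)
}

#' Run the full analysis pipeline
#'
#' Composes the stages: reference fixture (generated or supplied), initial
#' guess, tracking solve, inverse-dynamics knee loads, ACL forces, and the
#' evaluation metrics.  Any stage failure raises a structured error naming
#' the stage.
#'
#' @param config List: \code{model} (preset name), \code{muscles} (table
#'   path), \code{n_mesh}, \code{T}, \code{weights} (w1, w2, w3), \code{p},
#'   \code{guess} ("schuss"/"pd_tracking"), \code{seed},
#'   \code{acl_coefficients} (path), \code{solver} (control list).
#' @return An \code{evaluation_report}: per-channel RMSD (deg/m), speed
#'   series, minimum turn radius, peak activations, peak ACL per leg (N and
#'   BW), objective breakdown, and the underlying solution.
#' @export
run_pipeline <- function(config = list()) {
  cf <- utils::modifyList(list(
    model = "reduced_planar",
    muscles = ski_extdata("muscles_reduced_planar.csv"),
    n_mesh = 75, T = 2, weights = c(1, 10, 1e-3), p = 2,
    guess = "schuss", seed = 1L,
    acl_coefficients = ski_extdata("acl_coefficients.yaml"),
    solver = list()), config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      ski_stop(sprintf("pipeline stage '%s' failed: %s", name,
                       conditionMessage(e)), "skiturn_pipeline_error"))
  }
  bundle <- stage("model", ski_bundle(cf$model, cf$muscles))
  coeffs <- stage("acl_coefficients", read_acl_coefficients(cf$acl_coefficients))
  fixture <- if (!is.null(cf$fixture)) cf$fixture else
    stage("reference", generate_reference_turn(bundle, seed = cf$seed,
                                               n_mesh = cf$n_mesh, T = cf$T))
  grid <- collocation_grid(cf$n_mesh, cf$T)
  ref <- reference_data(fixture, grid)
  spec <- objective_spec(cf$weights[1], cf$weights[2], cf$weights[3], cf$p)
  prob <- stage("transcription", assemble_nlp(bundle, ref, spec, grid))
  guess <- stage("initial_guess", make_initial_guess(cf$guess, prob, cf$seed))
  sol <- stage("solve", solve_tracking(prob, guess, cf$solver))
  traj <- structure(list(time = grid$times, X = sol$X, U = sol$U,
                         dt = grid$h, layout = bundle$layout,
                         bundle_name = bundle$model$name),
                    class = "ski_trajectory")
  aclR <- stage("acl", acl_time_series(bundle, traj, "right", coeffs))
  aclL <- stage("acl", acl_time_series(bundle, traj, "left", coeffs))
  tm <- stage("metrics", track_metrics(bundle, traj))
  rms <- angle_rmsd(sol, ref, bundle)
  mass <- bundle$model$subject$mass_kg %||% bundle$model$total_mass
  report <- list(
    rmsd_deg = rms,
    max_rmsd_deg = max(rms),
    speed = tm$speed,
    min_turn_radius = tm$min_turn_radius,
    peak_activation = stats::setNames(apply(sol$X[bundle$layout$idx_a, ,
                                                  drop = FALSE], 1, max),
                                      bundle$muscles$names),
    peak_acl_N = c(right = max(aclR$acl$total), left = max(aclL$acl$total)),
    peak_acl_BW = body_weight_normalize(
      c(right = max(aclR$acl$total), left = max(aclL$acl$total)), mass),
    objective = sol$parts,
    solver_status = sol$status,
    constraint_violation = sol$constraint_violation,
    seed = cf$seed, config = cf)
  structure(list(report = report, solution = sol, trajectory = traj,
                 fixture = fixture, bundle = bundle,
                 acl = list(right = aclR, left = aclL)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  r <- x$report
  cat("<evaluation_report>\n")
  cat(sprintf("  solver: %s (feasibility %.1e)\n", r$solver_status,
              r$constraint_violation))
  cat(sprintf("  max joint-angle RMSD: %.3f deg\n", r$max_rmsd_deg))
  cat(sprintf("  speed: %.1f-%.1f m/s\n", min(r$speed), max(r$speed)))
  cat(sprintf("  peak ACL: right %.1f N (%.3f BW), left %.1f N\n",
              r$peak_acl_N["right"], r$peak_acl_BW["right"],
              r$peak_acl_N["left"]))
  invisible(x)
}

#' Write an evaluation report to delimited tables
#'
#' Writes the report's time series (tracked channels, activations, ACL
#' components) and a machine-readable summary into a directory.  Tables
#' carry explicit units in their headers.
#'
#' @param ev An \code{evaluation_report}; \code{dir} output directory.
#' @return Invisibly, the file paths written.
#' @export
write_report <- function(ev, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  b <- ev$bundle; L <- b$layout
  f1 <- file.path(dir, "tracked_channels.csv")
  ch <- t(ev$solution$X[L$idx_q, , drop = FALSE])
  colnames(ch) <- paste0(b$model$coord_names, "_rad_or_m")
  utils::write.csv(cbind(time_s = ev$trajectory$time, ch), f1, row.names = FALSE)
  f2 <- file.path(dir, "activations.csv")
  av <- t(ev$solution$X[L$idx_a, , drop = FALSE])
  colnames(av) <- b$muscles$names
  utils::write.csv(cbind(time_s = ev$trajectory$time, av), f2, row.names = FALSE)
  f3 <- file.path(dir, "acl_forces.csv")
  acl <- data.frame(time_s = ev$trajectory$time,
                    right_sagittal_N = ev$acl$right$acl$sagittal,
                    right_frontal_N = ev$acl$right$acl$frontal,
                    right_transverse_N = ev$acl$right$acl$transverse,
                    right_total_N = ev$acl$right$acl$total,
                    left_total_N = ev$acl$left$acl$total)
  utils::write.csv(acl, f3, row.names = FALSE)
  f4 <- file.path(dir, "summary.yaml")
  r <- ev$report
  yaml::write_yaml(list(max_rmsd_deg = r$max_rmsd_deg,
                        min_turn_radius_m = r$min_turn_radius,
                        speed_mps = range(r$speed),
                        peak_acl_N = as.list(r$peak_acl_N),
                        solver_status = r$solver_status,
                        seed = r$seed), f4)
  invisible(c(f1, f2, f3, f4))
}
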
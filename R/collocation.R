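## Direct-collocation trajectory tracking.  The optimal control problem --
## track reference channels subject to the implicit system dynamics and
## bounds -- is transcribed with implicit Euler on a uniform mesh: decision
## variables are the states and controls at every node, the dynamics enter
## as per-interval defect constraints f(x_{k+1}, (x_{k+1}-x_k)/h, u_{k+1}) =
## 0, and the objective is
##   J = (1/T) int [ (w1/n_d)||err_d||^2 + (w2/n_m)||a||_p^p
##                   + (w3/n_xu)(||xdot||^2 + ||udot||^2) ] dt
## with the integral by the right-endpoint rectangle rule matching the
## implicit-Euler nodes and xdot, udot by the same backward differences as
## the defects.  The NLP is solved by a projected Gauss-Newton augmented-
## Lagrangian method with sparse linear algebra.

#' Collocation grid
#' @param n_mesh Number of mesh nodes (>= 2); \code{T} horizon in s.
#' @return List with \code{n_mesh}, \code{T}, \code{h}, \code{times}.
#' @export
collocation_grid <- function(n_mesh = 75, T = 2) {
  assert_that(n_mesh >= 2, "need at least 2 mesh points")
  list(n_mesh = as.integer(n_mesh), T = T, h = T / (n_mesh - 1),
       times = seq(0, T, length.out = n_mesh))
}

#' Objective specification
#'
#' Weights and normalizers of the tracking objective.  \code{w2 = 10} and
#' effort exponent \code{p = 2} are the nominal settings; \code{w1} and
#' \code{w3} default so that the three terms are within a couple of orders
#' of magnitude on the synthetic case.
#'
#' @param w1,w2,w3 Nonnegative weights of tracking error, muscle effort and
#'   regularization.
#' @param p Effort exponent (2, 3 or 5).
#' @export
objective_spec <- function(w1 = 1, w2 = 10, w3 = 1e-3, p = 2) {
  assert_that(w1 >= 0 && w2 >= 0 && w3 >= 0, "weights must be nonnegative")
  assert_that(p >= 2, "effort exponent must be >= 2")
  list(w1 = w1, w2 = w2, w3 = w3, p = p)
}

#' Reference data for tracking
#'
#' Wraps tracked channels (generalized coordinates) with fixed
#' characteristic normalization scales: 10 degrees for angle channels and
#' 0.1 m for translations, so all error components are of the same order
#' and the objective is reproducible.
#'
#' @param fixture A \code{reference_fixture}, or a list with
#'   \code{channels}, \code{channel_names}, \code{angle_channels}, \code{T}.
#' @param grid Optional \code{collocation_grid}; channels are linearly
#'   resampled onto it when the mesh differs.
#' @return A \code{reference_data} object.
#' @export
reference_data <- function(fixture, grid = NULL) {
  ch <- fixture$channels
  nm <- fixture$channel_names
  ia <- fixture$angle_channels
  T <- fixture$T
  n0 <- ncol(ch)
  if (!is.null(grid) && grid$n_mesh != n0) {
    t0 <- seq(0, T, length.out = n0)
    ch <- t(apply(ch, 1, function(y)
      stats::approx(t0, y, xout = grid$times, rule = 2)$y))
  }
  structure(list(channels = ch, names = nm, is_angle = ia,
                 scales = ifelse(ia, deg2rad(10), 0.1),
                 T = T, x0 = fixture$trajectory$X[, 1],
                 truth_u = fixture$truth_u, truth_a = fixture$truth_a),
            class = "reference_data")
}

#' Objective value and its three parts
#'
#' @param X,U State and control node values (n_x x N, n_u x N).
#' @param ref A \code{reference_data} on the same grid.
#' @param spec An \code{objective_spec}.
#' @param grid A \code{collocation_grid}.
#' @param bundle The \code{ski_bundle} (for the state layout).
#' @return List with \code{J}, \code{tracking}, \code{effort},
#'   \code{regularization} (weighted parts; they sum to J).
#' @export
objective_terms <- function(X, U, ref, spec, grid, bundle) {
  L <- bundle$layout
  N <- grid$n_mesh; h <- grid$h; T <- grid$T
  assert_that(nrow(ref$channels) == L$n_q && ncol(ref$channels) == N,
              "reference channels do not match the tracked coordinate set")
  n_d <- nrow(ref$channels)
  n_m <- max(L$n_m, 1L)
  n_xu <- L$n_x + L$n_u
  ks <- 2:N
  err <- (X[L$idx_q, ks, drop = FALSE] - ref$channels[, ks, drop = FALSE]) /
    ref$scales
  tracking <- (spec$w1 / n_d) * sum(err^2) * h / T
  A <- if (L$n_m > 0) X[L$idx_a, ks, drop = FALSE] else matrix(0, 1, length(ks))
  effort <- (spec$w2 / n_m) * sum(pmax(A, 0)^spec$p) * h / T
  Xd <- (X[, ks, drop = FALSE] - X[, ks - 1, drop = FALSE]) / h
  Ud <- (U[, ks, drop = FALSE] - U[, ks - 1, drop = FALSE]) / h
  reg <- (spec$w3 / n_xu) * (sum(Xd^2) + sum(Ud^2)) * h / T
  list(J = tracking + effort + reg, tracking = tracking, effort = effort,
       regularization = reg)
}

#' Implicit-Euler defect constraints
#'
#' Returns the per-interval defects
#' \code{f(x_{k+1}, (x_{k+1}-x_k)/h, u_{k+1})} for a node trajectory; zero on
#' dynamically consistent trajectories.
#'
#' @param X,U Node values; \code{grid} a \code{collocation_grid};
#'   \code{bundle} a planar \code{ski_bundle}.
#' @return n_x x (N-1) defect matrix (scaled rows).
#' @export
discretize_dynamics <- function(X, U, grid, bundle) {
  N <- grid$n_mesh
  Xn <- X[, -1, drop = FALSE]
  Xd <- (X[, -1, drop = FALSE] - X[, -N, drop = FALSE]) / grid$h
  planar_residual(bundle, Xn, Xd, U[, -1, drop = FALSE])
}

#' Assemble the tracking NLP
#'
#' Builds the problem container: decision vector (states and controls at
#' every node), bound vectors, the least-squares residual of the objective,
#' the defect constraints, and their sparse Jacobians (objective analytic,
#' defects by vectorized finite differences of the implicit residual).
#'
#' @param bundle A planar \code{ski_bundle}; \code{ref} a
#'   \code{reference_data}; \code{spec} an \code{objective_spec}; \code{grid}
#'   a \code{collocation_grid}.
#' @return An \code{nlp_problem}.
#' @export
assemble_nlp <- function(bundle, ref, spec, grid) {
  L <- bundle$layout
  N <- grid$n_mesh
  n_x <- L$n_x; n_u <- L$n_u
  nz <- N * (n_x + n_u)
  ix <- function(k) (k - 1L) * n_x + seq_len(n_x)
  iu <- function(k) N * n_x + (k - 1L) * n_u + seq_len(n_u)
  bl <- c(rep(bundle$bounds$x_lower, N), rep(bundle$bounds$u_lower, N))
  bu <- c(rep(bundle$bounds$x_upper, N), rep(bundle$bounds$u_upper, N))
  assert_that(all(bl <= bu), "infeasible bounds (lower > upper)")
  pack <- function(X, U) c(X, U)
  unpack <- function(z) list(X = matrix(z[seq_len(N * n_x)], n_x, N),
                             U = matrix(z[N * n_x + seq_len(N * n_u)], n_u, N))
  structure(list(bundle = bundle, ref = ref, spec = spec, grid = grid,
                 n_z = nz, n_c = (N - 1L) * n_x,
                 lower = bl, upper = bu,
                 ix = ix, iu = iu, pack = pack, unpack = unpack),
            class = "nlp_problem")
}

#' @export
print.nlp_problem <- function(x, ...) {
  cat(sprintf("<nlp_problem>: %d variables, %d defect constraints, %d nodes\n",
              x$n_z, x$n_c, x$grid$n_mesh))
  invisible(x)
}

## objective least-squares residual and its sparse Jacobian (analytic)
nlp_objective_residual <- function(prob, z, jacobian = TRUE) {
  L <- prob$bundle$layout
  grid <- prob$grid; spec <- prob$spec; ref <- prob$ref
  N <- grid$n_mesh; h <- grid$h; T <- grid$T
  s <- prob$unpack(z); X <- s$X; U <- s$U
  n_d <- nrow(ref$channels); n_m <- max(L$n_m, 1L); n_xu <- L$n_x + L$n_u
  wt <- sqrt(spec$w1 / n_d * h / T)
  we <- sqrt(spec$w2 / n_m * h / T)
  wr <- sqrt(spec$w3 / n_xu * h / T)
  ks <- 2:N
  r_tr <- wt * as.numeric((X[L$idx_q, ks, drop = FALSE] -
                             ref$channels[, ks, drop = FALSE]) / ref$scales)
  A <- pmax(X[L$idx_a, ks, drop = FALSE], 0)
  r_ef <- we * as.numeric(A^(spec$p / 2))
  r_rgx <- wr * as.numeric((X[, ks, drop = FALSE] - X[, ks - 1, drop = FALSE]) / h)
  r_rgu <- wr * as.numeric((U[, ks, drop = FALSE] - U[, ks - 1, drop = FALSE]) / h)
  r <- c(r_tr, r_ef, r_rgx, r_rgu)
  if (!jacobian) return(list(r = r))
  ## sparse triplets
  n1 <- length(r_tr); n2 <- length(r_ef); n3 <- length(r_rgx); n4 <- length(r_rgu)
  off2 <- n1; off3 <- n1 + n2; off4 <- n1 + n2 + n3
  ii <- jj <- vv <- vector("list", 6)
  ## tracking: rows over (q, k)
  cols <- as.numeric(outer(L$idx_q, (ks - 1L) * L$n_x, `+`))
  ii[[1]] <- seq_len(n1); jj[[1]] <- cols
  vv[[1]] <- rep(wt / ref$scales, length(ks))
  ## effort
  cols <- as.numeric(outer(L$idx_a, (ks - 1L) * L$n_x, `+`))
  ii[[2]] <- off2 + seq_len(n2); jj[[2]] <- cols
  vv[[2]] <- we * (spec$p / 2) * as.numeric(A^(spec$p / 2 - 1))
  ## regularization states: two diagonals
  colsk <- as.numeric(outer(seq_len(L$n_x), (ks - 1L) * L$n_x, `+`))
  colskm <- as.numeric(outer(seq_len(L$n_x), (ks - 2L) * L$n_x, `+`))
  ii[[3]] <- off3 + rep(seq_len(n3), 2); jj[[3]] <- c(colsk, colskm)
  vv[[3]] <- c(rep(wr / h, n3), rep(-wr / h, n3))
  ## regularization controls
  cuk <- as.numeric(outer(seq_len(L$n_u), N * L$n_x + (ks - 1L) * L$n_u, `+`))
  cukm <- as.numeric(outer(seq_len(L$n_u), N * L$n_x + (ks - 2L) * L$n_u, `+`))
  ii[[4]] <- off4 + rep(seq_len(n4), 2); jj[[4]] <- c(cuk, cukm)
  vv[[4]] <- c(rep(wr / h, n4), rep(-wr / h, n4))
  Jr <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                             dims = c(length(r), prob$n_z))
  list(r = r, J = Jr)
}

## defect vector and its sparse Jacobian by vectorized finite differences
nlp_defects <- function(prob, z, jacobian = TRUE, fd_step = 1e-6) {
  b <- prob$bundle; L <- b$layout; grid <- prob$grid
  N <- grid$n_mesh; h <- grid$h
  s <- prob$unpack(z); X <- s$X; U <- s$U
  Xn <- X[, -1, drop = FALSE]; Xk <- X[, -N, drop = FALSE]
  Un <- U[, -1, drop = FALSE]
  Xd <- (Xn - Xk) / h
  R0 <- planar_residual(b, Xn, Xd, Un)
  cvec <- as.numeric(R0)
  if (!jacobian) return(list(c = cvec))
  n_x <- L$n_x; n_u <- L$n_u; M <- N - 1L
  ## one batched residual evaluation for all finite-difference directions:
  ## column blocks of width M = [base | x-perturbations | xdot-perturbations
  ## | u-perturbations]
  nb <- 1L + 2L * n_x + n_u
  XB <- matrix(Xn, n_x, M * nb)
  XdB <- matrix(Xd, n_x, M * nb)
  UB <- matrix(Un, n_u, M * nb)
  for (j in seq_len(n_x)) {
    XB[j, j * M + seq_len(M)] <- XB[j, j * M + seq_len(M)] + fd_step
    co <- (n_x + j) * M
    XdB[j, co + seq_len(M)] <- XdB[j, co + seq_len(M)] + fd_step
  }
  for (j in seq_len(n_u)) {
    co <- (2L * n_x + j) * M
    UB[j, co + seq_len(M)] <- UB[j, co + seq_len(M)] + fd_step
  }
  RB <- planar_residual(b, XB, XdB, UB)
  Rx <- (RB[, M + seq_len(n_x * M), drop = FALSE] -
           matrix(R0, n_x, n_x * M)) / fd_step
  Rxd <- (RB[, (1L + n_x) * M + seq_len(n_x * M), drop = FALSE] -
            matrix(R0, n_x, n_x * M)) / fd_step
  Ru <- (RB[, (1L + 2L * n_x) * M + seq_len(n_u * M), drop = FALSE] -
           matrix(R0, n_x, n_u * M)) / fd_step
  dim(Rx) <- c(n_x, M, n_x); dim(Rxd) <- c(n_x, M, n_x)
  dim(Ru) <- c(n_x, M, n_u)
  Rx <- aperm(Rx, c(1, 3, 2)); Rxd <- aperm(Rxd, c(1, 3, 2))
  Ru <- aperm(Ru, c(1, 3, 2))
  A <- Rx + Rxd / h                       # wrt x_{k+1}, [n_x, n_x, M]
  Bm <- -Rxd / h                          # wrt x_k
  base_i <- rep(seq_len(n_x), n_x)
  base_jx <- rep(seq_len(n_x), each = n_x)
  koff <- rep((seq_len(M) - 1L) * n_x, each = n_x * n_x)
  iiA <- rep(base_i, M) + koff
  jjA <- rep(base_jx, M) + rep(seq_len(M) * n_x, each = n_x * n_x)
  jjB <- rep(base_jx, M) + koff
  if (n_u > 0) {
    base_iu <- rep(seq_len(n_x), n_u)
    base_ju <- rep(seq_len(n_u), each = n_x)
    iiU <- rep(base_iu, M) + rep((seq_len(M) - 1L) * n_x, each = n_x * n_u)
    jjU <- N * n_x + rep(base_ju, M) + rep(seq_len(M) * n_u, each = n_x * n_u)
  } else { iiU <- integer(0); jjU <- integer(0) }
  Jc <- Matrix::sparseMatrix(
    i = c(iiA, iiA, iiU), j = c(jjA, jjB, jjU),
    x = c(as.numeric(A), as.numeric(Bm), as.numeric(Ru)),
    dims = c(length(cvec), prob$n_z))
  list(c = cvec, J = Jc)
}

#' Solve the tracking NLP
#'
#' Sparse sequential quadratic programming: each iteration solves the
#' Gauss-Newton KKT system of the equality-constrained subproblem (defects
#' linearized, objective Hessian approximated by 2 J_r' J_r plus
#' Levenberg damping), takes a projected line-search step on an l1 merit
#' function, and handles bounds by an active-set freeze of variables whose
#' Lagrangian gradient holds them on the bound.
#'
#' @param prob An \code{nlp_problem} from \code{\link{assemble_nlp}}.
#' @param guess Initial decision vector or a list with \code{X}, \code{U}.
#' @param control List: \code{tol_feas} (scaled defect tolerance, 1e-6),
#'   \code{max_iter}, \code{tol_obj} (relative objective stall), \code{verbose}.
#' @return An \code{nlp_solution}: node states/controls, objective parts,
#'   solver status, constraint violation.
#' @export
solve_tracking <- function(prob, guess, control = list()) {
  ct <- utils::modifyList(list(tol_feas = 1e-6, max_iter = 100,
                               tol_obj = 1e-7, verbose = FALSE), control)
  z <- if (is.list(guess)) prob$pack(guess$X, guess$U) else guess
  z <- pmin(pmax(z, prob$lower), prob$upper)
  n <- prob$n_z; m <- prob$n_c
  lam <- numeric(m)
  nu <- 1e-2
  sigma <- 10
  status <- "max_iterations"
  fprev <- Inf
  stall <- 0L
  ## per-variable characteristic scales (diagonal preconditioning of the
  ## KKT system and metric for the damping term / step cap)
  b <- prob$bundle; L <- b$layout
  dx <- numeric(L$n_x)
  dx[L$idx_q] <- 1; dx[L$idx_qd] <- 10
  if (L$n_m > 0) { dx[L$idx_s] <- b$muscles$table$l_opt; dx[L$idx_a] <- 1 }
  if (L$n_c > 0) dx[L$idx_mem] <- 0.05
  dscale <- c(rep(dx, prob$grid$n_mesh), rep(1, prob$grid$n_mesh * L$n_u))
  ## feasibility restoration: the defect manifold is exactly parameterized
  ## by (x_1, U) through the implicit-Euler step, so a trajectory can be
  ## re-simulated from the current controls at any time
  restore <- function(z) {
    s <- prob$unpack(z)
    b <- prob$bundle; grid <- prob$grid
    tr <- tryCatch(
      forward_simulate(b, s$X[, 1], s$U, T = grid$T, dt = grid$h, tol = 1e-9),
      error = function(e) NULL)
    if (is.null(tr)) return(z)
    Xr <- tr$X[, seq_len(grid$n_mesh), drop = FALSE]
    Xr <- pmin(pmax(Xr, b$bounds$x_lower), b$bounds$x_upper)
    prob$pack(Xr, s$U)
  }
  for (it in seq_len(ct$max_iter)) {
    ob <- nlp_objective_residual(prob, z)
    df <- nlp_defects(prob, z)
    f0 <- sum(ob$r^2); c0 <- sum(abs(df$c)); feas <- max(abs(df$c))
    g <- as.numeric(2 * Matrix::crossprod(ob$J, ob$r))
    ## active-set freeze: variables held on a bound by the Lagrangian
    gl <- g + as.numeric(Matrix::crossprod(df$J, lam))
    at_lb <- z <= prob$lower + 1e-11
    at_ub <- z >= prob$upper - 1e-11
    free <- !(at_lb & gl > 0) & !(at_ub & gl < 0)
    ## KKT system on the free variables
    Jf <- df$J[, free, drop = FALSE]
    accepted <- FALSE
    for (try in 1:10) {
      ## damping in the scaled metric: nu / d_i^2 on the diagonal
      Hf <- 2 * Matrix::crossprod(ob$J[, free, drop = FALSE]) +
        Matrix::Diagonal(sum(free), nu / dscale[free]^2)
      KKT <- rbind(cbind(Hf, Matrix::t(Jf)),
                   cbind(Jf, Matrix::Diagonal(m, -1e-10)))
      rhs <- c(-g[free], -df$c)
      sol <- tryCatch(as.numeric(Matrix::solve(KKT, rhs)),
                      error = function(e) NULL)
      if (!is.null(sol) && all(is.finite(sol))) {
        dz <- numeric(n); dz[free] <- sol[seq_len(sum(free))]
        ## cap the scaled step length (trust region)
        sn <- max(abs(dz / dscale))
        if (sn > 2) dz <- dz * (2 / sn)
        lam_new <- sol[sum(free) + seq_len(m)]
        sigma <- max(1.5 * max(abs(lam_new)), 10)
        phi0 <- f0 + sigma * c0
        Ddir <- sum(g * dz) - sigma * c0
        alpha <- 1
        soc_done <- FALSE
        for (ls in 1:12) {
          zt <- pmin(pmax(z + alpha * dz, prob$lower), prob$upper)
          rt <- nlp_objective_residual(prob, zt, jacobian = FALSE)$r
          cT <- nlp_defects(prob, zt, jacobian = FALSE)$c
          phit <- sum(rt^2) + sigma * sum(abs(cT))
          if (is.finite(phit) &&
              phit <= phi0 + 1e-4 * alpha * min(Ddir, 0) + 1e-12 * abs(phi0)) {
            accepted <- TRUE
            break
          }
          if (ls == 1 && !soc_done) {
            ## second-order correction: re-solve with the constraint value
            ## at the trial point to cancel the curvature-induced violation
            soc_done <- TRUE
            sol2 <- tryCatch(as.numeric(Matrix::solve(
              KKT, c(numeric(sum(free)), -cT))), error = function(e) NULL)
            if (!is.null(sol2) && all(is.finite(sol2))) {
              dsoc <- numeric(n); dsoc[free] <- sol2[seq_len(sum(free))]
              zt <- pmin(pmax(z + dz + dsoc, prob$lower), prob$upper)
              rt <- nlp_objective_residual(prob, zt, jacobian = FALSE)$r
              cT2 <- nlp_defects(prob, zt, jacobian = FALSE)$c
              phit <- sum(rt^2) + sigma * sum(abs(cT2))
              if (is.finite(phit) &&
                  phit <= phi0 + 1e-4 * min(Ddir, 0) + 1e-12 * abs(phi0)) {
                accepted <- TRUE
                dz <- dz + dsoc
                break
              }
            }
          }
          alpha <- alpha / 2
        }
        if (accepted) {
          z <- zt; lam <- lam_new
          nu <- if (alpha >= 0.5) max(nu / 3, 1e-5) else min(nu * 2, 1e4)
          break
        }
      }
      nu <- nu * 10
    }
    if (ct$verbose)
      message(sprintf(
        "  it %3d J %.6e feas %.2e |dz| %.2e alpha %.2g nu %.1e free %d%s",
        it, f0, feas, if (accepted) max(abs(dz)) else NA,
        if (accepted) alpha else NA, nu, sum(free),
        if (accepted) "" else " (no step)"))
    if (!accepted) {
      if (feas <= ct$tol_feas) status <- "solved"
      break
    }
    cnew <- nlp_defects(prob, z, jacobian = FALSE)$c
    fnew <- sum(nlp_objective_residual(prob, z, jacobian = FALSE)$r^2)
    if (max(abs(cnew)) <= ct$tol_feas &&
        abs(fprev - fnew) <= ct$tol_obj * (abs(fnew) + 1e-12)) {
      stall <- stall + 1L
      if (stall >= 2L) { status <- "solved"; break }
    } else stall <- 0L
    fprev <- fnew
  }
  ## final restoration so the returned trajectory satisfies the defects
  cfin <- max(abs(nlp_defects(prob, z, jacobian = FALSE)$c))
  if (cfin > ct$tol_feas) {
    zr <- restore(z)
    cr <- max(abs(nlp_defects(prob, zr, jacobian = FALSE)$c))
    if (cr < cfin) z <- zr
  }
  if (max(abs(nlp_defects(prob, z, jacobian = FALSE)$c)) <= ct$tol_feas &&
      status == "max_iterations")
    status <- "solved"
  s <- prob$unpack(z)
  parts <- objective_terms(s$X, s$U, prob$ref, prob$spec, prob$grid,
                           prob$bundle)
  cfin <- nlp_defects(prob, z, jacobian = FALSE)$c
  structure(list(X = s$X, U = s$U, z = z, objective = parts$J,
                 parts = parts, status = status,
                 constraint_violation = max(abs(cfin)),
                 multipliers = lam, grid = prob$grid),
            class = "nlp_solution")
}

#' @export
print.nlp_solution <- function(x, ...) {
  cat(sprintf(
    "<nlp_solution>: status '%s', J = %.5g (track %.3g, effort %.3g, reg %.3g), feas %.2e\n",
    x$status, x$objective, x$parts$tracking, x$parts$effort,
    x$parts$regularization, x$constraint_violation))
  invisible(x)
}

#' Sensitivity study over objective settings, mesh density and initial guess
#'
#' Re-solves the tracking problem over a factorial of effort exponents,
#' effort weights w2, mesh-point counts and initial-guess kinds on the same
#' reference fixture, warm-starting within a mesh where possible, and
#' tabulates peak activation, peak (outside-leg) ACL force, maximal
#' joint-angle RMSD and the objective parts per variant.  Individual variant
#' failures are recorded and the suite continues.
#'
#' @param bundle A planar \code{ski_bundle}; \code{fixture} a
#'   \code{reference_fixture}.
#' @param p_values,w2_values,mesh_values,guesses Factors to sweep.
#' @param coeffs ACL coefficients; \code{control} solver control list.
#' @return A data.frame with one row per variant.
#' @export
sensitivity_suite <- function(bundle, fixture,
                              p_values = c(2, 3, 5),
                              w2_values = c(2.5, 5, 10, 20, 40),
                              mesh_values = c(50, 75, 100, 125),
                              guesses = c("schuss", "pd_tracking"),
                              coeffs = read_acl_coefficients(),
                              control = list()) {
  rows <- list()
  L <- bundle$layout
  for (mesh in mesh_values) {
    grid <- collocation_grid(mesh, fixture$T)
    ref <- reference_data(fixture, grid)
    for (gk in guesses) {
      prob0 <- assemble_nlp(bundle, ref, objective_spec(), grid)
      guess <- tryCatch(make_initial_guess(gk, prob0), error = function(e) NULL)
      warm <- NULL
      for (p in p_values) for (w2 in w2_values) {
        spec <- objective_spec(w2 = w2, p = p)
        prob <- assemble_nlp(bundle, ref, spec, grid)
        res <- tryCatch({
          g0 <- if (!is.null(warm)) warm else guess
          sol <- solve_tracking(prob, g0, control)
          if (sol$status == "solved") warm <- list(X = sol$X, U = sol$U)
          traj <- structure(list(time = grid$times, X = sol$X, U = sol$U,
                                 dt = grid$h, layout = L),
                            class = "ski_trajectory")
          acl <- acl_time_series(bundle, traj, "right", coeffs)
          rms <- angle_rmsd(sol, ref, bundle)
          data.frame(mesh = mesh, guess = gk, p = p, w2 = w2,
                     status = sol$status, objective = sol$objective,
                     tracking = sol$parts$tracking,
                     effort = sol$parts$effort,
                     regularization = sol$parts$regularization,
                     peak_activation = max(sol$X[L$idx_a, ]),
                     peak_acl_N = max(acl$acl$total),
                     max_rmsd_deg = max(rms))
        }, error = function(e)
          data.frame(mesh = mesh, guess = gk, p = p, w2 = w2,
                     status = paste("error:", conditionMessage(e)),
                     objective = NA, tracking = NA, effort = NA,
                     regularization = NA, peak_activation = NA,
                     peak_acl_N = NA, max_rmsd_deg = NA))
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  do.call(rbind, rows)
}

#' Initial guesses for the tracking NLP
#'
#' \code{"schuss"}: a straight gliding simulation of the skier in the
#' reference crouch, independent of the reference data, resampled on the
#' grid.  \code{"pd_tracking"}: a reflex (PD) controller tracks the
#' reference joint angles with a static muscle-redundancy feedforward, and
#' the realized states and excitations populate the guess.
#'
#' @param kind "schuss" or "pd_tracking".
#' @param prob An \code{nlp_problem}.
#' @param seed Integer seed for the underlying simulations.
#' @return List with \code{X}, \code{U} (clamped into bounds).
#' @export
make_initial_guess <- function(kind = c("schuss", "pd_tracking"), prob,
                               seed = 1L) {
  kind <- match.arg(kind)
  b <- prob$bundle; grid <- prob$grid; L <- b$layout
  posture <- c(pelvis_pitch = 0.40, hip_r = 1.10, hip_l = 1.10,
               knee_r = 1.20, knee_l = 1.20, ankle_r = 0.285, ankle_l = 0.285)
  gains <- reflex_gains()
  speed <- 12
  alpha <- b$surf$slope_angle
  ff <- static_feedforward(b, posture, speed, trim = FALSE)
  x0 <- bundle_initial_state(b, c(posture, pelvis_tz = ff$tz),
          qd = c(pelvis_tx = speed * cos(alpha),
                 pelvis_tz = -speed * sin(alpha)),
          a0 = pmax(ff$u_ff, 0.02))
  if (kind == "schuss") {
    ## first pass with the static feedforward, then re-estimate the tonic
    ## feedforward from the measured dynamic joint moments and re-simulate
    hold <- function(uff) function(t)
      c(as.list(posture), list(u_ff = uff, tonic = 0.01))
    ctrl <- excitation_controller(b, hold(ff$u_ff), gains)
    sim1 <- simulate_closed_loop(b, x0, ctrl, T = grid$T, dt = grid$h)
    tau <- measured_required_moments(b, sim1)
    qset <- stats::setNames(sim1$X[L$idx_q, ncol(sim1$X)],
                            b$model$coord_names)
    uff2 <- muscle_redundancy_solve(b$muscles, qset, tau, p = 2)$a
    ctrl2 <- excitation_controller(b, hold(uff2), gains)
    sim <- simulate_closed_loop(b, x0, ctrl2, T = grid$T, dt = grid$h)
  } else {
    ## data-derived guess: adopt the reference kinematics node by node (the
    ## perfect-tracking limit of a PD follower), recover the required joint
    ## moments from the muscle-free residual, and populate a, u, s by the
    ## per-node static muscle-redundancy solve (min sum a^p subject to
    ## moment match and bounds) with isometric fiber states
    cn <- b$model$coord_names
    N <- grid$n_mesh
    Q <- prob$ref$channels
    h <- grid$h
    Qd <- cbind((Q[, 2] - Q[, 1]) / h,
                (Q[, -1, drop = FALSE] - Q[, -N, drop = FALSE]) / h)
    pc <- planar_contact_geometry(b, Q, Qd)
    mem <- t(apply(pmax(pc$depth, 0), 1, cummax))
    X <- matrix(0, L$n_x, N)
    X[L$idx_q, ] <- Q; X[L$idx_qd, ] <- Qd; X[L$idx_mem, ] <- mem
    traj0 <- structure(list(time = grid$times, X = X,
                            U = matrix(0, L$n_u, N), dt = h, layout = L),
                       class = "ski_trajectory")
    mm <- measured_required_moments(b, traj0, window = 2:N, average = FALSE)
    A <- matrix(0, L$n_m, N)
    aprev <- NULL
    for (w in seq_along(mm$nodes)) {
      k <- mm$nodes[w]
      qk <- stats::setNames(Q[, k], cn)
      sol_k <- muscle_redundancy_solve(b$muscles, qk, mm$tau[, w], p = 2,
                                       a0 = aprev)
      A[, k] <- sol_k$a
      aprev <- sol_k$a
    }
    A[, 1] <- A[, 2]
    ## isometric fiber states consistent with the adopted posture
    S <- matrix(0, L$n_m, N)
    for (m in seq_len(L$n_m)) {
      sp <- muscle_spec(b$muscles, m)
      for (k in seq_len(N)) {
        qk <- stats::setNames(Q[, k], cn)
        g <- muscle_tendon_length_and_moment_arms(qk, sp)
        root <- tryCatch(stats::uniroot(function(s)
          contraction_residual(list(s = s, a = A[m, k]), 0, g$l_mt,
                               sp)$residual,
          c(0.06 * sp$l_opt, 1.95 * sp$l_opt), tol = 1e-10)$root,
          error = function(e) sp$l_opt * cos(sp$pennation_opt))
        S[m, k] <- root
      }
    }
    X[L$idx_s, ] <- S; X[L$idx_a, ] <- A
    sim <- list(X = X, U = A)
  }
  X <- sim$X[, seq_len(grid$n_mesh), drop = FALSE]
  U <- sim$U[, seq_len(grid$n_mesh), drop = FALSE]
  X <- pmin(pmax(X, b$bounds$x_lower), b$bounds$x_upper)
  U <- pmin(pmax(U, b$bounds$u_lower), b$bounds$u_upper)
  list(X = X, U = U)
}
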
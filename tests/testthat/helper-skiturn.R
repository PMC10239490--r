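# Shared lazily-cached objects: building the planar bundle, the reference
# fixtures and the nominal-mesh tracking solution is expensive, so each is
# created once per test run and reused across files.

.skiturn_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .skiturn_cache))
    assign(name, expr, envir = .skiturn_cache)
  get(name, envir = .skiturn_cache)
}

planar_bundle <- function() {
  cached("bundle", ski_bundle("reduced_planar",
                              ski_extdata("muscles_reduced_planar.csv")))
}

# a "bare" planar bundle: no muscles, zero boot moment, no drag, skier high
# above the snow -- only rigid-body inertia and gravity act
bare_planar_bundle <- function() {
  cached("bare_bundle", {
    cfg <- yaml::read_yaml(ski_extdata("reduced_planar.yaml"))
    cfg$boot <- list(neutral_angle = 0, deadband = 0, stiffness = c(0, 0),
                     damping = 0)
    mdl <- build_skier_model(cfg)
    ski_bundle(mdl, NULL, aero = list(CdA = 0, rho = 1.07, wind = c(0, 0, 0)))
  })
}

turn_fixture <- function(n_mesh = 75) {
  cached(paste0("fixture", n_mesh),
         generate_reference_turn(planar_bundle(), seed = 1L, n_mesh = n_mesh))
}

# nominal tracking solve: 75 mesh points, w2 = 10, p = 2, schuss guess
nominal_tracking <- function() {
  cached("tracking75", {
    b <- planar_bundle()
    fx <- turn_fixture(75)
    grid <- collocation_grid(75, fx$T)
    ref <- reference_data(fx, grid)
    prob <- assemble_nlp(b, ref, objective_spec(), grid)
    guess <- make_initial_guess("schuss", prob)
    sol <- solve_tracking(prob, guess)
    list(sol = sol, prob = prob, ref = ref, grid = grid)
  })
}

carved_turn <- function() {
  cached("carved3d", generate_carved_turn_kinematics())
}

# effort-weight sweep at a reduced mesh, warm-started along the weight path;
# the unweighted tracking and effort parts are compared across w2
w2_sweep_data <- function() {
  cached("w2_sweep", {
    b <- planar_bundle()
    fx <- turn_fixture(75)
    grid <- collocation_grid(21, 2)
    ref <- reference_data(fx, grid)
    prob0 <- assemble_nlp(b, ref, objective_spec(), grid)
    warm <- make_initial_guess("schuss", prob0)
    w2s <- c(2.5, 5, 10, 20, 40)
    track <- numeric(0); effort <- numeric(0); status <- character(0)
    for (w2 in w2s) {
      prob <- assemble_nlp(b, ref, objective_spec(w2 = w2), grid)
      sol <- solve_tracking(prob, warm)
      if (sol$status == "solved") warm <- list(X = sol$X, U = sol$U)
      track <- c(track, sol$parts$tracking)
      effort <- c(effort, sol$parts$effort / w2)
      status <- c(status, sol$status)
    }
    data.frame(w2 = w2s, track = track, effort = effort, status = status)
  })
}

random_q <- function(model, seed = 1) {
  set.seed(seed)
  q <- stats::rnorm(model$n_q, 0, 0.4)
  stats::setNames(q, model$coord_names)
}
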
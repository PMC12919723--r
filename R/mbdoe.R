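#' Design space for a discriminating experiment
#'
#' Box constraints on the designable initial concentrations (observed
#' species only; intermediates are fixed, normally at zero), the time grid
#' on which rival models are compared, and the observed species entering
#' the divergence.
#'
#' @param lower,upper numeric vectors of box bounds per designable
#'   component (`lower <= upper` elementwise).
#' @param design_indices positions of the designable components in the full
#'   initial-condition vector.
#' @param fixed full-length template initial-condition vector supplying the
#'   non-designable components.
#' @param t_grid evaluation time grid.
#' @param observed_indices species entering the divergence sum.
#' @return A list of class `design_space`.
#' @export
design_space <- function(lower, upper, design_indices, fixed, t_grid,
                         observed_indices) {
  if (length(lower) != length(upper) || any(lower > upper))
    stopf("need elementwise lower <= upper")
  if (length(design_indices) != length(lower))
    stopf("'design_indices' must match the bounds length")
  if (length(t_grid) < 2L || any(diff(t_grid) <= 0))
    stopf("'t_grid' must be strictly increasing")
  structure(list(lower = lower, upper = upper,
                 design_indices = as.integer(design_indices),
                 fixed = fixed, t_grid = t_grid,
                 observed_indices = as.integer(observed_indices)),
            class = "design_space")
}

#' Hunter-Reiner prediction divergence between two fitted models
#'
#' Squared Euclidean distance between the two models' predicted observed
#' trajectories from a common initial condition: the sum over the time grid
#' and observed species of the squared prediction difference.  A simulation
#' failure of either model contributes `failure_penalty` (with a warning)
#' so the designer steers away from conditions where a candidate blows up.
#'
#' @param model_a,model_b two [mass_action_model()] objects over the same
#'   species space.
#' @param k_a,k_b their fitted rate constants.
#' @param x designable components of the initial condition (placed at
#'   `space$design_indices` within `space$fixed`).
#' @param space a [design_space()].
#' @param opts a [solver_opts()].
#' @param failure_penalty divergence charged on simulation failure.
#' @return Non-negative scalar divergence; symmetric in the two models.
#' @export
prediction_divergence <- function(model_a, k_a, model_b, k_b, x, space,
                                  opts = solver_opts(),
                                  failure_penalty = 1e10) {
  stopifnot(inherits(space, "design_space"))
  if (model_a$n_species != model_b$n_species)
    stopf("models must share the species dimension")
  if (length(x) != length(space$design_indices))
    stopf("'x' must match the design dimension")
  c0 <- space$fixed
  c0[space$design_indices] <- x
  sim_a <- simulate_model(model_a, k_a, c0, space$t_grid, opts)
  sim_b <- simulate_model(model_b, k_b, c0, space$t_grid, opts)
  if (!sim_a$success || !sim_b$success) {
    warning("simulation failure inside the design objective; penalised")
    return(failure_penalty)
  }
  diff <- sim_a$trajectory[, space$observed_indices, drop = FALSE] -
    sim_b$trajectory[, space$observed_indices, drop = FALSE]
  sum(diff * diff)
}

#' Design a model-discriminating experiment
#'
#' Chooses initial conditions maximising the Hunter-Reiner divergence
#' between the two best fitted models by seeded multistart bounded
#' quasi-Newton optimisation of the negated divergence over the design box.
#' Deterministic given the seed.
#'
#' @inheritParams prediction_divergence
#' @param n_starts number of multistart points (uniform in the box).
#' @param seed integer seed for the start points.
#' @param maxit optimiser iteration cap.
#' @return An object of class `design_result`: `x_star`, `divergence`, and
#'   `per_start` (start points with their achieved divergences).  A
#'   zero-volume box returns its single point directly; identical models
#'   yield divergence 0 with a warning.
#' @export
design_experiment <- function(model_a, k_a, model_b, k_b, space,
                              n_starts = 10L, seed = 1L,
                              opts = solver_opts(), maxit = 100L) {
  stopifnot(inherits(space, "design_space"))
  obj <- function(x) prediction_divergence(model_a, k_a, model_b, k_b, x,
                                           space, opts)
  d <- length(space$lower)
  if (all(space$upper == space$lower)) {
    x <- space$lower
    return(structure(list(x_star = x, divergence = obj(x),
                          per_start = NULL), class = "design_result"))
  }
  starts <- with_local_seed(seed, matrix(
    runif(n_starts * d, space$lower, space$upper), n_starts, d, byrow = TRUE))
  runs <- lapply(seq_len(n_starts), function(s) {
    res <- tryCatch(
      optim(starts[s, ], function(x) -obj(x), method = "L-BFGS-B",
            lower = space$lower, upper = space$upper,
            control = list(maxit = maxit)),
      error = function(e) NULL
    )
    if (is.null(res)) list(par = starts[s, ], value = obj(starts[s, ]))
    else list(par = res$par, value = -res$value)
  })
  values <- vapply(runs, `[[`, 0, "value")
  best <- which.max(values)
  if (values[best] <= 0)
    warning("zero divergence everywhere: the two models are predictively identical on this design space")
  structure(list(
    x_star = pmin(pmax(runs[[best]]$par, space$lower), space$upper),
    divergence = values[best],
    per_start = data.frame(start = I(lapply(runs, `[[`, "par")),
                           divergence = values)
  ), class = "design_result")
}
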
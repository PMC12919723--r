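#' Fitting configuration
#'
#' Controls the multistart bounded quasi-Newton estimation of rate
#' constants.  Bounds default to `[0, 10]`, which keeps rate constants
#' physically meaningful for the bundled case studies; both can be changed.
#'
#' @param lower,upper box bounds on every rate constant (`lower >= 0`).
#' @param n_starts number of random multistart points (uniform in the box).
#' @param seed integer seed driving the start points; fits are deterministic
#'   given `(seed, data, model)`.
#' @param opts a [solver_opts()] for the inner simulations.
#' @param failure_penalty large finite SSE charged when a simulation fails,
#'   so the optimiser can retreat from blow-up regions.
#' @param maxit iteration cap forwarded to the optimiser.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(lower = 0, upper = 10, n_starts = 5L, seed = 1L,
                       opts = solver_opts(), failure_penalty = 1e10,
                       maxit = 100L) {
  if (lower < 0) stopf("'lower' must be >= 0 (rate constants are non-negative)")
  if (upper <= lower) stopf("'upper' must exceed 'lower'")
  if (n_starts < 1L) stopf("'n_starts' must be >= 1")
  structure(list(lower = lower, upper = upper, n_starts = as.integer(n_starts),
                 seed = as.integer(seed), opts = opts,
                 failure_penalty = failure_penalty, maxit = as.integer(maxit)),
            class = "fit_config")
}

#' Sum of squared errors of a model against an experiment set
#'
#' Simulates the model from each experiment's full initial condition on its
#' time grid and accumulates squared residuals over all experiments,
#' sampling times and observed species.  A failed simulation contributes
#' `failure_penalty` instead of aborting.
#'
#' @param model a [mass_action_model()].
#' @param k rate-constant vector.
#' @param data an [experiment_set()].
#' @param opts a [solver_opts()].
#' @param failure_penalty finite SSE charged per failed simulation.
#' @return Non-negative scalar SSE.
#' @export
model_sse <- function(model, k, data, opts = solver_opts(),
                      failure_penalty = 1e10) {
  stopifnot(inherits(model, "mass_action_model"), inherits(data, "experiment_set"))
  if (length(data$species_names) != model$n_species)
    stopf("data species dimension (%d) does not match the model (%d)",
          length(data$species_names), model$n_species)
  if ((opts$engine %||% "compiled") == "compiled") {
    packed <- c(model$n_params, model$n_species,
                as.double(model$nu), as.double(model$order))
    exps <- lapply(data$experiments, function(e)
      list(e$t, e$y, e$C0_full, e$observed_indices - 1L))
    return(.Call("kinmech_sse_rk45", packed, as.double(k), exps,
                 opts$rtol, opts$atol, failure_penalty,
                 PACKAGE = "kinmech"))
  }
  # the compiled derivative routine is installed once per evaluation; the
  # per-experiment integrations then bypass simulate_model's per-call setup
  install_compiled_model(model, k)
  total <- 0
  for (exp in data$experiments) {
    out <- tryCatch(
      suppressWarnings(deSolve::ode(
        y = exp$C0_full, times = exp$t, func = "kinmech_derivs",
        parms = NULL, dllname = "kinmech", initfunc = NULL,
        rtol = opts$rtol, atol = opts$atol, method = opts$method
      )),
      error = function(e) NULL
    )
    if (is.null(out) || nrow(out) < length(exp$t) || any(!is.finite(out))) {
      total <- total + failure_penalty
      next
    }
    res <- out[, 1L + exp$observed_indices, drop = FALSE] - exp$y
    total <- total + sum(res * res)
  }
  total
}

#' Concentrated Gaussian negative log-likelihood from an SSE
#'
#' Gaussian likelihood with the pooled maximum-likelihood variance
#' `sigma^2 = SSE / N` substituted in and additive constants dropped:
#' `NLL = (N / 2) * log(SSE / N)`.  A zero SSE is floored at
#' `.Machine$double.eps * N` before the logarithm.
#'
#' @param sse non-negative sum of squared errors.
#' @param n_points total number of observed data values N.
#' @return Scalar NLL (can be negative; constants are dropped).
#' @export
nll_from_sse <- function(sse, n_points) {
  if (sse < 0) stopf("'sse' must be >= 0")
  if (n_points < 1) stopf("'n_points' must be >= 1")
  sse <- max(sse, .Machine$double.eps * n_points)
  (n_points / 2) * log(sse / n_points)
}

#' Akaike information criterion
#'
#' `AIC = 2 * NLL + 2 * d`, lower is better; `d` is the number of fitted
#' parameters (here, the number of elementary steps).
#'
#' @param nll negative log-likelihood.
#' @param d parameter count (`>= 0`).
#' @return Scalar AIC.
#' @export
aic_from_nll <- function(nll, d) {
  if (d < 0) stopf("'d' must be >= 0")
  2 * nll + 2 * d
}

#' Fit rate constants by multistart bounded quasi-Newton optimisation
#'
#' Runs `n_starts` L-BFGS-B minimisations of [model_sse()] from seeded
#' uniform-random start points in the bounds box and keeps the best final
#' SSE.  Gradients are finite-difference approximations supplied by the
#' optimiser; its stopping rules are left at their defaults (up to
#' `config$maxit` iterations).
#'
#' @param model a [mass_action_model()] with at least one step.
#' @param data an [experiment_set()].
#' @param config a [fit_config()].
#' @return An object of class `fit_result`: `k_hat`, `sse`, `nll`, `aic`,
#'   `d` (parameter count), `n_points`, `converged`, and `per_start` (a data
#'   frame of start points, final SSEs and convergence flags).  If every
#'   start fails the result carries `sse = failure_penalty` and
#'   `converged = FALSE`.
#' @export
fit_model <- function(model, data, config = fit_config()) {
  stopifnot(inherits(model, "mass_action_model"), inherits(data, "experiment_set"))
  if (model$n_params < 1L) stopf("model must have at least one parameter")
  d <- model$n_params
  objective <- function(k) model_sse(model, k, data, config$opts,
                                     config$failure_penalty)
  # filled by rows so that the first start of an n-start fit equals the
  # single start of a 1-start fit under the same seed (prefix property)
  starts <- with_local_seed(config$seed, {
    matrix(runif(config$n_starts * d, config$lower, config$upper),
           nrow = config$n_starts, ncol = d, byrow = TRUE)
  })
  runs <- lapply(seq_len(config$n_starts), function(s) {
    res <- tryCatch(
      optim(starts[s, ], objective, method = "L-BFGS-B",
            lower = rep(config$lower, d), upper = rep(config$upper, d),
            control = list(maxit = config$maxit)),
      error = function(e) NULL
    )
    if (is.null(res))
      list(par = starts[s, ], value = config$failure_penalty, converged = FALSE)
    else
      list(par = res$par, value = res$value, converged = res$convergence == 0)
  })
  values <- vapply(runs, `[[`, 0, "value")
  best <- which.min(values)
  k_hat <- pmin(pmax(runs[[best]]$par, config$lower), config$upper)
  sse <- values[best]
  nll <- nll_from_sse(sse, data$total_points)
  structure(list(
    k_hat = k_hat, sse = sse, nll = nll, aic = aic_from_nll(nll, d),
    d = d, n_points = data$total_points,
    converged = is.finite(sse) && sse < config$failure_penalty,
    per_start = data.frame(
      start = I(lapply(runs, `[[`, "par")),
      sse = values,
      converged = vapply(runs, `[[`, TRUE, "converged")
    )
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit:", x$d, "parameter(s), SSE =", format(x$sse, digits = 6),
      ", AIC =", format(x$aic, digits = 6), "\n")
  cat("k_hat:", paste(format(x$k_hat, digits = 4), collapse = ", "), "\n")
  invisible(x)
}
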
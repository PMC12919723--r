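#' Solver options
#'
#' Tolerances and method for the stiff-capable integrator used throughout
#' the package.  Candidate mechanisms can be stiff, so the default method is
#' `lsoda`, which switches automatically between stiff and non-stiff
#' regimes.
#'
#' Trajectory simulation ([simulate_model()]) always integrates with
#' deSolve; the fitting objective ([model_sse()]) additionally offers a
#' compiled adaptive Runge-Kutta engine with the same tolerance semantics,
#' used by default because candidate screening evaluates the objective
#' hundreds of thousands of times (the two engines are cross-checked in the
#' test suite).
#'
#' @param rtol relative tolerance (default `1e-6`).
#' @param atol absolute tolerance (default `1e-8`).
#' @param method a [deSolve::ode()] method name.
#' @param engine objective engine: `"compiled"` (adaptive Cash-Karp
#'   Runge-Kutta in C) or `"desolve"`.
#' @return A list of class `solver_opts`.
#' @export
solver_opts <- function(rtol = 1e-6, atol = 1e-8, method = "lsoda",
                        engine = c("compiled", "desolve")) {
  structure(list(rtol = rtol, atol = atol, method = method,
                 engine = match.arg(engine)),
            class = "solver_opts")
}

#' Simulate a mass-action model
#'
#' Integrates the model's initial-value problem on a time grid using a
#' compiled mass-action derivative routine.  Solver failure (non-convergence
#' or a non-finite state) is reported as a structured result rather than an
#' error so that parameter estimation can penalise it.
#'
#' @param model a [mass_action_model()].
#' @param k rate-constant vector.
#' @param C0 non-negative initial concentrations, length `model$n_species`.
#' @param times strictly increasing time grid; the first row of the
#'   trajectory equals `C0` at `times[1]`.
#' @param opts a [solver_opts()].
#' @return A list with `success` (logical), `trajectory`
#'   (`length(times) x n_species` matrix, species-named columns; `NULL` on
#'   failure) and `message`.
#' @examples
#' m <- parse_reactions("A -> B")
#' simulate_model(m, k = 0.5, C0 = c(A = 1, B = 0), times = seq(0, 4, 0.5))
#' @export
simulate_model <- function(model, k, C0, times, opts = solver_opts()) {
  stopifnot(inherits(model, "mass_action_model"))
  if (length(k) != model$n_params) stopf("'k' must have length %d", model$n_params)
  if (length(C0) != model$n_species) stopf("'C0' must have length %d", model$n_species)
  if (any(C0 < 0)) stopf("'C0' must be non-negative")
  if (length(times) < 2L || any(diff(times) <= 0))
    stopf("'times' must be strictly increasing with at least two points")
  install_compiled_model(model, k)
  out <- tryCatch(
    suppressWarnings(deSolve::ode(
      y = as.double(C0), times = as.double(times),
      func = "kinmech_derivs", parms = NULL, dllname = "kinmech",
      initfunc = NULL, rtol = opts$rtol, atol = opts$atol,
      method = opts$method
    )),
    error = function(e) e
  )
  if (inherits(out, "error"))
    return(list(success = FALSE, trajectory = NULL,
                message = conditionMessage(out)))
  if (nrow(out) < length(times) || any(!is.finite(out)))
    return(list(success = FALSE, trajectory = NULL,
                message = "integration did not reach the end of the grid or produced non-finite states"))
  traj <- out[, -1L, drop = FALSE]
  colnames(traj) <- model$species_names
  rownames(traj) <- NULL
  list(success = TRUE, trajectory = traj, message = "ok")
}

# Pack and install a model in the compiled derivative routine's state.
install_compiled_model <- function(model, k) {
  packed <- c(model$n_params, model$n_species,
              as.double(model$nu), as.double(model$order), as.double(k))
  .Call("kinmech_set_model", packed, PACKAGE = "kinmech")
  invisible(NULL)
}

#' Write a simulated trajectory as CSV
#'
#' Time column first, then one column per species.
#'
#' @param trajectory matrix as returned in `simulate_model()$trajectory`.
#' @param times the time grid used.
#' @param path output file path.
#' @export
write_trajectory <- function(trajectory, times, path) {
  df <- data.frame(time = times, trajectory, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
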
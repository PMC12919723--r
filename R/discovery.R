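#' Matrix dimensions for a ladder iteration
#'
#' The complexity ladder starts from the user-supplied minimal mechanism
#' size and adds one elementary step and one hidden intermediate per
#' iteration: iteration `i` uses `min_steps + i - 1` steps and
#' `min_species + i - 1` species.
#'
#' @param min_steps smallest number of elementary steps considered.
#' @param min_species smallest total species count (observed plus any
#'   intermediates already needed at iteration 1).
#' @param iteration_index 1-based iteration number.
#' @return List with `n_steps` and `n_species`.
#' @export
iteration_dimensions <- function(min_steps, min_species, iteration_index) {
  if (iteration_index < 1) stopf("'iteration_index' must be >= 1")
  list(n_steps = as.integer(min_steps + iteration_index - 1L),
       n_species = as.integer(min_species + iteration_index - 1L))
}

#' Smallest sensible ladder start for a stoichiometry
#'
#' For users who do not supply `min_steps`/`min_species`: the smallest
#' number of steps able to move the overall molecule counts under the
#' molecularity caps (each step consumes at most `max_reactant_molecules`
#' and produces at most `max_product_molecules` molecules), with no
#' intermediates at iteration 1 unless the step count forces them.
#'
#' @param stoich a [stoich_spec()].
#' @param config an [enum_config()] (only the molecularity caps are used).
#' @return List with `min_steps` and `min_species`.
#' @export
ladder_start <- function(stoich, config = enum_config(1L)) {
  consumed <- sum(-pmin(stoich$overall_coeffs, 0))
  produced <- sum(pmax(stoich$overall_coeffs, 0))
  steps <- max(ceiling(consumed / config$max_reactant_molecules),
               ceiling(produced / config$max_product_molecules), 1L)
  list(min_steps = as.integer(steps),
       min_species = length(stoich$species_names))
}

#' Enumerate and fit all candidates of one ladder iteration
#'
#' Enumerates every feasible mechanism at the iteration's dimensions,
#' translates each to a mass-action model, fits it to the data and selects
#' the candidate with the lowest AIC.  All candidates of an iteration share
#' the same parameter count, so AIC ties are SSE ties; they are broken by
#' the lexicographically smallest matrix serialisation (the enumeration
#' order).
#'
#' @param stoich a [stoich_spec()] for the observed species (its
#'   intermediate count is overridden per iteration).
#' @param data an [experiment_set()] of the observed species.
#' @param iteration_index 1-based ladder position.
#' @param min_steps,min_species ladder origin (see
#'   [iteration_dimensions()]).
#' @param enum an [enum_config()] template (its `n_steps` is overridden).
#' @param fit a [fit_config()] template; each candidate's fit seed is
#'   derived deterministically from `fit$seed`, the iteration and the
#'   candidate index.
#' @param screen optional two-stage screening for large candidate sets:
#'   a list with elements `n_starts`, `maxit` (the reduced budget used to
#'   fit every candidate) and `top` (how many of the best-screening
#'   candidates are then refitted at the full budget before selection).
#'   `NULL` (the default) fits every candidate at the full budget.  The
#'   winner is always selected from full-budget fits.
#' @return An object of class `iteration_record`: `iteration_index`,
#'   `n_steps`, `n_species`, `n_candidates`, `best_matrix`, `best_model`,
#'   `best_fit`, `aic_table` (per-candidate SSE/AIC data frame) and
#'   `enumeration_complete`.  With no feasible candidates, a record with
#'   `n_candidates = 0` and `NULL` best fields.
#' @export
run_iteration <- function(stoich, data, iteration_index, min_steps,
                          min_species, enum = enum_config(min_steps),
                          fit = fit_config(), screen = NULL) {
  dims <- iteration_dimensions(min_steps, min_species, iteration_index)
  n_inter <- dims$n_species - length(stoich$species_names)
  if (n_inter < 0)
    stopf("min_species (%d) is smaller than the number of observed species (%d)",
          dims$n_species, length(stoich$species_names))
  st <- set_intermediates(stoich, n_inter)
  ec <- enum
  ec$n_steps <- dims$n_steps
  mechs <- enumerate_mechanisms(st, ec)
  empty <- structure(list(
    iteration_index = iteration_index, n_steps = dims$n_steps,
    n_species = dims$n_species, n_candidates = length(mechs),
    best_matrix = NULL, best_model = NULL, best_fit = NULL,
    aic_table = NULL, enumeration_complete = attr(mechs, "complete")
  ), class = "iteration_record")
  if (length(mechs) == 0L) return(empty)

  data_full <- pad_experiment_set(data, st)
  fit_one <- function(i, template) {
    fc <- template
    fc$seed <- derive_seed(fit$seed, iteration_index, i)
    fit_model(mass_action_model(mechs[[i]]), data_full, fc)
  }
  use_screen <- !is.null(screen) && length(mechs) > screen$top
  if (use_screen) {
    cheap <- fit
    cheap$n_starts <- as.integer(screen$n_starts)
    cheap$maxit <- as.integer(screen$maxit)
    fits <- lapply(seq_along(mechs), fit_one, template = cheap)
    sses <- vapply(fits, `[[`, 0, "sse")
    keep <- order(sses)[seq_len(screen$top)]
    for (i in keep) fits[[i]] <- fit_one(i, fit)
  } else {
    fits <- lapply(seq_along(mechs), fit_one, template = fit)
  }
  aics <- vapply(fits, `[[`, 0, "aic")
  ok <- vapply(fits, `[[`, TRUE, "converged") |
    vapply(fits, `[[`, 0, "sse") < fit$failure_penalty
  if (!any(ok)) return(empty)
  aics[!ok] <- Inf
  best <- which.min(aics)  # first minimum = lexicographically smallest matrix
  rec <- empty
  rec$best_matrix <- mechs[[best]]
  rec$best_model <- mass_action_model(mechs[[best]])
  rec$best_fit <- fits[[best]]
  rec$aic_table <- data.frame(
    candidate = seq_along(mechs),
    sse = vapply(fits, `[[`, 0, "sse"),
    aic = vapply(fits, `[[`, 0, "aic"),
    converged = vapply(fits, `[[`, TRUE, "converged")
  )
  rec
}

# Re-express an experiment set in the species space of a candidate
# stoichiometry: observed species are mapped by name and the candidate's
# hidden intermediates start at zero concentration.
pad_experiment_set <- function(data, stoich) {
  obs_names <- data$species_names[data$observed_indices]
  if (!identical(obs_names, stoich$species_names))
    stopf("observed species of the data (%s) do not match the stoichiometry (%s)",
          paste(obs_names, collapse = ","),
          paste(stoich$species_names, collapse = ","))
  n_full <- length(stoich$all_species)
  src <- match(stoich$species_names, data$species_names)
  exps <- lapply(data$experiments, function(e) {
    c0 <- rep(0, n_full)
    c0[seq_along(src)] <- e$C0_full[src]
    kin_experiment(e$t, e$y, seq_along(src), c0)
  })
  experiment_set(exps, stoich$all_species)
}

#' Run the full discovery ladder
#'
#' Iterates [run_iteration()] from iteration 1, growing one step and one
#' intermediate at a time, and stops when the best AIC of the new iteration
#' fails to strictly improve on the incumbent (equal AIC counts as
#' worsening), when `max_iterations` is reached, or when the wall-clock
#' budget expires.  The returned winner is the incumbent at termination.
#'
#' @inheritParams run_iteration
#' @param max_iterations hard cap on ladder length.
#' @param total_budget wall-clock seconds for the whole run (`Inf` to
#'   disable); checked between iterations.
#' @param verbose print a per-iteration summary line.
#' @return An object of class `discovery_result`: `records` (list of
#'   iteration records), `winner` (the record with the best AIC),
#'   `termination_reason` (`"aic_worsened"`, `"max_iterations"`,
#'   `"budget"`, or `"no_candidates"`).
#' @export
run_discovery <- function(stoich, data, min_steps, min_species,
                          enum = enum_config(min_steps), fit = fit_config(),
                          max_iterations = 6L, total_budget = Inf,
                          verbose = FALSE, screen = NULL) {
  t0 <- Sys.time()
  records <- list()
  incumbent <- NULL
  reason <- "max_iterations"
  for (i in seq_len(max_iterations)) {
    rec <- run_iteration(stoich, data, i, min_steps, min_species, enum, fit,
                         screen = screen)
    records[[i]] <- rec
    if (verbose) {
      aic <- if (is.null(rec$best_fit)) NA_real_ else rec$best_fit$aic
      message(sprintf("iteration %d: %d x %d, %d candidate(s), best AIC %s",
                      i, rec$n_steps, rec$n_species, rec$n_candidates,
                      format(aic, digits = 6)))
    }
    if (is.null(rec$best_fit)) {
      if (is.null(incumbent)) { reason <- "no_candidates"; next }
      reason <- "aic_worsened"   # nothing fit at the larger size: no gain
      break
    }
    if (!is.null(incumbent) && rec$best_fit$aic >= incumbent$best_fit$aic) {
      reason <- "aic_worsened"
      break
    }
    incumbent <- rec
    if (difftime(Sys.time(), t0, units = "secs") > total_budget) {
      reason <- "budget"
      break
    }
  }
  structure(list(records = records, winner = incumbent,
                 termination_reason = reason),
            class = "discovery_result")
}

#' @export
print.discovery_result <- function(x, ...) {
  cat("Mechanism discovery:", length(x$records), "iteration(s), terminated by",
      x$termination_reason, "\n")
  for (r in x$records) {
    aic <- if (is.null(r$best_fit)) NA_real_ else r$best_fit$aic
    cat(sprintf("  iter %d (%d x %d): %d candidate(s), best AIC %s\n",
                r$iteration_index, r$n_steps, r$n_species, r$n_candidates,
                format(aic, digits = 6)))
  }
  if (!is.null(x$winner)) {
    cat("Winner (iteration ", x$winner$iteration_index, "):\n", sep = "")
    print(x$winner$best_model)
    cat("k_hat:", paste(format(x$winner$best_fit$k_hat, digits = 4),
                        collapse = ", "), "\n")
  }
  invisible(x)
}
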
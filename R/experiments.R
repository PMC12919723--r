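#' A single concentration-time experiment
#'
#' @param t strictly increasing sampling times (at least two).
#' @param y numeric matrix `length(t) x n_observed` of measured
#'   concentrations; column names are the observed species.
#' @param observed_indices positions of the observed species in the model's
#'   species vector.
#' @param C0_full full initial-condition vector over all model species,
#'   including intermediates (usually zero there).
#' @return An object of class `kin_experiment`.
#' @export
kin_experiment <- function(t, y, observed_indices, C0_full) {
  y <- as.matrix(y)
  rownames(y) <- NULL
  if (length(t) < 2L || any(diff(t) <= 0))
    stopf("'t' must be strictly increasing with at least two points")
  if (nrow(y) != length(t)) stopf("'y' must have one row per sampling time")
  if (any(!is.finite(y))) stopf("'y' must be finite")
  if (ncol(y) != length(observed_indices))
    stopf("'observed_indices' must match the columns of 'y'")
  if (max(observed_indices) > length(C0_full))
    stopf("'observed_indices' exceed the length of 'C0_full'")
  structure(list(t = as.double(t), y = y,
                 observed_indices = as.integer(observed_indices),
                 C0_full = as.double(C0_full)),
            class = "kin_experiment")
}

#' A set of experiments sharing species naming and observed set
#'
#' @param experiments list of [kin_experiment()] objects.
#' @param species_names full species vector (observed species first).
#' @return An object of class `experiment_set` with a `total_points` field
#'   (the N of the likelihood: total observed data values).
#' @export
experiment_set <- function(experiments, species_names) {
  stopifnot(length(experiments) >= 1L)
  lapply(experiments, function(e) stopifnot(inherits(e, "kin_experiment")))
  obs <- experiments[[1]]$observed_indices
  same <- vapply(experiments, function(e) identical(e$observed_indices, obs), TRUE)
  if (!all(same)) stopf("all experiments must share the same observed species")
  n0 <- length(experiments[[1]]$C0_full)
  if (!all(vapply(experiments, function(e) length(e$C0_full) == n0, TRUE)))
    stopf("all experiments must share the species dimension")
  if (length(species_names) != n0)
    stopf("'species_names' must cover the full species vector")
  structure(list(
    experiments = experiments,
    species_names = species_names,
    observed_indices = obs,
    total_points = sum(vapply(experiments,
                              function(e) length(e$t) * ncol(e$y), 0))
  ), class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  cat("Experiment set:", length(x$experiments), "experiment(s),",
      x$total_points, "observed points\n")
  cat("Species:", paste(x$species_names, collapse = ", "),
      "| observed:", paste(x$species_names[x$observed_indices], collapse = ", "),
      "\n")
  invisible(x)
}
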
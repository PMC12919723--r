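# Independent brute-force oracle for mechanism enumeration: filter the full
# Cartesian product of entry assignments through the feasibility rules,
# implemented here from scratch (vectorised row filtering over all d^n row
# vectors, then exhaustive row-tuple composition).  Deliberately shares no
# code with the package's backtracking search.
oracle_enumerate <- function(coeffs, n_inter, n_steps,
                             emin = -2L, emax = 2L, maxr = 2L, maxp = 2L) {
  n <- length(coeffs) + n_inter
  targets <- c(unname(coeffs), rep(0L, n_inter))
  inter <- seq_len(n) > length(coeffs)
  rows <- as.matrix(expand.grid(rep(list(emin:emax), n),
                                KEEP.OUT.ATTRS = FALSE))
  neg <- pmin(rows, 0); pos <- pmax(rows, 0)
  ok <- rowSums(neg) < 0 & rowSums(pos) > 0 &
    rowSums(-neg) <= maxr & rowSums(pos) <= maxp
  for (j in seq_len(n)) {
    if (!inter[j] && targets[j] < 0) ok <- ok & rows[, j] <= 0
    if (!inter[j] && targets[j] > 0) ok <- ok & rows[, j] >= 0
  }
  rows <- rows[ok, , drop = FALSE]
  if (nrow(rows) == 0L) return(list())
  idx <- as.matrix(expand.grid(rep(list(seq_len(nrow(rows))), n_steps),
                               KEEP.OUT.ATTRS = FALSE))
  out <- list()
  for (r in seq_len(nrow(idx))) {
    M <- rows[idx[r, ], , drop = FALSE]
    if (!all(colSums(M) == targets)) next
    bad <- FALSE
    for (j in which(inter)) {
      if (any(cumsum(M[, j]) < 0) || all(M[, j] == 0)) { bad <- TRUE; break }
    }
    if (!bad) out[[length(out) + 1L]] <- unname(M)
  }
  out
}

# canonical serialisation for comparing mechanism sets
mech_keys <- function(mats) {
  vapply(mats, function(m) paste(t(m), collapse = ","), "")
}

# tiny two-experiment set from a closed-form or simulated trajectory
make_experiment_set <- function(model, k, c0_list, times, observed) {
  exps <- lapply(c0_list, function(c0) {
    sim <- simulate_model(model, k, c0, times)
    stopifnot(sim$success)
    kin_experiment(times, sim$trajectory[, observed, drop = FALSE],
                   observed, c0)
  })
  experiment_set(exps, model$species_names)
}
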
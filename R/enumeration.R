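#' Enumeration configuration
#'
#' Settings for the mechanism-matrix search.  The defaults encode the four
#' classical elementary-reaction archetypes (A -> B, A + B -> C, A -> B + C,
#' A + B -> C + D): entries in `[-2, 2]` with at most two reactant molecules
#' and two product molecules per step, counting stoichiometric multiplicity.
#' All limits can be raised to admit termolecular or higher-order steps.
#'
#' @param n_steps number of elementary steps (matrix rows).
#' @param entry_min,entry_max integer entry range per matrix cell
#'   (`entry_min < 0 < entry_max`).
#' @param max_reactant_molecules,max_product_molecules per-step molecularity
#'   caps for the reactant and product sides.
#' @param time_budget wall-clock seconds allotted to the search per call;
#'   `Inf` disables the cap.  On expiry the partial feasible set is returned
#'   with attribute `complete = FALSE` and a warning.
#' @param n_workers worker processes for the parallel search (the tree is
#'   partitioned by first-row candidate; results are identical for any
#'   worker count).
#' @return An object of class `enum_config`.
#' @export
enum_config <- function(n_steps,
                        entry_min = -2L, entry_max = 2L,
                        max_reactant_molecules = 2L,
                        max_product_molecules = 2L,
                        time_budget = Inf,
                        n_workers = 1L) {
  n_steps <- as.integer(n_steps)
  entry_min <- as.integer(entry_min); entry_max <- as.integer(entry_max)
  if (is.na(n_steps) || n_steps < 1L) stopf("'n_steps' must be >= 1")
  if (!(entry_min < 0 && 0 < entry_max))
    stopf("need entry_min < 0 < entry_max")
  if (max_reactant_molecules < 1 || max_product_molecules < 1)
    stopf("molecularity limits must be >= 1")
  if (n_workers < 1) stopf("'n_workers' must be >= 1")
  structure(list(
    n_steps = n_steps, entry_min = entry_min, entry_max = entry_max,
    max_reactant_molecules = as.integer(max_reactant_molecules),
    max_product_molecules = as.integer(max_product_molecules),
    time_budget = time_budget, n_workers = as.integer(n_workers)
  ), class = "enum_config")
}

#' Candidate elementary-step rows
#'
#' All integer row vectors of length `n_species` that could form a single
#' elementary step: every entry within the configured range, at least one
#' negative and one positive entry, total reactant molecules (sum of
#' absolute negative entries) and product molecules (sum of positive
#' entries) within their caps.  Rows are returned in lexicographic order.
#'
#' @param n_species number of columns (species).
#' @param config an [enum_config()]; only its entry range and molecularity
#'   caps are used.
#' @return Integer matrix with one candidate row per matrix row.
#' @export
candidate_rows <- function(n_species, config = enum_config(1L)) {
  n_species <- as.integer(n_species)
  if (is.na(n_species) || n_species < 1L) stopf("'n_species' must be >= 1")
  vals <- seq.int(config$entry_min, config$entry_max)
  g <- as.matrix(expand.grid(rep(list(vals), n_species),
                             KEEP.OUT.ATTRS = FALSE))
  g <- g[do.call(order, as.data.frame(g)), , drop = FALSE]
  keep <- row_predicate(g, config)
  m <- matrix(as.integer(g[keep, , drop = FALSE]), ncol = n_species)
  dimnames(m) <- NULL
  m
}

# vectorised per-row feasibility predicate over a matrix of row vectors
row_predicate <- function(g, config) {
  neg <- pmin(g, 0); pos <- pmax(g, 0)
  rowSums(neg) < 0 & rowSums(pos) > 0 &
    rowSums(-neg) <= config$max_reactant_molecules &
    rowSums(pos) <= config$max_product_molecules
}

#' Size of the unconstrained search space
#'
#' Number of raw `n_steps` x `n_species` integer matrices over the entry
#' range, i.e. `d^(n_steps * n_species)` with `d = entry_max - entry_min +
#' 1`.  This is the brute-force space the backtracking search avoids; the
#' feasible subset is typically a vanishing fraction of it.
#'
#' @inheritParams candidate_rows
#' @param n_steps number of rows.
#' @return A double holding the exact count (exact up to 2^53; beyond that a
#'   warning notes the loss of integer exactness).
#' @examples
#' search_space_size(2, 3)   # 5^6 = 15625
#' @export
search_space_size <- function(n_steps, n_species, config = enum_config(1L)) {
  n_steps <- as.integer(n_steps); n_species <- as.integer(n_species)
  if (is.na(n_steps) || n_steps < 1L || is.na(n_species) || n_species < 1L)
    stopf("'n_steps' and 'n_species' must be >= 1")
  d <- config$entry_max - config$entry_min + 1L
  e <- n_steps * n_species
  out <- 1
  for (i in seq_len(e)) out <- out * d
  if (out > 2^53)
    warning("search-space size exceeds 2^53; value no longer integer-exact")
  out
}

# Admissible entry range per column given the species role: overall
# reactants are only ever consumed, overall products only ever produced,
# intermediates may do either.
column_entry_range <- function(stoich, config) {
  tg <- stoich$targets
  inter <- seq_along(tg) > length(stoich$species_names)
  lo <- ifelse(!inter & tg > 0, 0L, config$entry_min)
  hi <- ifelse(!inter & tg < 0, 0L, config$entry_max)
  list(lo = as.integer(lo), hi = as.integer(hi), inter = inter)
}

#' Check a mechanism matrix against the feasibility rules
#'
#' Applies, in order, the rules a physically sensible ordered mechanism must
#' satisfy: matching dimensions; every entry in range; every step with at
#' least one reactant and one product within the molecularity caps; overall
#' reactants never produced and overall products never consumed by any
#' step; every species column summing to its overall coefficient (zero for
#' intermediates); cumulative intermediate availability (scanning steps
#' top-to-bottom, the running sum of an intermediate column may never go
#' negative, so nothing is consumed before it has been produced); and every
#' intermediate column used by at least one step.
#'
#' @param matrix integer matrix, steps x species (observed columns first,
#'   then intermediates).
#' @param stoich a [stoich_spec()].
#' @param config an [enum_config()]; `config$n_steps` must equal
#'   `nrow(matrix)`.
#' @return `TRUE`, or `FALSE` with attribute `rule` naming the first
#'   violated rule (one of `"entry_range"`, `"row_molecularity"`,
#'   `"species_role"`, `"column_sums"`, `"intermediate_ordering"`,
#'   `"intermediate_unused"`).
#' @export
is_feasible <- function(matrix, stoich, config = enum_config(nrow(matrix))) {
  stopifnot(inherits(stoich, "stoich_spec"))
  if (!is.matrix(matrix) || nrow(matrix) != config$n_steps ||
      ncol(matrix) != length(stoich$targets))
    stopf("matrix dimensions (%d x %d) do not match n_steps = %d and %d species",
          nrow(matrix), ncol(matrix), config$n_steps, length(stoich$targets))
  fail <- function(rule) structure(FALSE, rule = rule)
  if (any(matrix < config$entry_min | matrix > config$entry_max))
    return(fail("entry_range"))
  if (!all(row_predicate(matrix, config)))
    return(fail("row_molecularity"))
  rng <- column_entry_range(stoich, config)
  if (any(t(matrix) < rng$lo) || any(t(matrix) > rng$hi))
    return(fail("species_role"))
  if (!all(colSums(matrix) == stoich$targets))
    return(fail("column_sums"))
  for (j in which(rng$inter)) {
    if (any(cumsum(matrix[, j]) < 0)) return(fail("intermediate_ordering"))
  }
  for (j in which(rng$inter)) {
    if (all(matrix[, j] == 0)) return(fail("intermediate_unused"))
  }
  TRUE
}

#' Enumerate all feasible mechanism matrices
#'
#' Backtracking search over ordered mechanism matrices: candidate rows (from
#' [candidate_rows()], restricted to the admissible sign pattern of each
#' species role) are composed row by row, and a partial matrix is abandoned
#' as soon as an intermediate would be consumed before production or a
#' column sum can no longer reach its target with the remaining rows.  The
#' result equals the brute-force filter of the full Cartesian product
#' through [is_feasible()], in lexicographic matrix order.  Matrices
#' differing only by row permutation are distinct results (no
#' canonicalisation).
#'
#' With `config$n_workers > 1` the tree is partitioned by first-row
#' candidate and explored in parallel worker processes; the returned set is
#' identical for any worker count.
#'
#' @param stoich a [stoich_spec()] (including its intermediate count).
#' @param config an [enum_config()] giving the number of steps, entry
#'   bounds, molecularity caps, time budget and worker count.
#' @return List of integer mechanism matrices (with species column names),
#'   with attributes `complete` (`FALSE` iff the time budget expired first)
#'   and `n_candidate_rows`.
#' @examples
#' st <- stoich_spec(c(A = -4, B = 1, C = 1))
#' enumerate_mechanisms(st, enum_config(n_steps = 2))  # the two 2A->B / 2A->C orderings
#' @export
enumerate_mechanisms <- function(stoich, config) {
  stopifnot(inherits(stoich, "stoich_spec"), inherits(config, "enum_config"))
  n_sp <- length(stoich$targets)
  rows <- candidate_rows(n_sp, config)
  rng <- column_entry_range(stoich, config)
  # drop rows violating the species-role sign restrictions up front
  ok <- rep(TRUE, nrow(rows))
  for (j in seq_len(n_sp))
    ok <- ok & rows[, j] >= rng$lo[j] & rows[, j] <= rng$hi[j]
  rows <- rows[ok, , drop = FALSE]

  run_chunk <- function(first_idx, budget) {
    .Call("kinmech_enumerate", rows, as.integer(stoich$targets),
          config$n_steps, as.integer(rng$inter), rng$lo, rng$hi,
          config$max_reactant_molecules, config$max_product_molecules,
          as.double(if (is.finite(budget)) budget else -1),
          as.integer(first_idx), PACKAGE = "kinmech")
  }

  n_first <- nrow(rows)
  complete <- TRUE
  if (n_first == 0L) {
    mats <- list()
  } else if (config$n_workers <= 1L) {
    res <- run_chunk(seq_len(n_first), config$time_budget)
    mats <- res$matrices
    complete <- res$complete
  } else {
    chunks <- split(seq_len(n_first),
                    cut(seq_len(n_first), config$n_workers, labels = FALSE))
    res <- parallel::mclapply(chunks, run_chunk,
                              budget = config$time_budget,
                              mc.cores = config$n_workers,
                              mc.preschedule = TRUE)
    bad <- vapply(res, function(r) inherits(r, "try-error") || is.null(r$matrices),
                  TRUE)
    if (any(bad)) stopf("enumeration worker failed on chunk %d", which(bad)[1])
    mats <- unname(do.call(c, lapply(res, `[[`, "matrices")))
    complete <- all(vapply(res, `[[`, TRUE, "complete"))
  }
  if (!complete)
    warning("enumeration time budget expired; returning partial feasible set")
  mats <- lapply(mats, function(m) {
    colnames(m) <- stoich$all_species
    m
  })
  # canonical lexicographic order of serialised matrices (already true for a
  # single worker; enforced here so any worker count yields the same order)
  if (length(mats) > 1L) {
    key <- vapply(mats, function(m) paste(t(m), collapse = ","), "")
    mats <- mats[order(key, method = "radix")]
  }
  structure(mats, complete = complete, n_candidate_rows = nrow(rows))
}
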
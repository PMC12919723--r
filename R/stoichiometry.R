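#' Overall-reaction stoichiometry specification
#'
#' Describes the overall (net) reaction whose mechanism is sought: the
#' observed species with their signed integer coefficients (negative =
#' overall reactant, positive = overall product) plus a count of hidden
#' intermediate species.  Intermediates carry a zero net coefficient and are
#' appended as extra columns after the observed species; their names are
#' drawn from the unused letters of the alphabet (so `A, B, C` observed
#' yields intermediates `D, E, ...`), falling back to `I1, I2, ...` when the
#' alphabet runs out.
#'
#' @param coeffs named integer vector of signed overall coefficients, e.g.
#'   `c(A = -4, B = 1, C = 1)` for 4A -> B + C.  Zeros are rejected:
#'   intermediates are declared through `n_intermediates`, not zero entries.
#' @param n_intermediates non-negative count of hidden intermediate species.
#' @return An object of class `stoich_spec` with fields `species_names`,
#'   `overall_coeffs`, `n_intermediates`, `all_species` (observed then
#'   intermediates) and `targets` (column-sum targets including the
#'   intermediate zeros).
#' @examples
#' stoich_spec(c(A = -4, B = 1, C = 1), n_intermediates = 1)
#' @export
stoich_spec <- function(coeffs, n_intermediates = 0L) {
  if (is.null(names(coeffs)) || any(!nzchar(names(coeffs))))
    stopf("'coeffs' must be a fully named vector of signed coefficients")
  if (anyDuplicated(names(coeffs)))
    stopf("duplicate species name in stoichiometry: %s",
          names(coeffs)[duplicated(names(coeffs))][1])
  coeffs_int <- as.integer(coeffs)
  if (any(is.na(coeffs_int)) || any(coeffs_int != coeffs))
    stopf("overall coefficients must be integers")
  if (any(coeffs_int == 0))
    stopf("zero coefficients are not allowed; declare intermediates via 'n_intermediates'")
  if (!any(coeffs_int < 0) || !any(coeffs_int > 0))
    stopf("stoichiometry needs at least one reactant (negative) and one product (positive)")
  n_intermediates <- as.integer(n_intermediates)
  if (is.na(n_intermediates) || n_intermediates < 0)
    stopf("'n_intermediates' must be a non-negative integer")
  inter_names <- intermediate_names(names(coeffs), n_intermediates)
  structure(list(
    species_names   = names(coeffs),
    overall_coeffs  = setNames(coeffs_int, names(coeffs)),
    n_intermediates = n_intermediates,
    all_species     = c(names(coeffs), inter_names),
    targets         = c(coeffs_int, rep(0L, n_intermediates))
  ), class = "stoich_spec")
}

intermediate_names <- function(observed, n) {
  if (n == 0L) return(character(0))
  pool <- setdiff(LETTERS, observed)
  if (length(pool) >= n) pool[seq_len(n)] else paste0("I", seq_len(n))
}

#' Derive a stoichiometry with a different number of intermediates
#'
#' @param stoich a [stoich_spec()].
#' @param n_intermediates new intermediate count.
#' @return A new `stoich_spec` with the same observed species.
#' @export
set_intermediates <- function(stoich, n_intermediates) {
  stopifnot(inherits(stoich, "stoich_spec"))
  stoich_spec(stoich$overall_coeffs, n_intermediates)
}

#' Parse a stoichiometry string
#'
#' Accepts the compact `"A:-4,B:1,C:1"` dialect used by the command-line
#' interface: comma-separated `name:coefficient` tokens, in the order the
#' species columns should appear.
#'
#' @param text stoichiometry string, e.g. `"A:-1,B:3,C:1"` for A -> 3B + C.
#' @param n_intermediates intermediate count forwarded to [stoich_spec()].
#' @return A [stoich_spec()].
#' @examples
#' parse_stoichiometry("A:-4,B:1,C:1")
#' @export
parse_stoichiometry <- function(text, n_intermediates = 0L) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stopf("'text' must be a single non-empty string")
  tokens <- strsplit(text, ",", fixed = TRUE)[[1]]
  tokens <- trimws(tokens)
  m <- regmatches(tokens, regexec("^([A-Za-z][A-Za-z0-9_]*):([+-]?[0-9]+)$", tokens))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad))
    stopf("malformed stoichiometry token: '%s'", tokens[bad][1])
  coeffs <- vapply(m, function(x) as.integer(x[3]), 1L)
  names(coeffs) <- vapply(m, function(x) x[2], "")
  stoich_spec(coeffs, n_intermediates)
}

#' @export
print.stoich_spec <- function(x, ...) {
  lhs <- x$overall_coeffs[x$overall_coeffs < 0]
  rhs <- x$overall_coeffs[x$overall_coeffs > 0]
  side <- function(v) paste(ifelse(abs(v) == 1, names(v),
                                   paste0(abs(v), names(v))), collapse = " + ")
  cat("Overall reaction: ", side(lhs), " -> ", side(rhs), "\n", sep = "")
  if (x$n_intermediates > 0)
    cat("Intermediates:    ",
        paste(x$all_species[-seq_along(x$species_names)], collapse = ", "),
        "\n", sep = "")
  invisible(x)
}
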
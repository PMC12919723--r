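#' Mass-action model from a mechanism matrix
#'
#' Translates an integer mechanism matrix (rows = elementary steps, columns
#' = species, negative entries = consumed, positive = produced) into a
#' mass-action kinetic model.  Step `j` consumes each species with a
#' negative entry (multiplicity = absolute value), produces each species
#' with a positive entry, and owns rate-constant slot `j`; its rate is
#' `k_j * prod(C_i^multiplicity)` over its reactants.  The matrix stores net
#' coefficients, so no species appears on both sides of a step.
#'
#' @param matrix integer matrix of net stoichiometric coefficients; column
#'   names are taken as species names (defaulting to `S1, S2, ...`).
#' @param species_names optional character vector overriding column names.
#' @return An object of class `mass_action_model` with fields `steps` (each
#'   a list with `reactants`/`products` matrices of `(index, mult)` pairs
#'   and `rate_index`), `nu` (the net matrix), `order` (reactant
#'   multiplicity matrix), `n_species`, `n_params` and `species_names`.
#' @examples
#' mass_action_model(matrix(c(-1, -1, 1, 1), 1, 4,
#'                          dimnames = list(NULL, c("A", "B", "C", "D"))))
#' @export
mass_action_model <- function(matrix, species_names = colnames(matrix)) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stopf("'matrix' must be a numeric matrix")
  if (any(matrix != round(matrix))) stopf("matrix entries must be integers")
  if (any(rowSums(matrix != 0) == 0))
    stopf("invalid mechanism: all-zero (redundant) step")
  n_sp <- ncol(matrix)
  if (is.null(species_names)) species_names <- paste0("S", seq_len(n_sp))
  mode(matrix) <- "integer"
  steps <- lapply(seq_len(nrow(matrix)), function(j) {
    row <- matrix[j, ]
    ri <- which(row < 0); pi <- which(row > 0)
    list(reactants = cbind(index = ri, mult = -row[ri]),
         products  = cbind(index = pi, mult = row[pi]),
         rate_index = j)
  })
  ord <- pmax(-matrix, 0L)
  structure(list(
    steps = steps, nu = matrix, order = ord,
    n_species = n_sp, n_params = nrow(matrix),
    species_names = species_names
  ), class = "mass_action_model")
}

#' Render a model as reaction strings
#'
#' One line per elementary step in the `"2A -> B"` dialect: multiplicity
#' prefixes are omitted when 1 and terms joined with `" + "`.  The output is
#' parseable back with [parse_reactions()].
#'
#' @param model a [mass_action_model()].
#' @return Character vector, one reaction string per step.
#' @export
reaction_strings <- function(model) {
  stopifnot(inherits(model, "mass_action_model"))
  side <- function(tab) {
    paste(ifelse(tab[, "mult"] == 1, model$species_names[tab[, "index"]],
                 paste0(tab[, "mult"], model$species_names[tab[, "index"]])),
          collapse = " + ")
  }
  vapply(model$steps, function(s) paste(side(s$reactants), "->", side(s$products)), "")
}

#' Parse reaction strings into a model
#'
#' Inverse of [reaction_strings()].  Each line is `<terms> -> <terms>` where
#' a term is an optional integer multiplicity followed by a species name
#' (letters, then letters/digits/underscores); the unicode arrow is
#' accepted on input.  Species order follows `species_names` when given,
#' otherwise first appearance.
#'
#' @param lines character vector of reaction strings, one step per line.
#' @param species_names optional species ordering for the matrix columns.
#' @return A [mass_action_model()].
#' @export
parse_reactions <- function(lines, species_names = NULL) {
  lines <- trimws(lines[nzchar(trimws(lines))])
  if (!length(lines)) stopf("no reaction strings to parse")
  lines <- gsub("→", "->", lines, fixed = TRUE)
  parse_side <- function(txt, line) {
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    m <- regmatches(terms, regexec("^([0-9]*)\\s*([A-Za-z][A-Za-z0-9_]*)$", terms))
    if (any(vapply(m, length, 1L) == 0L))
      stopf("cannot parse reaction term in: '%s'", line)
    data.frame(
      species = vapply(m, `[`, "", 3),
      mult = vapply(m, function(x) if (nzchar(x[2])) as.integer(x[2]) else 1L, 1L)
    )
  }
  parsed <- lapply(lines, function(ln) {
    halves <- strsplit(ln, "->", fixed = TRUE)[[1]]
    if (length(halves) != 2L) stopf("reaction line lacks a single '->': '%s'", ln)
    list(lhs = parse_side(halves[1], ln), rhs = parse_side(halves[2], ln))
  })
  seen <- unique(unlist(lapply(parsed, function(p) c(p$lhs$species, p$rhs$species))))
  if (is.null(species_names)) species_names <- seen
  if (!all(seen %in% species_names))
    stopf("species %s not in 'species_names'",
          paste(setdiff(seen, species_names), collapse = ", "))
  nu <- matrix(0L, length(parsed), length(species_names),
               dimnames = list(NULL, species_names))
  for (j in seq_along(parsed)) {
    p <- parsed[[j]]
    nu[j, p$lhs$species] <- nu[j, p$lhs$species] - p$lhs$mult
    nu[j, p$rhs$species] <- nu[j, p$rhs$species] + p$rhs$mult
  }
  mass_action_model(nu)
}

#' Mass-action ODE right-hand side
#'
#' Derivatives of all species concentrations: each step's rate is its rate
#' constant times the product of its reactant concentrations raised to
#' their multiplicities, and `dC/dt = t(nu) %*% rates`.
#'
#' @param model a [mass_action_model()].
#' @param k non-negative rate-constant vector, one per step.
#' @param C concentration vector of length `model$n_species`.
#' @return Numeric derivative vector of length `model$n_species`.
#' @export
mass_action_rhs <- function(model, k, C) {
  stopifnot(inherits(model, "mass_action_model"))
  if (length(k) != model$n_params) stopf("'k' must have length %d", model$n_params)
  if (any(!is.finite(k)) || any(k < 0)) stopf("rate constants must be finite and >= 0")
  if (length(C) != model$n_species) stopf("'C' must have length %d", model$n_species)
  rates <- vapply(seq_len(model$n_params), function(j) {
    r <- k[j]
    tab <- model$steps[[j]]$reactants
    for (i in seq_len(nrow(tab))) r <- r * C[tab[i, "index"]]^tab[i, "mult"]
    r
  }, 0)
  drop(crossprod(model$nu, rates))
}

#' @export
print.mass_action_model <- function(x, ...) {
  cat("Mass-action model:", x$n_params, "step(s),", x$n_species, "species\n")
  cat(paste0("  k", seq_len(x$n_params), ": ", reaction_strings(x),
             collapse = "\n"), "\n")
  invisible(x)
}
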
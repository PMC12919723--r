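#' Write an experiment set as CSV plus JSON sidecar
#'
#' The CSV holds columns `experiment_id, time, <species...>` for the
#' observed species; the sidecar (same path with extension `.json`) holds
#' the full species vector, observed indices and each experiment's full
#' initial-condition vector (including intermediate zeros), so that
#' [read_experiments()] can rebuild the set losslessly.
#'
#' @param data an [experiment_set()].
#' @param path CSV output path.
#' @param sidecar sidecar path; defaults to `path` with a `.json` extension.
#' @return `path`, invisibly.
#' @export
write_experiments <- function(data, path, sidecar = sidecar_path(path)) {
  stopifnot(inherits(data, "experiment_set"))
  obs_names <- data$species_names[data$observed_indices]
  rows <- lapply(seq_along(data$experiments), function(i) {
    e <- data$experiments[[i]]
    df <- data.frame(experiment_id = i, time = e$t, e$y, check.names = FALSE)
    names(df)[-(1:2)] <- obs_names
    df
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  meta <- list(
    species_names = data$species_names,
    observed_indices = data$observed_indices,
    C0_full = lapply(data$experiments, `[[`, "C0_full")
  )
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]*$", ".json", path)

#' Read an experiment set from CSV plus JSON sidecar
#'
#' Parses `experiment_id, time, <species...>` rows, groups them by
#' experiment id (file order of the blocks is irrelevant), validates
#' strictly increasing time within each experiment, and attaches full
#' initial conditions from the sidecar; without a sidecar, initial
#' conditions default to the first observed row with intermediates at zero.
#'
#' @param path CSV path.
#' @param sidecar sidecar path (see [write_experiments()]); may be missing.
#' @return An [experiment_set()].
#' @export
read_experiments <- function(path, sidecar = sidecar_path(path)) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- read.csv(path, check.names = FALSE)
  need <- c("experiment_id", "time")
  if (!all(need %in% names(df)))
    stopf("missing required column(s): %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  sp_cols <- setdiff(names(df), need)
  if (!length(sp_cols)) stopf("no species columns found")
  for (cn in c("time", sp_cols)) {
    v <- df[[cn]]
    if (!is.numeric(v))
      stopf("non-numeric value in column '%s' (row %d)", cn,
            which(is.na(suppressWarnings(as.numeric(v))))[1])
  }
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE)
  species <- meta$species_names %||% sp_cols
  obs_idx <- as.integer(meta$observed_indices %||% match(sp_cols, species))
  ids <- sort(unique(df$experiment_id))
  exps <- lapply(seq_along(ids), function(i) {
    block <- df[df$experiment_id == ids[i], , drop = FALSE]
    block <- block[order(block$time), , drop = FALSE]
    dup <- duplicated(block$time)
    if (any(dup)) {
      row <- which(df$experiment_id == ids[i])[dup][1]
      stopf("duplicated time %g within experiment %s (file row %d)",
            block$time[dup][1], ids[i], row + 1L)
    }
    c0 <- if (!is.null(meta$C0_full)) {
      if (is.matrix(meta$C0_full)) meta$C0_full[i, ] else meta$C0_full[[i]]
    } else {
      c0 <- rep(0, length(species))
      c0[obs_idx] <- unlist(block[1, sp_cols])
      c0
    }
    kin_experiment(block$time, as.matrix(block[, sp_cols, drop = FALSE]),
                   obs_idx, c0)
  })
  experiment_set(exps, species)
}

#' Serialise mechanisms to JSON
#'
#' @param mechanisms list of mechanism matrices (as from
#'   [enumerate_mechanisms()]).
#' @param path JSON output path.
#' @param species_names column names; defaults to those of the first
#'   matrix.
#' @return `path`, invisibly.
#' @export
write_mechanisms <- function(mechanisms, path,
                             species_names = colnames(mechanisms[[1]])) {
  obj <- list(
    species_names = species_names,
    complete = attr(mechanisms, "complete") %||% TRUE,
    matrices = lapply(mechanisms, function(m)
      lapply(seq_len(nrow(m)), function(j) unname(m[j, ])))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read mechanisms from JSON
#'
#' @param path a file written by [write_mechanisms()].
#' @return List of integer mechanism matrices with a `complete` attribute.
#' @export
read_mechanisms <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  species <- as.character(unlist(obj$species_names))
  mats <- lapply(obj$matrices, function(rows) {
    m <- do.call(rbind, lapply(rows, function(r) as.integer(unlist(r))))
    colnames(m) <- species
    m
  })
  structure(mats, complete = isTRUE(obj$complete))
}

#' Write mechanisms as a reaction-string text file
#'
#' One mechanism per block, one `"2A -> B"` line per step, blocks separated
#' by blank lines.
#'
#' @inheritParams write_mechanisms
#' @export
write_reaction_file <- function(mechanisms, path) {
  blocks <- vapply(mechanisms, function(m)
    paste(reaction_strings(mass_action_model(m)), collapse = "\n"), "")
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' Serialise a discovery result to JSON
#'
#' Stable-keyed JSON with a schema version, per-iteration records (matrix,
#' reaction strings, estimates, SSE/NLL/AIC, candidate counts, enumeration
#' completeness), the winner's iteration index and the termination reason.
#'
#' @param result a [run_discovery()] result.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "discovery_result"))
  rec_json <- lapply(result$records, function(r) {
    out <- list(
      iteration_index = r$iteration_index,
      n_steps = r$n_steps, n_species = r$n_species,
      n_candidates = r$n_candidates,
      enumeration_complete = r$enumeration_complete
    )
    if (!is.null(r$best_fit)) {
      out$best_matrix <- lapply(seq_len(nrow(r$best_matrix)),
                                function(j) unname(r$best_matrix[j, ]))
      out$species_names <- colnames(r$best_matrix)
      out$reactions <- reaction_strings(r$best_model)
      out$k_hat <- r$best_fit$k_hat
      out$sse <- r$best_fit$sse
      out$nll <- r$best_fit$nll
      out$aic <- r$best_fit$aic
    }
    out
  })
  obj <- list(
    schema = "kinmech/discovery/v1",
    termination_reason = result$termination_reason,
    winner_iteration = if (!is.null(result$winner))
      result$winner$iteration_index,
    records = rec_json
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a discovery result written by [write_result()]
#'
#' @param path JSON path.
#' @return A list mirroring the serialised fields (matrices restored as
#'   integer matrices).
#' @export
read_result <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$records <- lapply(seq_len(nrow_or_len(obj$records)), function(i) {
    r <- if (is.data.frame(obj$records)) lapply(obj$records, `[[`, i)
         else obj$records[[i]]
    if (!is.null(r$best_matrix)) {
      m <- if (is.matrix(r$best_matrix)) r$best_matrix
           else do.call(rbind, r$best_matrix)
      mode(m) <- "integer"
      colnames(m) <- r$species_names
      r$best_matrix <- m
    }
    r
  })
  obj
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
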
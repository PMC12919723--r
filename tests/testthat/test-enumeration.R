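test_that("candidate rows match a direct filter of all entry vectors", {
  # independent predicate applied to every vector in {-2..2}^n
  brute <- function(n) {
    g <- as.matrix(expand.grid(rep(list(-2:2), n), KEEP.OUT.ATTRS = FALSE))
    neg <- pmin(g, 0); pos <- pmax(g, 0)
    g[rowSums(neg) < 0 & rowSums(pos) > 0 &
        rowSums(-neg) <= 2 & rowSums(pos) <= 2, , drop = FALSE]
  }
  for (n in 2:4) {
    got <- candidate_rows(n)
    want <- brute(n)
    expect_equal(nrow(got), nrow(want))
    expect_setequal(apply(got, 1, paste, collapse = ","),
                    apply(want, 1, paste, collapse = ","))
  }
  expect_equal(nrow(candidate_rows(2)), 8L)
  expect_equal(nrow(candidate_rows(3)), 36L)
  # a single species cannot host both a reactant and a product
  expect_equal(nrow(candidate_rows(1)), 0L)
  expect_error(candidate_rows(0), "n_species")
})

test_that("candidate rows come out in lexicographic order", {
  m <- candidate_rows(3)
  key <- apply(m, 1, paste, collapse = ",")
  ord <- do.call(order, as.data.frame(m))
  expect_equal(key, key[ord])
})

test_that("search-space size is exact integer arithmetic", {
  expect_identical(search_space_size(2, 3), 15625)
  expect_identical(search_space_size(3, 4), 244140625)
  expect_identical(search_space_size(4, 5), 95367431640625)
  expect_identical(search_space_size(1, 4), 625)
  expect_identical(search_space_size(1, 1), 5)
  expect_error(search_space_size(0, 3), ">= 1")
})

test_that("feasibility rules fire in order with diagnostic tags", {
  st <- stoich_spec(c(A = -4, B = 1, C = 1))
  cfg <- enum_config(2)
  ok <- is_feasible(rbind(c(-2, 1, 0), c(-2, 0, 1)), st, cfg)
  expect_true(ok)

  bad <- is_feasible(rbind(c(-2, 1, 1), c(-2, 0, 0)), st, cfg)
  expect_false(bad)
  expect_equal(attr(bad, "rule"), "row_molecularity")

  st1 <- stoich_spec(c(A = -2, B = 1), n_intermediates = 1L)
  # intermediate consumed in step 1, produced only in step 2
  bad <- is_feasible(rbind(c(-1, 1, -1), c(-1, 0, 1)), st1, cfg)
  expect_false(bad)
  expect_equal(attr(bad, "rule"), "intermediate_ordering")

  bad <- is_feasible(rbind(c(-2, 1, 0), c(-2, 1, 0)), st, cfg)
  expect_false(bad)
  expect_equal(attr(bad, "rule"), "column_sums")

  # overall product consumed by a step
  bad <- is_feasible(rbind(c(-2, 2, 0), c(-1, -1, 1)), st, cfg)
  expect_false(bad)
  expect_equal(attr(bad, "rule"), "species_role")

  expect_error(is_feasible(rbind(c(-2, 1, 0)), st, cfg), "dimensions")
})

test_that("backtracking equals the brute-force Cartesian filter", {
  cases <- list(
    list(coeffs = c(A = -4, B = 1, C = 1), n_inter = 0L, n_steps = 2L),
    list(coeffs = c(A = -1, B = -1, C = 1, D = 1), n_inter = 0L, n_steps = 1L),
    list(coeffs = c(A = -2, B = 1, C = 1), n_inter = 1L, n_steps = 2L),
    list(coeffs = c(A = -4, B = 1, C = 1), n_inter = 1L, n_steps = 3L)
  )
  for (cs in cases) {
    st <- stoich_spec(cs$coeffs, cs$n_inter)
    got <- enumerate_mechanisms(st, enum_config(cs$n_steps))
    want <- oracle_enumerate(cs$coeffs, cs$n_inter, cs$n_steps)
    expect_setequal(mech_keys(got), mech_keys(want))
    expect_true(attr(got, "complete"))
  }
})

test_that("enumeration counts reproduce the case-study iteration ladder", {
  st <- stoich_spec(c(A = -4, B = 1, C = 1))
  expect_length(enumerate_mechanisms(st, enum_config(2)), 2L)
  expect_length(enumerate_mechanisms(set_intermediates(st, 1), enum_config(3)), 31L)
  stf <- stoich_spec(c(A = -1, B = 3, C = 1), n_intermediates = 2L)
  expect_length(enumerate_mechanisms(stf, enum_config(3)), 10L)
  sta <- stoich_spec(c(A = -1, B = -1, C = 1, D = 1))
  m <- enumerate_mechanisms(sta, enum_config(1))
  expect_length(m, 1L)
  expect_equal(unname(m[[1]]), matrix(c(-1, -1, 1, 1), 1))
})

test_that("every emitted matrix is feasible", {
  cases <- list(
    list(st = stoich_spec(c(A = -4, B = 1, C = 1), 1L), steps = 3L),
    list(st = stoich_spec(c(A = -1, B = 3, C = 1), 2L), steps = 3L),
    list(st = stoich_spec(c(A = -1, B = -1, C = 1, D = 1), 1L), steps = 2L)
  )
  for (cs in cases) {
    cfg <- enum_config(cs$steps)
    mechs <- enumerate_mechanisms(cs$st, cfg)
    expect_gt(length(mechs), 0L)
    for (m in mechs) expect_true(is_feasible(m, cs$st, cfg))
  }
})

test_that("the feasible set is identical for any worker count", {
  st <- stoich_spec(c(A = -4, B = 1, C = 1), n_intermediates = 1L)
  ref <- enumerate_mechanisms(st, enum_config(3, n_workers = 1))
  for (w in c(2L, 4L)) {
    got <- enumerate_mechanisms(st, enum_config(3, n_workers = w))
    expect_identical(got[seq_along(got)], ref[seq_along(ref)])
  }
})

test_that("an expired time budget returns a flagged partial set", {
  st <- stoich_spec(c(A = -1, B = -1, C = 1, D = 1), n_intermediates = 3L)
  expect_warning(
    got <- enumerate_mechanisms(st, enum_config(4, time_budget = 1e-4)),
    "budget"
  )
  expect_false(attr(got, "complete"))
  full <- enumerate_mechanisms(st, enum_config(4))
  expect_true(attr(full, "complete"))
  expect_lte(length(got), length(full))
  expect_true(all(mech_keys(got) %in% mech_keys(full)))
})
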
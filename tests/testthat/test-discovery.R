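test_that("the complexity ladder adds one step and one intermediate per rung", {
  # hypothetical: 2x3 -> 3x4 -> 4x5 -> 5x6
  dims <- lapply(1:4, function(i) iteration_dimensions(2, 3, i))
  expect_equal(vapply(dims, `[[`, 0L, "n_steps"), 2:5)
  expect_equal(vapply(dims, `[[`, 0L, "n_species"), 3:6)
  # aldol iteration 3 is 3x6; fructose iteration 2 is 4x6
  expect_equal(iteration_dimensions(1, 4, 3), list(n_steps = 3L, n_species = 6L))
  expect_equal(iteration_dimensions(3, 5, 2), list(n_steps = 4L, n_species = 6L))
  expect_error(iteration_dimensions(1, 4, 0), ">= 1")
})

test_that("the ladder start helper respects the molecularity caps", {
  # 4A -> B + C needs two steps to consume four molecules of A
  expect_equal(ladder_start(stoich_spec(c(A = -4, B = 1, C = 1)))$min_steps, 2L)
  # A + B -> C + D fits in a single bimolecular step
  expect_equal(ladder_start(stoich_spec(c(A = -1, B = -1, C = 1, D = 1)))$min_steps, 1L)
  # A -> 3B + C must emit four product molecules: at least two steps
  expect_equal(ladder_start(stoich_spec(c(A = -1, B = 3, C = 1)))$min_steps, 2L)
})

test_that("an iteration fits all candidates and selects the AIC minimum", {
  data <- generate_aldol(seed = 4)
  st <- stoich_spec(c(A = -1, B = -1, C = 1, D = 1))
  rec <- run_iteration(st, data, 1, min_steps = 1, min_species = 4,
                       fit = fit_config(seed = 2))
  expect_equal(rec$n_candidates, 1L)
  expect_equal(unname(rec$best_matrix), matrix(c(-1, -1, 1, 1), 1))
  expect_equal(rec$best_fit$aic, min(rec$aic_table$aic))
  expect_true(rec$enumeration_complete)
})

test_that("row-permuted candidates are observationally tied", {
  # the two orderings of {2A -> B, 2A -> C} describe the same kinetics with
  # the rate-constant labels swapped, so their best fits essentially tie
  # (the lexicographically first candidate is reported on an exact tie)
  st <- stoich_spec(c(A = -4, B = 1, C = 1))
  true_m <- parse_reactions(c("2A -> B", "2A -> C"), c("A", "B", "C"))
  tt <- seq(0, 10, length.out = 12)
  data <- generate_generic(true_m, c(0.1, 0.15),
                           list(c(10, 0, 0), c(5, 1, 1)), tt, 1:3,
                           noise_sd = 0.15, seed = 8)
  rec <- run_iteration(st, data, 1, min_steps = 2, min_species = 3,
                       fit = fit_config(seed = 3))
  expect_equal(rec$n_candidates, 2L)
  expect_lt(diff(range(rec$aic_table$aic)), 0.5)
  expect_equal(rec$best_fit$aic, min(rec$aic_table$aic))
})

test_that("discovery stops on AIC worsening and returns the generator", {
  # data generated noiselessly from the only iteration-1 candidate: the
  # ladder must stop at iteration 2 and return the generating mechanism
  st <- stoich_spec(c(A = -1, B = -1, C = 1, D = 1))
  gen <- parse_reactions("A + B -> C + D")
  tt <- seq(0, 10, length.out = 15)
  data <- make_experiment_set(gen, 0.3,
                              list(c(5, 10, 0, 0), c(5, 5, 2, 0), c(8, 4, 0, 1)),
                              tt, 1:4)
  disc <- run_discovery(st, data, min_steps = 1, min_species = 4,
                        fit = fit_config(seed = 6), max_iterations = 3)
  expect_equal(disc$termination_reason, "aic_worsened")
  expect_equal(disc$winner$iteration_index, 1L)
  expect_length(disc$records, 2L)
  expect_equal(unname(disc$winner$best_matrix), unname(gen$nu))
  expect_lt(abs(disc$winner$best_fit$k_hat - 0.3), 1e-3)
  # winner AIC is the running minimum over all completed iterations
  aics <- vapply(disc$records, function(r) r$best_fit$aic, 0)
  expect_equal(disc$winner$best_fit$aic, min(aics))
})

test_that("an infeasible iteration yields an empty record", {
  st <- stoich_spec(c(A = -4, B = 1, C = 1))
  data <- generate_hypothetical(seed = 1)
  # a single step cannot consume four A under the bimolecular cap
  rec <- run_iteration(st, data, 1, min_steps = 1, min_species = 3,
                       fit = fit_config(seed = 1))
  expect_equal(rec$n_candidates, 0L)
  expect_null(rec$best_fit)
})
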
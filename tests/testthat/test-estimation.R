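test_that("the SSE accumulates squared residuals over all observations", {
  m <- parse_reactions("A -> B")
  tt <- seq(0, 4, length.out = 10)
  sim <- simulate_model(m, 0.5, c(1, 0), tt)$trajectory

  # data generated noiselessly from the model gives (near) zero SSE
  es <- kin_experiment(tt, sim, observed_indices = 1:2, C0_full = c(1, 0))
  data <- experiment_set(list(es), c("A", "B"))
  expect_lt(model_sse(m, 0.5, data), 1e-8)

  # a single residual of 0.5 contributes 0.25
  y <- sim
  y[5, "A"] <- y[5, "A"] + 0.5
  data2 <- experiment_set(list(kin_experiment(tt, y, 1:2, c(1, 0))),
                          c("A", "B"))
  expect_equal(model_sse(m, 0.5, data2), 0.25, tolerance = 1e-6)

  # the two objective engines agree
  expect_equal(model_sse(m, 0.5, data2, solver_opts(engine = "compiled")),
               model_sse(m, 0.5, data2, solver_opts(engine = "desolve")),
               tolerance = 1e-6)

  # unsolvable rates are charged the finite failure penalty
  m2 <- parse_reactions(c("2A -> B", "B -> A + C"), c("A", "B", "C"))
  d3 <- experiment_set(list(kin_experiment(tt, cbind(A = exp(-tt)), 1L,
                                           c(10, 0, 0))), c("A", "B", "C"))
  sse <- model_sse(m2, c(1e300, 1e300), d3, failure_penalty = 1e10)
  expect_true(is.finite(sse))
  expect_equal(sse, 1e10)
})

test_that("objective engines agree on the case-study models at random rates", {
  dd <- generate_aldol(seed = 3)
  cs <- case_study("aldol")
  full <- kinmech:::pad_experiment_set(dd, cs$stoich)
  set.seed(21)
  for (i in 1:5) {
    k <- runif(3, 0, 5)
    a <- model_sse(cs$true_model, k, full, solver_opts(engine = "compiled"))
    b <- model_sse(cs$true_model, k, full, solver_opts(engine = "desolve"))
    expect_equal(a, b, tolerance = 1e-5)
  }
})

test_that("the concentrated Gaussian NLL and the AIC follow their forms", {
  expect_equal(nll_from_sse(150, 150), 0)
  expect_equal(nll_from_sse(15, 150), 75 * log(0.1))   # ~ -172.69
  expect_equal(nll_from_sse(15, 150), -172.6939, tolerance = 1e-4)
  # strictly increasing in SSE at fixed N
  sses <- c(0.1, 1, 5, 20, 100)
  expect_true(all(diff(vapply(sses, nll_from_sse, 0, n_points = 50)) > 0))
  # zero SSE is floored, not -Inf
  expect_true(is.finite(nll_from_sse(0, 100)))

  expect_equal(aic_from_nll(0, 0), 0)
  expect_equal(aic_from_nll(10, 3), 26)
  # parsimony: equal fit, fewer parameters wins
  expect_lt(aic_from_nll(5, 2), aic_from_nll(5, 3))
})

test_that("fitting recovers rate constants from noiseless data", {
  m <- parse_reactions("A -> B")
  tt <- seq(0, 6, length.out = 20)
  data <- make_experiment_set(m, 0.5, list(c(1, 0), c(2, 0.5)), tt, 1:2)
  f <- fit_model(m, data, fit_config(seed = 5))
  expect_lt(abs(f$k_hat - 0.5), 1e-3)
  expect_lt(f$sse, 1e-6 * data$total_points)
  expect_true(f$converged)
  expect_equal(f$aic, 2 * f$nll + 2 * f$d)
})

test_that("noiseless recovery holds for every smallest aldol candidate", {
  st <- stoich_spec(c(A = -1, B = -1, C = 1, D = 1), n_intermediates = 1L)
  mechs <- enumerate_mechanisms(st, enum_config(2))
  tt <- seq(0, 10, length.out = 15)
  for (mm in mechs) {
    model <- mass_action_model(mm)
    k_true <- rep(0.4, model$n_params)
    data <- make_experiment_set(model, k_true,
                                list(c(5, 10, 0, 0, 0), c(5, 5, 2, 1, 0)),
                                tt, 1:4)
    f <- fit_model(model, data, fit_config(seed = 11))
    expect_lt(f$sse, 1e-6 * data$total_points)
  }
})

test_that("fits are deterministic and improve with more starts", {
  m <- parse_reactions("A -> B")
  tt <- seq(0, 6, length.out = 15)
  data <- make_experiment_set(m, 0.7, list(c(1, 0)), tt, 1:2)
  f1 <- fit_model(m, data, fit_config(seed = 9))
  f2 <- fit_model(m, data, fit_config(seed = 9))
  expect_equal(f1$sse, f2$sse, tolerance = 1e-10)
  expect_identical(f1$k_hat, f2$k_hat)

  # the single-start fit uses the first start of the five-start stream,
  # so adding starts can only improve the returned SSE
  s1 <- fit_model(m, data, fit_config(seed = 9, n_starts = 1))
  expect_gte(s1$sse + 1e-12, f1$sse)
  expect_equal(s1$per_start$sse[1], f1$per_start$sse[1], tolerance = 1e-12)
})
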
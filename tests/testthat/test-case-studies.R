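test_that("case-study definitions encode the study designs", {
  h <- case_study("hypothetical")
  expect_equal(h$true_k, c(0.1, 0.2, 0.13, 0.25))
  expect_equal(length(h$initial_conditions), 5L)
  expect_equal(h$times[c(1, 30)], c(0, 10))
  expect_equal(h$noise_sd, 0.15)
  # net consumption of A across the mechanism is four molecules
  expect_equal(colSums(h$true_model$nu), c(A = -4L, B = 1L, C = 1L, D = 0L, E = 0L))

  a <- case_study("aldol")
  expect_equal(a$true_k, c(0.759, 0.293, 0.681))
  expect_equal(reaction_strings(a$true_model),
               c("A -> E", "B + E -> F", "F -> C + D"))

  f <- case_study("fructose")
  expect_equal(f$true_k, 0.9 * 3.3e-2)
  expect_equal(f$times[c(1, 30)], c(0, 90))
  expect_equal(f$noise_sd, 0.2)
})

test_that("the Arrhenius helper reduces to k_ref at the reference temperature", {
  expect_equal(arrhenius_rate(), 0.9)
  expect_equal(arrhenius_rate(k_ref = 2, T_K = 410.15, T_ref = 410.15), 2)
  # higher temperature raises the rate for positive activation energy
  expect_gt(arrhenius_rate(Ea = 5e4, T_K = 420, T_ref = 410), 0.9)
  expect_error(arrhenius_rate(T_K = -1), "positive")
})

test_that("generators are deterministic in the seed and sized as designed", {
  for (gen in list(generate_hypothetical, generate_aldol, generate_fructose)) {
    d1 <- gen(seed = 42)
    d2 <- gen(seed = 42)
    expect_identical(d1, d2)
    d3 <- gen(seed = 43)
    expect_false(identical(d1, d3))
    expect_length(d1$experiments, 5L)
    expect_equal(sum(vapply(d1$experiments, function(e) length(e$t), 0)), 150)
  }
  # noiseless part is seed-independent
  expect_identical(generate_aldol(1, noiseless = TRUE),
                   generate_aldol(2, noiseless = TRUE))
})

test_that("noiseless trajectories satisfy the generating ODEs", {
  # finite-difference derivative of a fine-grid simulation vs the rhs
  for (name in c("hypothetical", "aldol")) {
    cs <- case_study(name)
    tt <- seq(0, 10, length.out = 2001)
    sim <- simulate_model(cs$true_model, cs$true_k,
                          cs$initial_conditions[[1]], tt)$trajectory
    mid <- seq(2, length(tt) - 1)
    fd <- (sim[mid + 1, ] - sim[mid - 1, ]) / (tt[3] - tt[1])
    rhs <- t(vapply(mid, function(i)
      mass_action_rhs(cs$true_model, cs$true_k, sim[i, ]),
      numeric(ncol(sim))))
    # relative to the local derivative scale: the initial transient of the
    # hypothetical system has |dA/dt| ~ 70, where absolute FD error is
    # dominated by curvature
    expect_lt(max(abs(fd - rhs) / (1 + abs(rhs))), 5e-3)
  }
})

test_that("aldol mass bookkeeping closes along noiseless paths", {
  d <- generate_aldol(seed = 1, noiseless = TRUE)
  cs <- case_study("aldol")
  for (i in seq_along(d$experiments)) {
    c0 <- cs$initial_conditions[[i]]
    sim <- simulate_model(cs$true_model, cs$true_k, c0, cs$times)$trajectory
    # every A consumed is in the enolate, the adduct, or the product
    consumed <- c0[1] - sim[, "A"]
    held <- (sim[, "E"] - c0[5]) + (sim[, "F"] - c0[6]) + (sim[, "C"] - c0[3])
    expect_lt(max(abs(consumed - held)), 1e-5)
  }
})

test_that("fructose follows the pseudo-first-order closed form", {
  d <- generate_fructose(seed = 3, noiseless = TRUE)
  cs <- case_study("fructose")
  k_eff <- 0.9 * 3.3e-2
  for (i in seq_along(d$experiments)) {
    e <- d$experiments[[i]]
    a0 <- e$C0_full[1]
    expect_lt(max(abs(e$y[, 1] - a0 * exp(-k_eff * e$t))), 1e-5)
    # water is produced three molecules per HMF
    expect_lt(max(abs((e$y[, 2] - e$C0_full[2]) -
                        3 * (e$y[, 3] - e$C0_full[3]))), 1e-5)
  }
})

test_that("noise is zero-mean at the stated standard deviation", {
  base <- generate_hypothetical(seed = 10, noiseless = TRUE)
  noisy <- lapply(1:14, function(s) generate_hypothetical(seed = 100 + s))
  resid <- unlist(lapply(noisy, function(d)
    mapply(function(a, b) a$y - b$y, d$experiments, base$experiments)))
  n <- length(resid)   # 14 replicates x 450 values > 6000 draws
  expect_lt(abs(mean(resid)), 3 * 0.15 / sqrt(n))
  expect_equal(sd(resid), 0.15, tolerance = 0.05)
})

test_that("the generic generator honours its noise contract", {
  m <- parse_reactions("A -> B")
  tt <- seq(0, 5, length.out = 10)
  clean <- generate_generic(m, 0.4, list(c(1, 0)), tt, 1:2, noise_sd = 0,
                            seed = 1)
  sim <- simulate_model(m, 0.4, c(1, 0), tt)$trajectory
  expect_equal(unname(clean$experiments[[1]]$y), unname(sim), tolerance = 1e-10)
  n1 <- generate_generic(m, 0.4, list(c(1, 0)), tt, 1:2, noise_sd = 0.1, seed = 1)
  n2 <- generate_generic(m, 0.4, list(c(1, 0)), tt, 1:2, noise_sd = 0.1, seed = 2)
  expect_false(identical(n1$experiments[[1]]$y, n2$experiments[[1]]$y))
})
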
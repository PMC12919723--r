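#' Bundled in-silico case studies
#'
#' Definitions of the three benchmark systems used throughout the package:
#'
#' * `hypothetical` — overall 4A -> B + C through two hidden intermediates
#'   (D, E) in four steps: 2A -> D, D -> B, E -> C, 2A -> E with rate
#'   constants `(0.1, 0.2, 0.13, 0.25)` (k1, k4 in 1/M/h; k2, k3 in 1/h).
#'   Five experiments on `[0, 10]` h, 30 samples, noise sd 0.15 on the
#'   observed species A, B, C.
#' * `aldol` — aldol condensation A + B -> C + D via enolization
#'   (A -> E), carbon-carbon coupling (E + B -> F) and dehydration
#'   (F -> C + D), `k = (0.759, 0.293, 0.681)`; noise sd 0.15 on A-D;
#'   intermediates E, F unobserved; `[0, 10]` h, 30 samples.
#' * `fructose` — dehydration of fructose A -> 3B + C driven by the
#'   literature rate law `r = k * C_A * C_acid` with constant acid
#'   concentration 3.3e-2 M and `k = 0.9` 1/M/min at 410.15 K, represented
#'   as a pseudo-first-order step with effective constant
#'   `k_eff = k * C_acid`; noise sd 0.2 on A, B, C; `[0, 90]` min,
#'   30 samples.
#'
#' @param name one of `"hypothetical"`, `"aldol"`, `"fructose"`.
#' @return A list of class `case_study`: `name`, `stoich`, `true_model`,
#'   `true_k`, `initial_conditions` (list of full C0 vectors), `times`,
#'   `noise_sd`, `observed_indices`, `min_steps`, `min_species` and
#'   `time_unit`.
#' @export
case_study <- function(name = c("hypothetical", "aldol", "fructose")) {
  name <- match.arg(name)
  cs <- switch(name,
    hypothetical = {
      st <- stoich_spec(c(A = -4, B = 1, C = 1), n_intermediates = 2L)
      nu <- matrix(c(
        -2, 0, 0, 1, 0,   # 2A -> D
         0, 1, 0, -1, 0,  # D -> B
         0, 0, 1, 0, -1,  # E -> C
        -2, 0, 0, 0, 1    # 2A -> E
      ), nrow = 4, byrow = TRUE, dimnames = list(NULL, st$all_species))
      list(stoich = st, nu = nu, k = c(0.1, 0.2, 0.13, 0.25),
           ics = list(c(10, 0, 2, 0, 0), c(10, 2, 0, 0, 0), c(10, 2, 2, 0, 0),
                      c(5, 0, 0, 0, 0), c(10, 0, 0, 0, 0)),
           times = seq(0, 10, length.out = 30), noise_sd = 0.15,
           observed = 1:3, min_steps = 2L, min_species = 3L, unit = "h")
    },
    aldol = {
      st <- stoich_spec(c(A = -1, B = -1, C = 1, D = 1), n_intermediates = 2L)
      nu <- matrix(c(
        -1, 0, 0, 0, 1, 0,   # A -> E        (enolization)
         0, -1, 0, 0, -1, 1, # E + B -> F    (C-C coupling)
         0, 0, 1, 1, 0, -1   # F -> C + D    (dehydration)
      ), nrow = 3, byrow = TRUE, dimnames = list(NULL, st$all_species))
      list(stoich = st, nu = nu, k = c(0.759, 0.293, 0.681),
           ics = list(c(5, 10, 0, 0, 0, 0), c(5, 5, 2, 0, 0, 0),
                      c(5, 10, 0, 2, 0, 0), c(10, 10, 0, 2, 0, 0),
                      c(10, 10, 2, 2, 0, 0)),
           times = seq(0, 10, length.out = 30), noise_sd = 0.15,
           observed = 1:4, min_steps = 1L, min_species = 4L, unit = "h")
    },
    fructose = {
      st <- stoich_spec(c(A = -1, B = 3, C = 1), n_intermediates = 0L)
      nu <- matrix(c(-1, 3, 1), nrow = 1,
                   dimnames = list(NULL, st$all_species))
      k_eff <- arrhenius_rate() * 3.3e-2   # pseudo-first-order k * C_acid
      list(stoich = st, nu = nu, k = k_eff,
           ics = list(c(4, 0, 0), c(6, 2, 1), c(4, 2, 0), c(4, 0, 1),
                      c(6, 2, 0)),
           times = seq(0, 90, length.out = 30), noise_sd = 0.2,
           observed = 1:3, min_steps = 3L, min_species = 5L, unit = "min")
    }
  )
  structure(list(
    name = name, stoich = cs$stoich,
    true_model = mass_action_model(cs$nu),
    true_k = cs$k, initial_conditions = cs$ics, times = cs$times,
    noise_sd = cs$noise_sd, observed_indices = cs$observed,
    min_steps = cs$min_steps, min_species = cs$min_species,
    time_unit = cs$unit
  ), class = "case_study")
}

#' Arrhenius rate constant
#'
#' `k = k_ref * exp(-Ea/R * (1/T - 1/T_ref))`; with `T == T_ref` the
#' exponential factor is 1 and `k = k_ref`.  Defaults are the fructose
#' case-study values (isothermal operation at 410.15 K).
#'
#' @param k_ref reference rate constant (1/M/min).
#' @param Ea activation energy (J/mol).
#' @param T_K,T_ref temperature and reference temperature (K).
#' @param R gas constant (J/K/mol).
#' @return Rate constant at `T_K`, same units as `k_ref`.
#' @export
arrhenius_rate <- function(k_ref = 0.9, Ea = 124, T_K = 410.15,
                           T_ref = 410.15, R = 8.314) {
  if (T_K <= 0 || T_ref <= 0) stopf("temperatures must be positive")
  k_ref * exp(-Ea / R * (1 / T_K - 1 / T_ref))
}

#' Generic simulate-then-perturb dataset generator
#'
#' Simulates `model` with rate constants `k` from each initial-condition
#' vector on the time grid and adds zero-mean Gaussian noise of standard
#' deviation `noise_sd` to the observed species (independently per value;
#' one generator stream per experiment, filled column-major: all times of
#' the first observed species, then the next).  Negative noisy values are
#' retained, preserving the zero-mean noise model.
#'
#' @param model a [mass_action_model()].
#' @param k rate constants used for generation.
#' @param initial_conditions list of full C0 vectors.
#' @param times sampling time grid shared by all experiments.
#' @param observed_indices which species are recorded in the dataset.
#' @param noise_sd per-value noise standard deviation (0 gives noiseless
#'   data equal to the simulation).
#' @param seed integer seed; the dataset is reproducible bitwise.
#' @param opts a [solver_opts()].
#' @return An [experiment_set()].
#' @export
generate_generic <- function(model, k, initial_conditions, times,
                             observed_indices, noise_sd, seed = 1L,
                             opts = solver_opts()) {
  stopifnot(inherits(model, "mass_action_model"))
  sims <- lapply(initial_conditions, function(c0) {
    sim <- simulate_model(model, k, c0, times, opts)
    if (!sim$success)
      stopf("data generation failed: %s", sim$message)
    sim$trajectory
  })
  noisy <- with_local_seed(seed, lapply(sims, function(tr) {
    y <- tr[, observed_indices, drop = FALSE]
    if (noise_sd > 0)
      y <- y + matrix(rnorm(length(y), 0, noise_sd), nrow(y), ncol(y))
    y
  }))
  exps <- lapply(seq_along(noisy), function(i)
    kin_experiment(times, noisy[[i]], observed_indices,
                   initial_conditions[[i]]))
  experiment_set(exps, model$species_names)
}

case_dataset <- function(name, seed, noiseless = FALSE) {
  cs <- case_study(name)
  generate_generic(cs$true_model, cs$true_k, cs$initial_conditions,
                   cs$times, cs$observed_indices,
                   if (noiseless) 0 else cs$noise_sd, seed = seed)
}

#' Generate the hypothetical-reaction dataset
#'
#' Five experiments at the study's initial conditions, 30 samples on
#' `[0, 10]` h, Gaussian noise sd 0.15 on A, B and C; intermediates D and E
#' are unobserved.  150 sampled times in total.
#'
#' @param seed integer seed.
#' @param noiseless generate without measurement noise.
#' @return An [experiment_set()].
#' @export
generate_hypothetical <- function(seed = 1L, noiseless = FALSE)
  case_dataset("hypothetical", seed, noiseless)

#' Generate the aldol-condensation dataset
#'
#' Five experiments, 30 samples on `[0, 10]` h, noise sd 0.15 on A-D;
#' intermediates E (enolate) and F (beta-hydroxy adduct) are unobserved.
#'
#' @inheritParams generate_hypothetical
#' @return An [experiment_set()].
#' @export
generate_aldol <- function(seed = 1L, noiseless = FALSE)
  case_dataset("aldol", seed, noiseless)

#' Generate the fructose-dehydration dataset
#'
#' Five experiments, 30 samples on `[0, 90]` min, noise sd 0.2 on A
#' (fructose), B (water) and C (HMF); generated from the pseudo-first-order
#' literature rate law (see [case_study()]).
#'
#' @inheritParams generate_hypothetical
#' @return An [experiment_set()].
#' @export
generate_fructose <- function(seed = 1L, noiseless = FALSE)
  case_dataset("fructose", seed, noiseless)
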
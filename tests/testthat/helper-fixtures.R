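# Small deterministic populations and a shared fitted chain, built once per
# test run.

# a compact clean population: 4 practices x 5 farms x 20 calves
small_clean_config <- function(seed = 99, ...) {
  sim_config(n_practices = 4,
             farms_per_practice = list(mean = 5, dispersion = 0),
             calves_per_farm = list(mean = 20, dispersion = 0),
             weighings_per_calf = list(mean = 3, dispersion = 0),
             birth_weight_rate = 1,
             seed = seed, ...)
}

# zero-variance configuration: weights deterministically on the mean curve,
# hence inside (30, 225] for all ages 0-138
flat_config <- function(seed = 1, ...) {
  sim_config(n_practices = 3,
             farms_per_practice = list(mean = 4, dispersion = 0),
             calves_per_farm = list(mean = 10, dispersion = 0),
             weighings_per_calf = list(mean = 3, dispersion = 0),
             var_practice = 0,
             cov_farm = matrix(0, 2, 2),
             var_calf_residual = 0,
             birth_weight_rate = 1,
             seed = seed, ...)
}

.fixture_env <- new.env(parent = emptyenv())

# shared fitted chain on a small clean population (2,000 stored draws)
get_test_fit <- function() {
  if (!exists("fit", envir = .fixture_env)) {
    sim <- simulate_population(small_clean_config())
    records <- append_birth_records(sim$records, sim$birth_weights)
    design <- build_design(records)
    chain <- run_mcmc(design,
                      settings = mcmc_settings(burn_in = 500,
                                               total_iterations = 4000,
                                               thin = 2, seed = 5),
                      store_ranef = TRUE)
    assign("fit", list(sim = sim, records = records, design = design,
                       chain = chain), envir = .fixture_env)
  }
  get("fit", envir = .fixture_env)
}

# independent pure-R Gibbs sampler for the two-level intercepts-only model
# y = mu + b_g + e; used as a brute-force reference for the C++ kernel
ref_two_level_gibbs <- function(y, g, n_iter = 20000, burn = 2000,
                                seed = 1) {
  set.seed(seed)
  G <- max(g); n <- length(y)
  ng <- tabulate(g, G)
  mu <- mean(y); b <- rep(0, G); var_b <- 1; var_e <- 1
  out <- matrix(NA_real_, n_iter, 2,
                dimnames = list(NULL, c("var_b", "var_e")))
  for (it in seq_len(burn + n_iter)) {
    mu <- rnorm(1, mean(y - b[g]), sqrt(var_e / n))
    r <- y - mu
    sums <- rowsum(r, g)[, 1]
    prec <- ng / var_e + 1 / var_b
    b <- rnorm(G, (sums / var_e) / prec, sqrt(1 / prec))
    var_b <- 1 / rgamma(1, 0.001 + G / 2, 0.001 + sum(b^2) / 2)
    var_e <- 1 / rgamma(1, 0.001 + n / 2,
                        0.001 + sum((r - b[g])^2) / 2)
    if (it > burn) out[it - burn, ] <- c(var_b, var_e)
  }
  out
}

# records tibble from bare vectors, single farm/practice unless given
make_records <- function(age, weight, farm = "F1", practice = "P1",
                         calf = paste0("C", seq_along(age)),
                         birth = as.Date("2015-01-01"),
                         estimate = FALSE) {
  tibble::tibble(practice_id = practice, farm_id = farm, calf_id = calf,
                 birth_date = birth, recording_date = birth + age,
                 age_days = as.integer(age), weight_kg = weight,
                 is_estimate = estimate, is_birth_weight = FALSE)
}
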
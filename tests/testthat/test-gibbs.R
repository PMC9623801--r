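test_that("stored draw count and determinism follow the schedule", {
  fit <- get_test_fit()
  des <- fit$design
  ch <- run_mcmc(des, settings = mcmc_settings(burn_in = 100,
                                               total_iterations = 1000,
                                               thin = 10, seed = 3))
  expect_equal(nrow(ch$draws), 100L)
  ch2 <- run_mcmc(des, settings = mcmc_settings(burn_in = 100,
                                                total_iterations = 1000,
                                                thin = 10, seed = 3))
  expect_identical(ch$draws, ch2$draws)
  ch3 <- run_mcmc(des, settings = mcmc_settings(burn_in = 100,
                                                total_iterations = 1000,
                                                thin = 10, seed = 4))
  expect_false(identical(ch$draws$alpha, ch3$draws$alpha))
})

test_that("no-random-effects sub-model matches the conjugate closed form", {
  # y = X beta + e with flat prior on beta and Gamma(a, b) on the precision:
  # marginally E[beta | y] is the OLS estimate and
  # E[sigma^2 | y] = (b + SSE/2) / (a + (n - p)/2 - 1)
  set.seed(42)
  n <- 300
  age <- sample(1:138, n, replace = TRUE)
  y <- 40 + 0.6 * age + 0.001 * age^2 + rnorm(n, 0, 3)
  rec <- make_records(age = age, weight = y)
  des <- build_design(rec)
  ch <- run_mcmc(des, settings = mcmc_settings(burn_in = 1000,
                                               total_iterations = 20000,
                                               thin = 4, seed = 9),
                 include_practice = FALSE, include_farm = FALSE)
  ols <- lm(y ~ age + I(age^2))
  bhat <- unname(coef(ols))
  sse <- sum(residuals(ols)^2)
  a <- b <- 0.001
  evar <- (b + sse / 2) / (a + (n - 3) / 2 - 1)
  for (i in seq_len(3)) {
    col <- ch$draws[[c("alpha", "beta_age", "beta_age2")[i]]]
    mcse <- sd(col) / sqrt(effective_sample_size(col))
    expect_lt(abs(mean(col) - bhat[i]), 3 * mcse)
  }
  ve <- ch$draws$var_residual
  mcse_v <- sd(ve) / sqrt(effective_sample_size(ve))
  expect_lt(abs(mean(ve) - evar), 3 * mcse_v)
})

test_that("two-level toy agrees with an independent reference sampler", {
  # balanced 5 groups x 20 observations, intercepts only
  set.seed(7)
  G <- 5; m <- 20
  g <- rep(seq_len(G), each = m)
  b_true <- rnorm(G, 0, 2)
  y <- 50 + b_true[g] + rnorm(G * m, 0, 1)
  rec <- make_records(age = rep(1:m, G), weight = y,
                      farm = paste0("F", g), practice = paste0("P", g),
                      calf = paste0("C", seq_along(y)))
  des <- build_design(rec, degree = 0L)
  ch <- run_mcmc(des, settings = mcmc_settings(burn_in = 2000,
                                               total_iterations = 40000,
                                               thin = 2, seed = 11),
                 include_farm = FALSE)
  ref <- ref_two_level_gibbs(y, g, n_iter = 40000, burn = 2000, seed = 12)
  for (term in c("var_practice", "var_residual")) {
    ours <- ch$draws[[term]]
    theirs <- ref[, if (term == "var_practice") "var_b" else "var_e"]
    se <- sqrt(sd(ours)^2 / effective_sample_size(ours) +
               sd(theirs)^2 / effective_sample_size(theirs))
    expect_lt(abs(mean(ours) - mean(theirs)), 3 * se)
  }
})

test_that("a single Gibbs sweep preserves state shape and validity", {
  fit <- get_test_fit()
  ini <- init_state(fit$design)
  set.seed(1)
  st <- gibbs_step(ini$state, fit$design, S_u = ini$S_u)
  expect_named(st, c("beta", "v", "U", "var_practice", "cov_farm",
                     "var_residual"))
  expect_length(st$v, fit$design$n_practice)
  expect_equal(dim(st$U), c(fit$design$n_farm, 2L))
  expect_gt(st$var_practice, 0)
  expect_gt(st$var_residual, 0)
  ev <- eigen(st$cov_farm, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_false(isTRUE(all.equal(st$beta, ini$state$beta)))
})

test_that("with no farm data the Wishart update reduces to the prior", {
  # prior: precision ~ Wishart(df0, R0^-1), so E[precision] = df0 * R0^-1;
  # empty-data draws must reproduce that expectation
  S_u <- matrix(c(4.391, 0.024, 0.024, 0.017), 2)
  R0 <- 2 * S_u
  set.seed(33)
  draws <- replicate(4000, calfgrowth:::.rwishart(2, solve(R0)))
  expect_equal(apply(draws, 1:2, mean), 2 * solve(R0), tolerance = 0.1)
})

test_that("split-half means of the residual variance are stable", {
  ch <- get_test_fit()$chain
  ve <- ch$draws$var_residual
  h <- length(ve) %/% 2
  a <- ve[seq_len(h)]; b <- ve[(h + 1):length(ve)]
  se <- sqrt(sd(a)^2 / effective_sample_size(a) +
             sd(b)^2 / effective_sample_size(b))
  expect_lt(abs(mean(a) - mean(b)), 3 * se)
})

test_that("doubling the data contracts the posterior for the age slope", {
  sds <- purrr::map_dbl(c(10, 20), function(cpf) {
    cfg <- sim_config(n_practices = 4,
                      farms_per_practice = list(mean = 4, dispersion = 0),
                      calves_per_farm = list(mean = cpf, dispersion = 0),
                      weighings_per_calf = list(mean = 3, dispersion = 0),
                      birth_weight_rate = 1, seed = 500 + cpf)
    sim <- simulate_population(cfg)
    des <- build_design(append_birth_records(sim$records,
                                             sim$birth_weights))
    ch <- run_mcmc(des, settings = mcmc_settings(burn_in = 500,
                                                 total_iterations = 4000,
                                                 thin = 2, seed = 1))
    sd(ch$draws$beta_age)
  })
  expect_lt(sds[2], sds[1])
})
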
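ref <- calf_reference_params()

test_that("per-level variances follow the random-slope variance function", {
  v0 <- variance_at_age(ref, 0)
  expect_equal(v0$farm, 2.37)
  expect_equal(v0$total, 98.06)
  v130 <- variance_at_age(ref, 130)
  # 2.37 + 2*130*0.007 + 130^2*0.019
  expect_equal(v130$farm, 325.29)
  expect_equal(v130$practice, 13.04)
  expect_equal(v130$calf, 82.65)
  # degenerate slope: farm variance constant in age
  flat <- dplyr::mutate(ref, cov_farm_int_slope = 0, var_farm_slope = 0)
  expect_equal(variance_at_age(flat, 0)$farm,
               variance_at_age(flat, 130)$farm)
  neg <- dplyr::mutate(ref, cov_farm_int_slope = -5)
  expect_error(variance_at_age(neg, 130), "positive definite")
})

test_that("plug-in VPCs reproduce the published shares at ages 0 and 130", {
  prof <- vpc_profile(ref, ages = c(0, 130))
  get <- function(a, lv, col = "mean")
    prof[[col]][prof$age == a & prof$level == lv]
  expect_equal(round(get(0, "calf"), 2), 0.84)
  expect_equal(round(get(0, "farm"), 2), 0.02)
  expect_equal(round(get(130, "farm"), 2), 0.77)
  expect_equal(round(get(130, "calf"), 2), 0.20)
  # a one-row draw table is a degenerate chain: mean == plug-in exactly
  expect_equal(prof$mean, prof$plugin)
})

test_that("VPC draws sum to one at every age on a fitted chain", {
  ch <- get_test_fit()$chain
  for (a in c(0, 1, 60, 130)) {
    v <- variance_at_age(ch, a)
    shares <- (v$practice + v$farm + v$calf) / v$total
    expect_equal(shares, rep(1, nrow(v)), tolerance = 1e-12)
  }
  prof <- vpc_profile(ch, ages = c(0, 66, 130))
  sums <- prof |>
    dplyr::group_by(age) |>
    dplyr::summarise(s = sum(mean))
  expect_equal(sums$s, rep(1, 3), tolerance = 1e-12)
})

test_that("farm VPC grows with age when the slope variance is positive", {
  ch <- get_test_fit()$chain
  prof <- vpc_profile(ch, ages = c(0, 130))
  farm <- prof[prof$level == "farm", ]
  expect_lt(farm$mean[farm$age == 0], farm$mean[farm$age == 130])
})

test_that("simulated random effects reproduce the variance shares", {
  # Monte Carlo check of the variance function at age 60 from one draw
  set.seed(60)
  n <- 1e5
  age <- 60
  v <- rnorm(n, 0, sqrt(ref$var_practice))
  U <- matrix(rnorm(2 * n), n, 2) %*%
    chol(matrix(c(ref$var_farm_int, ref$cov_farm_int_slope,
                  ref$cov_farm_int_slope, ref$var_farm_slope), 2))
  e <- rnorm(n, 0, sqrt(ref$var_residual))
  contrib <- cbind(v, U[, 1] + U[, 2] * age, e)
  emp <- apply(contrib, 2, var)
  theo <- variance_at_age(ref, age)
  expect_equal(emp[1] / sum(emp), theo$practice / theo$total,
               tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(emp[2] / sum(emp), theo$farm / theo$total,
               tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(emp[3] / sum(emp), theo$calf / theo$total,
               tolerance = 0.02, ignore_attr = TRUE)
})

test_that("growth rates reproduce the published derivative and chord", {
  expect_equal(round(growth_rate(ref, 1)$mean, 2), 0.59)
  expect_equal(round(growth_rate(ref, 138)$mean, 2), 0.87)
  expect_equal(round(cumulative_growth_rate(ref, 138)$mean, 2), 0.73)
  # beta2 = 0: rate constant and equal to beta1 everywhere
  lin <- dplyr::mutate(ref, beta_age2 = 0)
  expect_equal(growth_rate(lin, c(1, 70, 138))$mean, rep(0.59, 3))
  expect_equal(cumulative_growth_rate(lin, 138)$mean, 0.59)
  expect_error(cumulative_growth_rate(ref, 0))
})

test_that("cumulative rate equals the chord slope of the mean curve", {
  ch <- get_test_fit()$chain
  d <- ch$draws
  for (h in c(30, 138)) {
    curve <- function(a) d$alpha + d$beta_age * a + d$beta_age2 * a^2
    chord <- (curve(h) - curve(0)) / h
    expect_equal(mean(chord), cumulative_growth_rate(ch, h)$mean,
                 tolerance = 1e-12)
  }
})

test_that("gaussian cluster coverage reproduces the published endpoints", {
  cov <- cluster_mean_coverage(ref, "birth_weight")
  expect_equal(round(cov$mean), c(34, 49))
  # zero cluster variances collapse the interval to the mean
  degen <- dplyr::mutate(ref, var_practice = 0, var_farm_int = 0)
  cov0 <- cluster_mean_coverage(degen, "birth_weight")
  expect_equal(cov0$mean, c(41.26, 41.26))
  rate <- cluster_mean_coverage(ref, "cumulative_rate", horizon = 138)
  expect_equal(rate$mean,
               0.59 + 0.001 * 138 + qnorm(c(0.025, 0.975)) * sqrt(0.019),
               tolerance = 1e-12)
})

test_that("empirical coverage matches direct quantiles of cluster means", {
  fit <- get_test_fit()
  truth <- fit$sim$truth
  # degenerate one-draw chain carrying the generator's true effects
  fp <- match(truth$farm_effects$practice_id,
              truth$practice_effects$practice_id)
  ch <- calfgrowth:::new_calf_chain(
    dplyr::mutate(calf_reference_params(), .draw = 1, deviance = 0),
    ranef = list(
      practice = truth$practice_effects,
      farm = dplyr::transmute(truth$farm_effects, farm_id, practice_id,
                              u_int, u_slope),
      v_draws = matrix(truth$practice_effects$v, 1),
      U_draws = matrix(c(truth$farm_effects$u_int,
                         truth$farm_effects$u_slope), 1)))
  emp <- cluster_mean_coverage(ch, "birth_weight", method = "empirical")
  direct <- quantile(41.26 + truth$practice_effects$v[fp] +
                       truth$farm_effects$u_int, c(0.025, 0.975))
  expect_equal(emp$mean, unname(direct))
  # empirical method demands stored random-effect draws
  bare <- calfgrowth:::new_calf_chain(fit$chain$draws)
  expect_error(cluster_mean_coverage(bare, method = "empirical"),
               "store_ranef")
})

test_that("posterior predictive weight behaves as a normal mixture", {
  ch <- get_test_fit()$chain
  pp <- posterior_predictive_weight(ch, age = 60, interval = c(60, 100))
  med <- pp$quantiles$weight_kg[pp$quantiles$prob == 0.5]
  # symmetry: an interval and its reflection about the mixture centre have
  # equal probability for the symmetric per-draw normals of a degenerate
  # chain; on a real chain the median-centred quantiles must bracket it
  expect_true(all(diff(pp$quantiles$weight_kg) > 0))
  expect_gt(pp$interval_probability, 0)
  expect_lt(pp$interval_probability, 1)

  degen <- posterior_predictive_weight(ref, age = 60)
  mu <- ref$alpha + ref$beta_age * 60 + ref$beta_age2 * 3600
  lo <- posterior_predictive_weight(ref, age = 60,
                                    interval = mu + c(-10, 0))
  hi <- posterior_predictive_weight(ref, age = 60,
                                    interval = mu + c(0, 10))
  expect_equal(lo$interval_probability, hi$interval_probability,
               tolerance = 1e-9)

  # probabilities over a partition of the line sum to one
  cuts <- c(-Inf, 40, 60, 80, 100, Inf)
  probs <- purrr::map_dbl(seq_len(length(cuts) - 1), function(i)
    posterior_predictive_weight(ch, age = 60,
      interval = c(cuts[i], cuts[i + 1]))$interval_probability)
  expect_equal(sum(probs), 1, tolerance = 1e-9)

  # zero-variance draws give a point mass at the curve value
  point <- dplyr::mutate(ref, var_practice = 0, var_farm_int = 0,
                         cov_farm_int_slope = 0, var_farm_slope = 0,
                         var_residual = 0)
  pp0 <- posterior_predictive_weight(point, age = 60,
                                     interval = c(mu - 1, mu + 1))
  expect_equal(pp0$interval_probability, 1)
  expect_equal(pp0$quantiles$weight_kg, rep(mu, 5), ignore_attr = TRUE)
  expect_error(posterior_predictive_weight(ch, 60, interval = c(2, 1)),
               "a <= b")
})
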
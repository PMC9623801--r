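#' Coerce to a table of parameter draws
#'
#' Derived-quantity functions accept either a fitted `calf_chain` or a plain
#' data frame of parameter draws (one row per draw). A one-row data frame —
#' for example [calf_reference_params()] — acts as a degenerate chain and
#' yields plug-in values.
#'
#' @param x A `calf_chain` or data frame with (a subset of) the columns
#'   `alpha`, `beta_age`, `beta_age2`, `var_practice`, `var_farm_int`,
#'   `cov_farm_int_slope`, `var_farm_slope`, `var_residual`.
#' @param need Character vector of required columns.
#' @return A tibble of draws.
#' @keywords internal
param_draws <- function(x, need = param_cols) {
  d <- if (inherits(x, "calf_chain")) x$draws else tibble::as_tibble(x)
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("draw table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  d
}

#' Per-level variances at a given age
#'
#' Under the random-slope model the unexplained variance at age \eqn{a}
#' splits into a constant practice component \eqn{\sigma_v^2}, a farm
#' component that is quadratic in age,
#' \eqn{\sigma_{u0}^2 + 2 a \sigma_{u01} + a^2 \sigma_{u1}^2},
#' and a constant calf-level residual \eqn{\sigma_e^2}.
#'
#' @param x A `calf_chain` or data frame of draws (see [param_draws()]).
#' @param age Age in days (scalar or vector).
#' @return A tibble with one row per draw and age: `.draw`, `age`,
#'   `practice`, `farm`, `calf`, `total`.
#' @examples
#' variance_at_age(calf_reference_params(), age = c(0, 130))
#' @export
variance_at_age <- function(x, age) {
  d <- param_draws(x, need = c("var_practice", "var_farm_int",
                               "cov_farm_int_slope", "var_farm_slope",
                               "var_residual"))
  purrr::map_dfr(age, function(a) {
    farm <- d$var_farm_int + 2 * a * d$cov_farm_int_slope +
      a^2 * d$var_farm_slope
    if (any(farm < 0))
      stop("negative farm-level variance at age ", a,
           ": farm covariance matrix not positive definite", call. = FALSE)
    tibble::tibble(.draw = seq_len(nrow(d)), age = a,
                   practice = d$var_practice, farm = farm,
                   calf = d$var_residual,
                   total = d$var_practice + farm + d$var_residual)
  })
}

#' Variance partition coefficients across ages
#'
#' For every stored draw and every age on the grid, the VPC at a level is
#' that level's variance share of the total unexplained variance at that age
#' ([variance_at_age()]). By construction the three shares sum to one for
#' every draw and age. Two point estimates are reported: the posterior mean
#' of the per-draw ratio (`mean`) and the plug-in ratio evaluated at the
#' posterior means of the components (`plugin`); for a one-row draw table
#' they coincide.
#'
#' @param x A `calf_chain` or data frame of draws.
#' @param ages Integer age grid in days (default 0--130).
#' @return A tibble of class `vpc_profile`: `age`, `level` (factor practice /
#'   farm / calf), `mean`, `median`, `q025`, `q975`, `plugin`.
#' @examples
#' vpc_profile(calf_reference_params(), ages = c(0, 130))
#' @export
vpc_profile <- function(x, ages = 0:130) {
  d <- param_draws(x, need = c("var_practice", "var_farm_int",
                               "cov_farm_int_slope", "var_farm_slope",
                               "var_residual"))
  means <- dplyr::summarise(d, dplyr::across(dplyr::any_of(param_cols), mean))
  out <- purrr::map_dfr(ages, function(a) {
    v <- variance_at_age(d, a)
    pv <- variance_at_age(means, a)
    purrr::map_dfr(c("practice", "farm", "calf"), function(lv) {
      share <- v[[lv]] / v$total
      tibble::tibble(age = a, level = lv,
                     mean = mean(share), median = median(share),
                     q025 = quantile(share, 0.025),
                     q975 = quantile(share, 0.975),
                     plugin = pv[[lv]] / pv$total)
    })
  })
  out$level <- factor(out$level, levels = c("practice", "farm", "calf"))
  class(out) <- c("vpc_profile", class(out))
  out
}

#' @rdname vpc_profile
#' @param object A `vpc_profile` (for `autoplot`).
#' @param ... Unused.
#' @export
autoplot.vpc_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$age, .data$mean,
                                       colour = .data$level,
                                       fill = .data$level)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q025, ymax = .data$q975),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "calf age (d)", y = "variance partition coefficient",
                  colour = "level", fill = "level") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Instantaneous growth rate
#'
#' The derivative of the quadratic mean growth curve,
#' \eqn{\beta_1 + 2 \beta_2 a}, per draw, summarized over draws.
#'
#' @param x A `calf_chain` or data frame of draws.
#' @param ages Ages in days at which to evaluate the rate.
#' @return A tibble: `age`, `mean`, `median`, `q025`, `q975` (kg/day).
#' @examples
#' growth_rate(calf_reference_params(), ages = c(1, 138))
#' @export
growth_rate <- function(x, ages) {
  d <- param_draws(x, need = c("beta_age", "beta_age2"))
  purrr::map_dfr(ages, function(a) {
    rate <- d$beta_age + 2 * d$beta_age2 * a
    tibble::tibble(age = a, mean = mean(rate), median = median(rate),
                   q025 = quantile(rate, 0.025),
                   q975 = quantile(rate, 0.975))
  })
}

#' Cumulative mean growth rate to a horizon
#'
#' The chord slope of the quadratic mean curve between birth and the horizon:
#' \eqn{(\mu(h) - \mu(0)) / h = \beta_1 + \beta_2 h} (kg/day).
#'
#' @param x A `calf_chain` or data frame of draws.
#' @param horizon Horizon in days (> 0).
#' @return A tibble: `horizon`, `mean`, `median`, `q025`, `q975`.
#' @examples
#' cumulative_growth_rate(calf_reference_params(), horizon = 138)
#' @export
cumulative_growth_rate <- function(x, horizon) {
  stopifnot(horizon > 0)
  d <- param_draws(x, need = c("beta_age", "beta_age2"))
  purrr::map_dfr(horizon, function(h) {
    rate <- d$beta_age + d$beta_age2 * h
    tibble::tibble(horizon = h, mean = mean(rate), median = median(rate),
                   q025 = quantile(rate, 0.025),
                   q975 = quantile(rate, 0.975))
  })
}

#' Quantile coverage of cluster-specific means
#'
#' The spread of practice-farm cluster means for either birth weight or the
#' cumulative growth rate to a horizon. The default gaussian method uses the
#' model's own distributional assumptions per draw: for birth weight the
#' cluster mean is \eqn{\alpha + v_k + u_{0jk}} so the `q`-quantile band is
#' \eqn{\alpha \pm z_q \sqrt{\sigma_v^2 + \sigma_{u0}^2}}; for the cumulative
#' rate only the farm slope varies between clusters, giving
#' \eqn{(\beta_1 + \beta_2 h) \pm z_q \sigma_{u1}}. The empirical method
#' instead takes quantiles of the realized cluster means across the sampled
#' clusters of each stored draw, which requires a chain fitted with
#' `store_ranef = TRUE`.
#'
#' @param x A `calf_chain` or data frame of draws.
#' @param quantity `"birth_weight"` or `"cumulative_rate"`.
#' @param quantiles Lower and upper cluster quantiles (default 0.025, 0.975).
#' @param method `"gaussian"` (default) or `"empirical"`.
#' @param horizon Horizon in days for `"cumulative_rate"` (default 138).
#' @return A tibble with one row per endpoint: `quantity`, `quantile`,
#'   `mean`, `median`, `q025`, `q975` (posterior summaries of the endpoint).
#' @examples
#' cluster_mean_coverage(calf_reference_params(), "birth_weight")
#' @export
cluster_mean_coverage <- function(x,
                                  quantity = c("birth_weight",
                                               "cumulative_rate"),
                                  quantiles = c(0.025, 0.975),
                                  method = c("gaussian", "empirical"),
                                  horizon = 138) {
  quantity <- match.arg(quantity)
  method <- match.arg(method)
  stopifnot(length(quantiles) == 2L, quantiles[1] < quantiles[2])
  if (method == "gaussian") {
    d <- param_draws(x, need = switch(quantity,
      birth_weight = c("alpha", "var_practice", "var_farm_int"),
      cumulative_rate = c("beta_age", "beta_age2", "var_farm_slope")))
    centre <- switch(quantity,
                     birth_weight = d$alpha,
                     cumulative_rate = d$beta_age + d$beta_age2 * horizon)
    spread <- switch(quantity,
                     birth_weight = sqrt(d$var_practice + d$var_farm_int),
                     cumulative_rate = sqrt(d$var_farm_slope))
    ends <- purrr::map(quantiles, ~ centre + qnorm(.x) * spread)
  } else {
    if (!inherits(x, "calf_chain") || is.null(x$ranef$v_draws))
      stop("empirical method needs a calf_chain fitted with ",
           "store_ranef = TRUE", call. = FALSE)
    d <- x$draws
    J <- nrow(x$ranef$farm)
    fp <- match(x$ranef$farm$practice_id, x$ranef$practice$practice_id)
    cl_means <- function(i) switch(quantity,
      birth_weight = d$alpha[i] + x$ranef$v_draws[i, fp] +
        x$ranef$U_draws[i, seq_len(J)],
      cumulative_rate = d$beta_age[i] + d$beta_age2[i] * horizon +
        x$ranef$U_draws[i, J + seq_len(J)])
    qs <- vapply(seq_len(nrow(d)),
                 function(i) quantile(cl_means(i), quantiles),
                 numeric(2L))
    ends <- list(qs[1L, ], qs[2L, ])
  }
  purrr::map2_dfr(ends, quantiles, function(e, q)
    tibble::tibble(quantity = quantity, quantile = q,
                   mean = mean(e), median = median(e),
                   q025 = quantile(e, 0.025), q975 = quantile(e, 0.975)))
}

#' Posterior predictive weight distribution at an age
#'
#' For each stored draw the predictive weight at age \eqn{a} is normal with
#' mean equal to the fixed quadratic curve and variance depending on scope:
#' `"median_cluster"` conditions on a typical farm and practice (random
#' effects zero, residual variance only), while `"population"` adds the
#' practice and age-dependent farm variance, describing a calf from an
#' unknown farm. Quantiles of the draw-mixture are returned, plus the mixture
#' probability that weight falls inside `interval` — the quantity used to set
#' proportion-based weight-for-age targets.
#'
#' @param x A `calf_chain` or data frame of draws.
#' @param age Age in days.
#' @param scope `"median_cluster"` (default) or `"population"`.
#' @param probs Predictive quantiles to report.
#' @param interval Optional `c(a, b)` weight interval (kg), `a <= b`.
#' @return A list of class `predictive_weight`: `age`, `scope`, `quantiles`
#'   (tibble `prob`, `weight_kg`) and `interval_probability` (or `NA`).
#' @examples
#' posterior_predictive_weight(calf_reference_params(), age = 60,
#'                             interval = c(60, 100))
#' @export
posterior_predictive_weight <- function(x, age,
                                        scope = c("median_cluster",
                                                  "population"),
                                        probs = c(0.025, 0.25, 0.5, 0.75,
                                                  0.975),
                                        interval = NULL) {
  scope <- match.arg(scope)
  d <- param_draws(x)
  mu <- d$alpha + d$beta_age * age + d$beta_age2 * age^2
  sigma2 <- d$var_residual
  if (scope == "population") {
    farm <- d$var_farm_int + 2 * age * d$cov_farm_int_slope +
      age^2 * d$var_farm_slope
    sigma2 <- sigma2 + d$var_practice + farm
  }
  sig <- sqrt(sigma2)
  mix_cdf <- function(w) mean(pnorm(w, mu, sig))
  qs <- vapply(probs, function(p) {
    if (all(sig == 0)) return(quantile(mu, p, names = FALSE))
    lo <- min(mu - 10 * max(sig, 1e-12)); hi <- max(mu + 10 * max(sig, 1e-12))
    uniroot(function(w) mix_cdf(w) - p, c(lo, hi), tol = 1e-8)$root
  }, numeric(1L))
  ip <- NA_real_
  if (!is.null(interval)) {
    stopifnot(length(interval) == 2L)
    if (interval[1] > interval[2])
      stop("interval must satisfy a <= b", call. = FALSE)
    ip <- if (all(sig == 0))
      mean(mu >= interval[1] & mu <= interval[2])
    else mean(pnorm(interval[2], mu, sig) - pnorm(interval[1], mu, sig))
  }
  structure(list(age = age, scope = scope,
                 quantiles = tibble::tibble(prob = probs, weight_kg = qs),
                 interval = interval, interval_probability = ip),
            class = "predictive_weight")
}

#' @export
print.predictive_weight <- function(x, ...) {
  cat("<predictive_weight> age ", x$age, " d, scope ", x$scope, "\n",
      sep = "")
  print(x$quantiles)
  if (!is.na(x$interval_probability))
    cat(sprintf("P(weight in [%g, %g] kg) = %.3f\n", x$interval[1],
                x$interval[2], x$interval_probability))
  invisible(x)
}
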
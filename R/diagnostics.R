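#' Effective sample size of a chain
#'
#' Estimates \eqn{N_{eff} = N / (1 + 2\sum_k \rho_k)} with the autocovariance
#' sum truncated by the initial-positive-sequence rule: successive pairs of
#' autocorrelations \eqn{\rho_{2t} + \rho_{2t+1}} are accumulated while their
#' sum stays positive. The result is capped at \eqn{N} (for chains with
#' negative autocorrelation the nominal value can exceed the draw count, which
#' is not meaningful as a run-length summary). A constant series has no
#' autocorrelation information and returns \eqn{N} with a warning.
#'
#' @param series Numeric vector of ordered draws of one scalar parameter
#'   (length at least 10).
#' @return A single positive number in `(0, N]`.
#' @examples
#' effective_sample_size(rnorm(1000))
#' @export
effective_sample_size <- function(series) {
  n <- length(series)
  stopifnot(n >= 10L)
  if (sd(series) == 0) {
    warning("constant series: effective sample size undefined, returning N")
    return(as.numeric(n))
  }
  rho <- as.numeric(acf(series, lag.max = n - 1L, plot = FALSE,
                        demean = TRUE)$acf)[-1L]
  # initial positive sequence: sum consecutive pairs while positive
  s <- 0
  t <- 1L
  while (t <= length(rho)) {
    pair <- rho[t] + if (t + 1L <= length(rho)) rho[t + 1L] else 0
    if (pair <= 0) break
    s <- s + pair
    t <- t + 2L
  }
  min(n / (1 + 2 * s), n)
}

#' Raftery-Lewis run-length diagnostic
#'
#' Implements the two-state Markov-chain method for judging how many MCMC
#' iterations are needed to estimate the `q`-quantile of a parameter to within
#' `+/- r` with probability `s`. The series is binarized at its empirical
#' `q`-quantile; the smallest thinning `k` is found at which the binary chain
#' is adequately first-order Markov (BIC comparison of first- versus
#' second-order models on consecutive triples); transition probabilities of
#' the thinned chain then give the required burn-in and post-burn-in length.
#' The independence-chain minimum is
#' \eqn{n_{min} = \lceil z_{(1+s)/2}^2 \, q(1-q) / r^2 \rceil}.
#'
#' @param series Numeric vector of ordered draws.
#' @param q Quantile of interest (default 0.025).
#' @param r Required accuracy on the cumulative probability scale
#'   (default 0.005).
#' @param s Probability of achieving accuracy `r` (default 0.95).
#' @param converge_eps Tolerance defining convergence of the binary chain for
#'   the burn-in calculation (default 0.001).
#' @return A list of class `raftery_lewis`: `n_min`, `burn_in_required`,
#'   `n_required` (burn-in plus post-burn-in iterations, on the original
#'   un-thinned scale), `thinning_k` and `dependence_factor`
#'   (`n_required / n_min`).
#' @examples
#' raftery_lewis(rnorm(5000))$n_min  # 3746 for the defaults
#' @export
raftery_lewis <- function(series, q = 0.025, r = 0.005, s = 0.95,
                          converge_eps = 0.001) {
  stopifnot(q > 0, q < 1, r > 0, r < min(q, 1 - q), s > 0, s < 1)
  z <- qnorm((1 + s) / 2)
  n_min <- ceiling(z^2 * q * (1 - q) / r^2)
  n <- length(series)
  if (n < n_min)
    stop("series too short for Raftery-Lewis: need at least ", n_min,
         " draws, got ", n, call. = FALSE)
  zt <- as.integer(series <= quantile(series, q))

  # smallest thinning at which a first-order Markov fit is adequate (BIC)
  k <- 1L
  repeat {
    sub <- zt[seq.int(1L, n, by = k)]
    m <- length(sub)
    if (m < 4L)
      stop("series too short to estimate transition structure at thinning ",
           k, call. = FALSE)
    tri <- table(factor(sub[1:(m - 2L)], levels = 0:1),
                 factor(sub[2:(m - 1L)], levels = 0:1),
                 factor(sub[3:m], levels = 0:1))
    g2 <- 0
    for (i in 1:2) for (j in 1:2) for (l in 1:2) {
      o <- tri[i, j, l]
      if (o > 0) {
        e <- sum(tri[i, j, ]) * sum(tri[, j, l]) / sum(tri[, j, ])
        g2 <- g2 + 2 * o * log(o / e)
      }
    }
    bic <- g2 - 2 * log(m - 2L)
    if (bic <= 0 || k > n / 4L) break
    k <- k + 1L
  }

  sub <- zt[seq.int(1L, n, by = k)]
  m <- length(sub)
  from <- sub[1:(m - 1L)]; to <- sub[2:m]
  alpha <- sum(from == 0L & to == 1L) / max(sum(from == 0L), 1L)  # 0 -> 1
  beta <- sum(from == 1L & to == 0L) / max(sum(from == 1L), 1L)   # 1 -> 0
  alpha <- min(max(alpha, 1e-6), 1 - 1e-6)
  beta <- min(max(beta, 1e-6), 1 - 1e-6)
  lambda <- 1 - alpha - beta
  burn <- if (abs(lambda) < 1e-12) k else
    k * ceiling(log(converge_eps * (alpha + beta) / max(alpha, beta)) /
                  log(abs(lambda)))
  post <- k * ceiling(alpha * beta * (2 - alpha - beta) /
                        (alpha + beta)^3 * (z / r)^2)
  # the independence-chain minimum is a hard lower bound; the plug-in
  # transition estimates can dip marginally below it by sampling noise
  n_required <- max(burn + post, n_min)
  structure(list(n_min = as.integer(n_min),
                 burn_in_required = as.integer(burn),
                 n_required = as.integer(n_required),
                 thinning_k = k,
                 dependence_factor = n_required / n_min),
            class = "raftery_lewis")
}

#' @export
print.raftery_lewis <- function(x, ...) {
  cat("<raftery_lewis> n_min=", x$n_min, " burn-in=", x$burn_in_required,
      " total required=", x$n_required, " thinning=", x$thinning_k,
      " dependence factor=", round(x$dependence_factor, 2), "\n", sep = "")
  invisible(x)
}

#' Deviance information criterion
#'
#' Conditional-on-random-effects DIC: the per-draw deviance is
#' \eqn{-2 \log N(y \mid \hat y_{draw}, \sigma_e^2)} (accumulated by the
#' sampler as it runs), `p_d` is the mean deviance minus the deviance at the
#' posterior means of all parameters (fixed effects, random effects, residual
#' variance), and `dic = mean_deviance + p_d`. Lower values indicate a more
#' parsimonious model.
#'
#' @param chain A `calf_chain` whose draws carry a `deviance` column and
#'   whose random-effect posterior means are available.
#' @param design The [build_design()] bundle the chain was fitted to.
#' @return A list of class `dic_result` with `dic`, `p_d`, `mean_deviance`
#'   and `deviance_at_means`.
#' @export
dic <- function(chain, design) {
  stopifnot(inherits(chain, "calf_chain"), inherits(design, "calf_design"))
  dev <- chain$draws$deviance
  if (is.null(dev) || any(!is.finite(dev))) {
    bad <- which(!is.finite(dev))
    stop("non-finite deviance",
         if (length(bad)) paste0(" at draw ", bad[1]), call. = FALSE)
  }
  mean_dev <- mean(dev)

  fixed_cols <- colnames(design$X)
  beta_hat <- purrr::map_dbl(fixed_cols, ~ mean(chain$draws[[.x]]))
  fit <- as.numeric(design$X %*% beta_hat)
  if (!is.null(chain$ranef)) {
    v_hat <- chain$ranef$practice$v
    U_hat <- cbind(chain$ranef$farm$u_int, chain$ranef$farm$u_slope)
    fit <- fit + v_hat[design$farm_practice[design$farm]] +
      U_hat[design$farm, 1L] + U_hat[design$farm, 2L] * design$age
  }
  var_e_hat <- mean(chain$draws$var_residual)
  sse <- sum((design$y - fit)^2)
  dev_at_means <- design$n * log(2 * pi * var_e_hat) + sse / var_e_hat
  p_d <- mean_dev - dev_at_means
  structure(list(dic = mean_dev + p_d, p_d = p_d,
                 mean_deviance = mean_dev,
                 deviance_at_means = dev_at_means),
            class = "dic_result")
}

#' @export
print.dic_result <- function(x, ...) {
  cat("<dic_result> DIC=", round(x$dic, 2), " pD=", round(x$p_d, 2),
      " mean deviance=", round(x$mean_deviance, 2), "\n", sep = "")
  invisible(x)
}

#' Chain-quality report for the variance parameters
#'
#' Applies [effective_sample_size()] and [raftery_lewis()] to the four
#' variance parameters of a fitted chain (practice intercept variance, farm
#' intercept variance, farm slope variance, residual variance), the
#' parameters for which run-length diagnostics matter most in this model.
#'
#' @param chain A `calf_chain`.
#' @inheritParams raftery_lewis
#' @return A tibble with one row per variance parameter: `term`, `ess`,
#'   `rl_n_min`, `rl_burn_in`, `rl_n_required`, `rl_thinning`,
#'   `rl_dependence_factor`.
#' @export
diagnose_chain <- function(chain, q = 0.025, r = 0.005, s = 0.95) {
  stopifnot(inherits(chain, "calf_chain"))
  terms <- intersect(variance_cols, names(chain$draws))
  purrr::map_dfr(terms, function(tm) {
    x <- chain$draws[[tm]]
    rl <- tryCatch(raftery_lewis(x, q = q, r = r, s = s),
                   error = function(e) {
                     message("raftery_lewis unavailable for ", tm, ": ",
                             conditionMessage(e))
                     list(n_min = NA_integer_, burn_in_required = NA_integer_,
                          n_required = NA_integer_, thinning_k = NA_integer_,
                          dependence_factor = NA_real_)
                   })
    tibble::tibble(term = tm,
                   ess = effective_sample_size(x),
                   rl_n_min = rl$n_min,
                   rl_burn_in = rl$burn_in_required,
                   rl_n_required = rl$n_required,
                   rl_thinning = rl$thinning_k,
                   rl_dependence_factor = rl$dependence_factor)
  })
}
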
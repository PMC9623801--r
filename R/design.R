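#' Build the three-level design from selected records
#'
#' Assembles the response vector, the fixed polynomial-age design, and the
#' nested cluster index maps (record to farm, farm to practice) required by
#' the Gibbs sampler. Ages enter in raw days, so the intercept is
#' interpretable as mean birth weight.
#'
#' @param records Selected weight records.
#' @param degree Degree of the polynomial in age: 2 (default, quadratic), 1,
#'   or 0 (intercept only, for sub-model comparisons).
#' @return A list of class `calf_design`: `y`, `X` (with columns `alpha`,
#'   `beta_age`, and for degree 2 `beta_age2`), `age`, `farm` (1-based record
#'   to farm index), `farm_practice` (1-based farm to practice index),
#'   `farm_ids`, `practice_ids`, `n`, `n_farm`, `n_practice`.
#' @export
build_design <- function(records, degree = 2L) {
  stopifnot(nrow(records) > 0, degree %in% c(0L, 1L, 2L))
  bad_calf <- records |>
    dplyr::distinct(.data$calf_id, .data$farm_id) |>
    dplyr::count(.data$calf_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(bad_calf) > 0L)
    stop("nesting violated: calf(s) ",
         paste(utils::head(bad_calf$calf_id, 5), collapse = ", "),
         " appear under more than one farm", call. = FALSE)
  bad_farm <- records |>
    dplyr::distinct(.data$farm_id, .data$practice_id) |>
    dplyr::count(.data$farm_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(bad_farm) > 0L)
    stop("nesting violated: farm(s) ",
         paste(utils::head(bad_farm$farm_id, 5), collapse = ", "),
         " appear under more than one practice", call. = FALSE)

  farm_ids <- sort(unique(records$farm_id))
  farm <- match(records$farm_id, farm_ids)
  fp <- records |> dplyr::distinct(.data$farm_id, .data$practice_id)
  practice_ids <- sort(unique(fp$practice_id))
  farm_practice <- match(fp$practice_id[match(farm_ids, fp$farm_id)],
                         practice_ids)
  age <- as.numeric(records$age_days)
  X <- switch(as.character(degree),
              "2" = cbind(alpha = 1, beta_age = age, beta_age2 = age^2),
              "1" = cbind(alpha = 1, beta_age = age),
              "0" = cbind(alpha = rep(1, length(age))))
  structure(list(y = records$weight_kg, X = X, age = age,
                 farm = farm, farm_practice = farm_practice,
                 farm_ids = farm_ids, practice_ids = practice_ids,
                 n = nrow(records), n_farm = length(farm_ids),
                 n_practice = length(practice_ids)),
            class = "calf_design")
}

#' Starting values for the Gibbs sampler
#'
#' Fixed effects come from ordinary least squares on the fixed design;
#' variance components from moment estimators: the practice variance is the
#' variance of per-practice mean residuals, the farm-level 2x2 covariance is
#' the covariance of per-farm regression coefficients of residuals on
#' (1, age), and the residual variance pools the within-farm regression
#' residuals. All variance estimates are floored at `1e-6` so the starting
#' state is valid even for degenerate data. The farm-level estimate is also
#' returned separately for constructing the Wishart prior scale.
#'
#' @param design A [build_design()] result.
#' @return A list: `state` (fields `beta`, `v`, `U`, `var_practice`,
#'   `cov_farm`, `var_residual`) and `S_u` (the farm-level moment estimate).
#' @export
init_state <- function(design) {
  stopifnot(inherits(design, "calf_design"))
  X <- design$X; y <- design$y
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("fixed design is singular; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, y)
  r <- as.numeric(y - X %*% beta)
  floor_var <- 1e-6

  prac_of_rec <- design$farm_practice[design$farm]
  pm <- tapply(r, prac_of_rec, mean)
  var_practice <- max(if (length(pm) > 1) var(as.numeric(pm)) else 0, floor_var)
  r2 <- r - as.numeric(pm)[match(prac_of_rec, as.integer(names(pm)))]

  # per-farm regression of residuals on (1, age) where identifiable
  coefs <- matrix(NA_real_, design$n_farm, 2L)
  sse <- 0; sse_n <- 0L
  for (j in seq_len(design$n_farm)) {
    idx <- which(design$farm == j)
    a <- design$age[idx]
    if (length(idx) >= 3L && sd(a) > 0) {
      fit <- stats::lm.fit(cbind(1, a), r2[idx])
      coefs[j, ] <- fit$coefficients
      sse <- sse + sum(fit$residuals^2)
      sse_n <- sse_n + length(idx) - 2L
    }
  }
  ok <- stats::complete.cases(coefs)
  S_u <- if (sum(ok) >= 3L) stats::cov(coefs[ok, , drop = FALSE])
         else diag(c(1, 1e-3))
  ev <- eigen(S_u, symmetric = TRUE)
  S_u <- ev$vectors %*% (pmax(ev$values, floor_var) * t(ev$vectors))
  var_residual <- max(if (sse_n > 0L) sse / sse_n else var(r2), floor_var)

  state <- list(beta = beta,
                v = rep(0, design$n_practice),
                U = matrix(0, design$n_farm, 2L),
                var_practice = var_practice,
                cov_farm = S_u,
                var_residual = var_residual)
  list(state = state, S_u = S_u)
}

#' Prior specification for the Gibbs sampler
#'
#' Default noninformative priors: Gamma(0.001, 0.001) on the practice-level
#' and residual precisions, and a Wishart with 2 degrees of freedom on the
#' farm-level 2x2 precision matrix. The Wishart scale is built from an initial
#' moment estimate \eqn{\hat S_u} of the farm covariance as
#' \eqn{(2 \hat S_u)^{-1}}, so that the prior expectation of the precision
#' matrix equals \eqn{\hat S_u^{-1}} (the usual default-prior convention for
#' multilevel software). Pass `wishart_scale_inverse` to fix the scale
#' directly instead.
#'
#' @param gamma_shape_practice,gamma_rate_practice Gamma prior on the
#'   practice-level precision.
#' @param gamma_shape_residual,gamma_rate_residual Gamma prior on the
#'   residual precision.
#' @param wishart_df Wishart degrees of freedom (must be at least 2).
#' @param wishart_scale_inverse Optional fixed 2x2 matrix \eqn{R_0} with the
#'   farm precision prior Wishart(df, \eqn{R_0^{-1}}); when `NULL` (default)
#'   \eqn{R_0 = 2 \hat S_u} is computed from the initializer.
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(gamma_shape_practice = 0.001,
                       gamma_rate_practice = 0.001,
                       gamma_shape_residual = 0.001,
                       gamma_rate_residual = 0.001,
                       wishart_df = 2,
                       wishart_scale_inverse = NULL) {
  stopifnot(gamma_shape_practice > 0, gamma_rate_practice > 0,
            gamma_shape_residual > 0, gamma_rate_residual > 0,
            wishart_df >= 2)
  structure(list(gamma_shape_practice = gamma_shape_practice,
                 gamma_rate_practice = gamma_rate_practice,
                 gamma_shape_residual = gamma_shape_residual,
                 gamma_rate_residual = gamma_rate_residual,
                 wishart_df = wishart_df,
                 wishart_scale_inverse = wishart_scale_inverse),
            class = "prior_spec")
}

#' MCMC schedule
#'
#' Two built-in profiles: `"paper"` replicates the production schedule
#' (100,000 burn-in sweeps, 1,000,000 post-burn-in sweeps, keep every 100th,
#' yielding 10,000 stored draws) and `"desk"` is a reduced schedule for
#' interactive or test use (5,000 / 50,000 / 10, also 5,000 stored draws).
#'
#' @param profile `"desk"` or `"paper"`; ignored when all three schedule
#'   numbers are supplied.
#' @param burn_in Discarded initial sweeps.
#' @param total_iterations Post-burn-in sweeps; must be divisible by `thin`.
#' @param thin Keep every `thin`-th post-burn-in state.
#' @param seed Integer seed for the run.
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(profile = c("desk", "paper"),
                          burn_in = NULL, total_iterations = NULL,
                          thin = NULL, seed = 1L) {
  profile <- match.arg(profile)
  def <- switch(profile,
                desk = list(burn_in = 5000L, total_iterations = 50000L,
                            thin = 10L),
                paper = list(burn_in = 100000L, total_iterations = 1000000L,
                             thin = 100L))
  s <- list(burn_in = as.integer(burn_in %||% def$burn_in),
            total_iterations = as.integer(total_iterations %||%
                                          def$total_iterations),
            thin = as.integer(thin %||% def$thin),
            seed = as.integer(seed), profile = profile)
  stopifnot(s$thin >= 1L, s$burn_in >= 0L,
            s$total_iterations %% s$thin == 0L)
  structure(s, class = "mcmc_settings")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
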
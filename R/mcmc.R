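#' Fit the three-level model by Gibbs sampling
#'
#' Runs a blocked Gibbs sampler with exact conjugate conditional draws for the
#' random-slope model
#' \deqn{y_{ijk} = \alpha + \beta_1 a + \beta_2 a^2 + v_k + u_{0jk} +
#'   u_{1jk} a + e_{ijk},}
#' with \eqn{v_k \sim N(0, \sigma_v^2)}, \eqn{(u_{0jk}, u_{1jk}) \sim
#' N_2(0, \Omega_u)} and \eqn{e_{ijk} \sim N(0, \sigma_e^2)}. One sweep
#' updates, in order: the fixed effects from their joint conditional normal;
#' each practice intercept; each farm (intercept, slope) pair from its
#' conditional bivariate normal; the practice precision from its Gamma
#' conditional; the residual precision from its Gamma conditional; and the
#' farm precision matrix from its Wishart conditional with degrees of freedom
#' prior df + number of farms. Starting values come from [init_state()]; the
#' burn-in makes results insensitive to them.
#'
#' @param design A [build_design()] bundle.
#' @param priors A [prior_spec()]. When its Wishart scale is unset, it is
#'   built from the initializer's farm-covariance estimate (see
#'   [prior_spec()]).
#' @param settings An [mcmc_settings()] schedule; the seed it carries governs
#'   all randomness, so identical settings reproduce identical chains.
#' @param include_practice,include_farm Switch off a random-effect level (the
#'   corresponding effects are held at zero and their variances are not
#'   updated); used for model comparison and for conjugate sub-model checks.
#' @param store_ranef Keep all per-draw random effects (memory permitting);
#'   otherwise only their posterior means are retained.
#' @return A `calf_chain`: `draws` is a tibble with one row per stored draw
#'   (columns `alpha`, `beta_age`, `beta_age2`, `var_practice`,
#'   `var_farm_int`, `cov_farm_int_slope`, `var_farm_slope`, `var_residual`,
#'   `deviance`), plus random-effect summaries, the settings and priors used,
#'   and cluster bookkeeping.
#' @examples
#' sim <- simulate_population(sim_config(n_practices = 3,
#'   farms_per_practice = list(mean = 3, dispersion = 0),
#'   calves_per_farm = list(mean = 20, dispersion = 0), seed = 7))
#' des <- build_design(append_birth_records(sim$records, sim$birth_weights))
#' chain <- run_mcmc(des, settings = mcmc_settings(
#'   burn_in = 200, total_iterations = 1000, thin = 5, seed = 1))
#' tidy(chain)
#' @export
run_mcmc <- function(design, priors = prior_spec(),
                     settings = mcmc_settings(),
                     include_practice = TRUE, include_farm = TRUE,
                     store_ranef = FALSE) {
  stopifnot(inherits(design, "calf_design"),
            inherits(priors, "prior_spec"),
            inherits(settings, "mcmc_settings"))
  set.seed(settings$seed)
  ini <- init_state(design)
  state <- ini$state
  R0 <- priors$wishart_scale_inverse %||% (2 * ini$S_u)

  res <- .gibbs_kernel(
    y = design$y, X = design$X, age = design$age,
    farm = design$farm - 1L, farm_prac = design$farm_practice - 1L,
    n_prac = design$n_practice,
    a_v = priors$gamma_shape_practice, b_v = priors$gamma_rate_practice,
    a_e = priors$gamma_shape_residual, b_e = priors$gamma_rate_residual,
    w_df = priors$wishart_df, w_R0 = R0,
    beta = state$beta, v = state$v, U = state$U,
    var_v = state$var_practice, Omega = state$cov_farm,
    var_e = state$var_residual,
    burn_in = settings$burn_in, n_iter = settings$total_iterations,
    thin = settings$thin,
    use_prac = include_practice, use_farm = include_farm,
    store_ranef = store_ranef)

  draws <- tibble::as_tibble(as.data.frame(res$draws))
  names(draws) <- c(colnames(design$X),
                    "var_practice", "var_farm_int", "cov_farm_int_slope",
                    "var_farm_slope", "var_residual", "deviance")
  draws <- dplyr::mutate(draws, .draw = dplyr::row_number(),
                         .before = 1L)
  ranef <- list(
    practice = tibble::tibble(practice_id = design$practice_ids,
                              v = as.numeric(res$v_mean)),
    farm = tibble::tibble(farm_id = design$farm_ids,
                          practice_id =
                            design$practice_ids[design$farm_practice],
                          u_int = res$U_mean[, 1L],
                          u_slope = res$U_mean[, 2L]))
  if (store_ranef) {
    ranef$v_draws <- res$v_draws
    ranef$U_draws <- res$U_draws
  }
  new_calf_chain(draws, ranef = ranef, settings = settings,
                 priors = utils::modifyList(unclass(priors),
                                            list(wishart_scale_inverse = R0)),
                 info = list(n = design$n, n_farm = design$n_farm,
                             n_practice = design$n_practice,
                             include_practice = include_practice,
                             include_farm = include_farm,
                             S_u_init = ini$S_u))
}

new_calf_chain <- function(draws, ranef = NULL, settings = NULL,
                           priors = NULL, info = NULL) {
  structure(list(draws = draws, ranef = ranef, settings = settings,
                 priors = priors, info = info),
            class = "calf_chain")
}

#' One Gibbs sweep
#'
#' Advances a full parameter state by a single sweep of the conditional
#' updates used by [run_mcmc()]; mainly useful for testing the updates
#' against independent references.
#'
#' @param state A list with `beta`, `v`, `U`, `var_practice`, `cov_farm`,
#'   `var_residual` (as produced by [init_state()]).
#' @param design A [build_design()] bundle.
#' @param priors A [prior_spec()] whose Wishart scale is resolved: either its
#'   `wishart_scale_inverse` is set or `S_u` is supplied.
#' @param S_u Farm-covariance estimate used to build the Wishart scale when
#'   the prior does not fix one.
#' @return The updated state (same shape as `state`).
#' @export
gibbs_step <- function(state, design, priors = prior_spec(), S_u = NULL) {
  R0 <- priors$wishart_scale_inverse %||%
    (if (!is.null(S_u)) 2 * S_u else
       stop("supply S_u or a prior with a fixed Wishart scale", call. = FALSE))
  res <- .gibbs_kernel(
    y = design$y, X = design$X, age = design$age,
    farm = design$farm - 1L, farm_prac = design$farm_practice - 1L,
    n_prac = design$n_practice,
    a_v = priors$gamma_shape_practice, b_v = priors$gamma_rate_practice,
    a_e = priors$gamma_shape_residual, b_e = priors$gamma_rate_residual,
    w_df = priors$wishart_df, w_R0 = R0,
    beta = state$beta, v = state$v, U = state$U,
    var_v = state$var_practice, Omega = state$cov_farm,
    var_e = state$var_residual,
    burn_in = 0L, n_iter = 1L, thin = 1L,
    use_prac = TRUE, use_farm = TRUE, store_ranef = FALSE)
  res$final
}

#' @export
print.calf_chain <- function(x, ...) {
  cat("<calf_chain> ", nrow(x$draws), " stored draws",
      if (!is.null(x$settings))
        sprintf(" (burn-in %d, %d sweeps, thin %d, seed %d)",
                x$settings$burn_in, x$settings$total_iterations,
                x$settings$thin, x$settings$seed),
      "\n", sep = "")
  print(tidy(x), n = 10)
  invisible(x)
}

#' @rdname run_mcmc
#' @param x A `calf_chain`.
#' @param ... Unused.
#' @export
tidy.calf_chain <- function(x, ...) {
  x$draws |>
    dplyr::select(-".draw", -dplyr::any_of("deviance")) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "term") |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      estimate = mean(.data$value),
      median = median(.data$value),
      std.error = sd(.data$value),
      conf.low = quantile(.data$value, 0.025),
      conf.high = quantile(.data$value, 0.975),
      ess = effective_sample_size(.data$value),
      .groups = "drop") |>
    dplyr::arrange(match(.data$term, param_cols))
}

#' @rdname run_mcmc
#' @export
glance.calf_chain <- function(x, ...) {
  tibble::tibble(
    n_draws = nrow(x$draws),
    burn_in = x$settings$burn_in %||% NA_integer_,
    total_iterations = x$settings$total_iterations %||% NA_integer_,
    thin = x$settings$thin %||% NA_integer_,
    seed = x$settings$seed %||% NA_integer_,
    n_records = x$info$n %||% NA_integer_,
    n_farms = x$info$n_farm %||% NA_integer_,
    n_practices = x$info$n_practice %||% NA_integer_,
    min_ess = min(purrr::map_dbl(
      dplyr::select(x$draws, dplyr::any_of(param_cols)),
      effective_sample_size)))
}

#' @rdname run_mcmc
#' @param object A `calf_chain` (for `autoplot`).
#' @export
autoplot.calf_chain <- function(object, ...) {
  object$draws |>
    dplyr::select(".draw", dplyr::any_of(param_cols)) |>
    tidyr::pivot_longer(-".draw", names_to = "term") |>
    ggplot2::ggplot(ggplot2::aes(.data$.draw, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "steelblue4") +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "stored draw", y = NULL) +
    ggplot2::theme_minimal()
}

#' Write or read a stored chain
#'
#' The chain travels as a delimited table with one row per stored draw and
#' fixed header names (`alpha`, `beta_age`, `beta_age2`, `var_practice`,
#' `var_farm_int`, `cov_farm_int_slope`, `var_farm_slope`, `var_residual`,
#' plus `deviance`).
#'
#' @param chain A `calf_chain`.
#' @param path File path.
#' @export
write_chain <- function(chain, path) {
  readr::write_csv(dplyr::select(chain$draws, -".draw"), path)
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  draws <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_double()))
  draws <- dplyr::mutate(draws, .draw = dplyr::row_number(), .before = 1L)
  new_calf_chain(draws)
}
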
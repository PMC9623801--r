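#' Configuration for the synthetic weight-recording generator
#'
#' Describes a synthetic population of dairy calves nested in farms nested in
#' veterinary practices, weighed irregularly from birth to 20 weeks, together
#' with the data-entry defects that a selection pipeline must remove. The
#' defaults emulate the structure of a national UK calf weight-recording
#' database: 28 practices, about 5 farms per practice, enough calves per farm
#' to reach roughly 20,000 calves, a median of 3 weighings per calf with fewer
#' weighings at older ages, and generating parameters equal to
#' [calf_reference_params()].
#'
#' Count distributions are negative binomial, shifted so that every practice
#' has at least one farm and every farm at least two calves; setting
#' `dispersion = 0` makes the count deterministic (exactly `mean`). The
#' per-calf weighing count is `1 + NegBin(mean - 1, dispersion)`, calibrated at
#' the defaults to a median of 3 weighings.
#'
#' @param n_practices Number of veterinary practices.
#' @param farms_per_practice,calves_per_farm,weighings_per_calf Lists with
#'   elements `mean` and `dispersion` (negative-binomial size; `0` = fixed).
#' @param age_range_days Integer interval for follow-up weighing ages (days).
#' @param fixed_effects Named vector `alpha` (kg), `beta_age` (kg/day),
#'   `beta_age2` (kg/day^2): the quadratic population mean growth curve.
#' @param var_practice Practice-level intercept variance (kg^2).
#' @param cov_farm 2x2 symmetric positive semi-definite covariance matrix of
#'   the farm-level (intercept, age-slope) random effects.
#' @param var_calf_residual Calf-level residual variance (kg^2).
#' @param birth_weight_rate Proportion of calves with a confirmed birth weight.
#' @param attrition,attrition_rate If `attrition` is `TRUE`, weighing ages are
#'   sampled with linearly decreasing probability across the age window; at the
#'   upper end the sampling weight is reduced by `attrition_rate` (0 = none,
#'   1 = no weighings at the maximum age).
#' @param corruption List of defect rates in `[0, 1]`: `age` (recording age
#'   replaced by an implausible value outside the 1--138 day window),
#'   `estimate` (weight flagged as an estimate), `weight` (weight replaced by a
#'   value outside the (30, 225] kg range), `short_window` (per-farm
#'   probability that all of a farm's recordings are compressed into a span of
#'   at most one year).
#' @param start_date First possible farm enrolment date.
#' @param farm_window_days Span (days) over which a farm's calves are born;
#'   non-degenerate farms are constructed to exceed one year of recording
#'   activity so that only `short_window` farms fail the activity filter.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_population()]
#' @export
sim_config <- function(n_practices = 28,
                       farms_per_practice = list(mean = 5, dispersion = 2),
                       calves_per_farm = list(mean = 142, dispersion = 1.5),
                       weighings_per_calf = list(mean = 3, dispersion = 3),
                       age_range_days = c(1L, 138L),
                       fixed_effects = c(alpha = 41.26, beta_age = 0.59,
                                         beta_age2 = 0.001),
                       var_practice = 13.04,
                       cov_farm = matrix(c(2.37, 0.007, 0.007, 0.019), 2),
                       var_calf_residual = 82.65,
                       birth_weight_rate = 0.75,
                       attrition = TRUE,
                       attrition_rate = 0.5,
                       corruption = list(age = 0, estimate = 0, weight = 0,
                                         short_window = 0),
                       start_date = as.Date("2014-06-05"),
                       farm_window_days = 540,
                       seed = NULL) {
  stopifnot(n_practices >= 1, length(age_range_days) == 2,
            age_range_days[1] >= 1, age_range_days[1] <= age_range_days[2])
  if (var_practice < 0 || var_calf_residual < 0)
    stop("variance components must be non-negative", call. = FALSE)
  if (!isTRUE(all.equal(cov_farm, t(cov_farm), tolerance = 1e-10)))
    stop("cov_farm must be symmetric", call. = FALSE)
  ev <- eigen(cov_farm, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8))
    stop("cov_farm is not positive semi-definite (eigenvalues ",
         paste(signif(ev, 4), collapse = ", "), ")", call. = FALSE)
  corruption <- utils::modifyList(
    list(age = 0, estimate = 0, weight = 0, short_window = 0), corruption)
  rates <- unlist(corruption)
  if (any(rates < 0 | rates > 1))
    stop("corruption rates must lie in [0, 1]", call. = FALSE)
  if (sum(rates[c("age", "estimate", "weight")]) > 1)
    stop("record-level corruption rates must sum to at most 1", call. = FALSE)
  fe <- fixed_effects
  names(fe) <- c("alpha", "beta_age", "beta_age2")
  structure(
    list(n_practices = as.integer(n_practices),
         farms_per_practice = farms_per_practice,
         calves_per_farm = calves_per_farm,
         weighings_per_calf = weighings_per_calf,
         age_range_days = as.integer(age_range_days),
         fixed_effects = fe,
         var_practice = var_practice,
         cov_farm = cov_farm,
         var_calf_residual = var_calf_residual,
         birth_weight_rate = birth_weight_rate,
         attrition = isTRUE(attrition),
         attrition_rate = attrition_rate,
         corruption = corruption,
         start_date = as.Date(start_date),
         farm_window_days = farm_window_days,
         seed = seed),
    class = "sim_config")
}

# shifted negative-binomial count draw; dispersion 0 means deterministic
draw_count <- function(n, spec, min_count) {
  mu <- spec$mean - min_count
  if (spec$dispersion == 0 || mu <= 0)
    return(rep(max(min_count, round(spec$mean)), n))
  min_count + rnbinom(n, size = spec$dispersion, mu = mu)
}

# symmetric square root, tolerant of semi-definite input
mat_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate a nested calf weight-recording population
#'
#' Draws a three-level population under the random-slope growth model: practice
#' intercepts \eqn{v_k \sim N(0, \sigma_v^2)}, farm intercept/slope pairs
#' \eqn{(u_{0jk}, u_{1jk}) \sim N_2(0, \Omega_u)}, and per-weighing weights
#' \deqn{w = \alpha + \beta_1 a + \beta_2 a^2 + v_k + u_{0jk} + u_{1jk} a + e,
#'   \quad e \sim N(0, \sigma_e^2),}
#' where \eqn{a} is calf age in days. Every calf receives a true day-0 weight;
#' the configured proportion of these is reported as a confirmed birth weight.
#' Data-entry defects (implausible ages, estimate flags, out-of-range weights,
#' farms with under a year of recording activity) are injected after clean
#' generation, on disjoint record sets, and tallied so that downstream
#' selection stages can be checked against known ground truth.
#'
#' Farms not flagged as short-window are constructed so their recording span
#' always exceeds 365 days, and the calves anchoring a farm's first and last
#' recording dates are exempt from record-level corruption; each injected
#' defect is therefore removed by exactly one selection rule.
#'
#' @param config A [sim_config()].
#' @return A list of class `calf_sim` with elements
#'   \describe{
#'     \item{records}{Tibble of follow-up weighings, one row per weighing:
#'       `practice_id`, `farm_id`, `calf_id`, `birth_date`, `recording_date`,
#'       `age_days`, `weight_kg`, `is_estimate`, `is_birth_weight`.}
#'     \item{birth_weights}{Tibble of confirmed birth weights: `calf_id`,
#'       `weight_kg`.}
#'     \item{truth}{Generating parameters, realized random effects
#'       (`practice_effects`, `farm_effects`), all day-0 weights
#'       (`birth_weights_all`), per-record defect labels (`defect`), and
#'       per-rule corruption tallies (`tallies`).}
#'   }
#' @examples
#' sim <- simulate_population(sim_config(n_practices = 2,
#'   farms_per_practice = list(mean = 3, dispersion = 0),
#'   calves_per_farm = list(mean = 10, dispersion = 0), seed = 1))
#' dplyr::count(sim$records, practice_id)
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  fe <- config$fixed_effects
  amin <- config$age_range_days[1]; amax <- config$age_range_days[2]

  K <- config$n_practices
  farms_per <- draw_count(K, config$farms_per_practice, 1L)
  J <- sum(farms_per)
  farm_prac <- rep.int(seq_len(K), farms_per)

  v <- rnorm(K, 0, sqrt(config$var_practice))
  U <- matrix(rnorm(2L * J), J, 2L) %*% mat_sqrt(config$cov_farm)

  calves_per <- draw_count(J, config$calves_per_farm, 2L)
  short_farm <- runif(J) < config$corruption$short_window
  farm_start <- config$start_date + sample.int(1500L, J, replace = TRUE) - 1L

  practice_id <- sprintf("P%02d", seq_len(K))
  farm_id <- sprintf("F%04d", seq_len(J))

  # per-calf birth offsets within the farm window; non-short farms pin the
  # first and last calf to the window ends so recording span > 365 d is
  # guaranteed by construction
  win <- config$farm_window_days
  birth_offset <- unlist(lapply(seq_len(J), function(j) {
    n <- calves_per[j]
    if (short_farm[j]) round(runif(n, 0, 200))
    else if (n >= 2) c(0, win, round(runif(n - 2L, 0, win)))
    else round(runif(n, 0, win))
  }))
  calf_farm <- rep.int(seq_len(J), calves_per)
  n_calf <- length(calf_farm)
  calf_id <- sprintf("C%06d", seq_len(n_calf))
  calf_birth <- farm_start[calf_farm] + birth_offset
  # calves anchoring each non-short farm's recording window
  anchor <- unlist(lapply(seq_len(J), function(j) {
    n <- calves_per[j]
    if (short_farm[j] || n < 2) rep(FALSE, n) else c(TRUE, TRUE, rep(FALSE, n - 2L))
  }))

  # weighing schedule: shifted negative-binomial count, ages sampled without
  # replacement with optional linear attrition toward older ages
  m <- pmin(draw_count(n_calf, config$weighings_per_calf, 1L), amax - amin + 1L)
  grid <- seq.int(amin, amax)
  wts <- if (config$attrition)
    1 - config$attrition_rate * (grid - amin) / max(amax - amin, 1L) else
    rep(1, length(grid))
  ages <- lapply(m, function(mi)
    sort(sample(grid, mi, replace = FALSE, prob = wts)))

  rec_calf <- rep.int(seq_len(n_calf), m)
  age_days <- unlist(ages)
  rec_farm <- calf_farm[rec_calf]
  mu <- fe[["alpha"]] + fe[["beta_age"]] * age_days +
    fe[["beta_age2"]] * age_days^2 +
    v[farm_prac[rec_farm]] + U[rec_farm, 1L] + U[rec_farm, 2L] * age_days
  weight <- mu + rnorm(length(age_days), 0, sqrt(config$var_calf_residual))

  records <- tibble::tibble(
    practice_id = practice_id[farm_prac[rec_farm]],
    farm_id = farm_id[rec_farm],
    calf_id = calf_id[rec_calf],
    birth_date = calf_birth[rec_calf],
    recording_date = calf_birth[rec_calf] + age_days,
    age_days = as.integer(age_days),
    weight_kg = weight,
    is_estimate = FALSE,
    is_birth_weight = FALSE)

  # record-level corruption on disjoint sets, never on short-window farms or
  # window-anchoring calves
  n_rec <- nrow(records)
  defect <- rep("none", n_rec)
  defect[short_farm[rec_farm]] <- "short_window"
  eligible <- defect == "none" & !anchor[rec_calf]
  cr <- config$corruption
  u <- runif(n_rec)
  idx_age <- eligible & u < cr$age
  idx_est <- eligible & u >= cr$age & u < cr$age + cr$estimate
  idx_wt  <- eligible & u >= cr$age + cr$estimate &
    u < cr$age + cr$estimate + cr$weight
  if (any(idx_age)) {
    bad_ages <- sample(c(-30:-1, (amax + 1L):500L), sum(idx_age), replace = TRUE)
    records$age_days[idx_age] <- as.integer(bad_ages)
    records$recording_date[idx_age] <- records$birth_date[idx_age] + bad_ages
    defect[idx_age] <- "age"
  }
  if (any(idx_est)) {
    records$is_estimate[idx_est] <- TRUE
    defect[idx_est] <- "estimate"
  }
  if (any(idx_wt)) {
    nlow <- rbinom(1L, sum(idx_wt), 0.5)
    bad_w <- sample(c(runif(nlow, 5, 30), runif(sum(idx_wt) - nlow, 225.1, 350)))
    records$weight_kg[idx_wt] <- bad_w
    defect[idx_wt] <- "weight"
  }

  # day-0 weights for every calf; a configured fraction is "confirmed"
  bw_all <- fe[["alpha"]] + v[farm_prac[calf_farm]] + U[calf_farm, 1L] +
    rnorm(n_calf, 0, sqrt(config$var_calf_residual))
  confirmed <- runif(n_calf) < config$birth_weight_rate
  birth_weights <- tibble::tibble(calf_id = calf_id[confirmed],
                                  weight_kg = bw_all[confirmed])

  truth <- list(
    fixed_effects = fe,
    var_practice = config$var_practice,
    cov_farm = config$cov_farm,
    var_residual = config$var_calf_residual,
    practice_effects = tibble::tibble(practice_id = practice_id, v = v),
    farm_effects = tibble::tibble(farm_id = farm_id,
                                  practice_id = practice_id[farm_prac],
                                  u_int = U[, 1L], u_slope = U[, 2L],
                                  short_window = short_farm),
    birth_weights_all = tibble::tibble(calf_id = calf_id,
                                       weight_kg = bw_all,
                                       confirmed = confirmed),
    defect = defect,
    tallies = list(
      age = sum(defect == "age"),
      estimate = sum(defect == "estimate"),
      weight = sum(defect == "weight"),
      short_window_farms = sum(short_farm),
      short_window_records = sum(defect == "short_window"),
      natural_out_of_range = sum(defect == "none" &
        (records$weight_kg <= 30 | records$weight_kg > 225))),
    config = config)

  structure(list(records = records, birth_weights = birth_weights,
                 truth = truth),
            class = "calf_sim")
}

#' @export
print.calf_sim <- function(x, ...) {
  t <- x$truth$tallies
  cat("<calf_sim> ", nrow(x$records), " weighings | ",
      dplyr::n_distinct(x$records$calf_id), " calves | ",
      dplyr::n_distinct(x$records$farm_id), " farms | ",
      dplyr::n_distinct(x$records$practice_id), " practices\n", sep = "")
  cat("  confirmed birth weights: ", nrow(x$birth_weights), "\n", sep = "")
  cat("  injected defects: age=", t$age, " estimate=", t$estimate,
      " weight=", t$weight, " short-window farms=", t$short_window_farms,
      "\n", sep = "")
  invisible(x)
}
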
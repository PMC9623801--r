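#' Published posterior means for the UK calf-weight model
#'
#' Posterior-mean parameter estimates from a national analysis of UK
#' Holstein-Friesian heifer-calf weight recordings (28 veterinary practices,
#' 139 farms, 19,708 calves, 59,588 weighings, ages 0--138 days): a quadratic
#' fixed-effect growth curve with a random intercept at the veterinary-practice
#' level, a correlated random intercept and age slope at the farm level, and a
#' calf-level residual. These values serve two purposes: they are the default
#' generating values of [sim_config()], and they can be piped straight into the
#' derived-quantity functions ([vpc_profile()], [growth_rate()],
#' [cluster_mean_coverage()]) to reproduce published plug-in summaries.
#'
#' @return A one-row tibble with columns `alpha` (intercept, kg; interpretable
#'   as mean birth weight), `beta_age` (kg/day), `beta_age2` (kg/day^2),
#'   `var_practice` (kg^2), `var_farm_int` (kg^2), `cov_farm_int_slope`
#'   (kg^2/day), `var_farm_slope` (kg^2/day^2) and `var_residual` (kg^2).
#' @examples
#' calf_reference_params()
#' calf_reference_params() |> growth_rate(ages = c(1, 138))
#' @export
calf_reference_params <- function() {
  tibble::tibble(
    alpha              = 41.26,
    beta_age           = 0.59,
    beta_age2          = 0.001,
    var_practice       = 13.04,
    var_farm_int       = 2.37,
    cov_farm_int_slope = 0.007,
    var_farm_slope     = 0.019,
    var_residual       = 82.65
  )
}

# canonical order of scalar parameter columns in chains / draw tables
param_cols <- c(
  "alpha", "beta_age", "beta_age2", "var_practice",
  "var_farm_int", "cov_farm_int_slope", "var_farm_slope", "var_residual"
)

variance_cols <- c("var_practice", "var_farm_int", "var_farm_slope", "var_residual")
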
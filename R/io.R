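#' Read and write weight-recording tables
#'
#' Records travel as plain delimited text with a fixed header:
#' `practice_id, farm_id, calf_id, birth_date, recording_date, age_days,
#' weight_kg, is_estimate, is_birth_weight`, ISO-8601 dates, decimal points,
#' one row per weighing.
#'
#' @param records A tibble of weight records.
#' @param path File path.
#' @return `read_records()` returns a tibble; the writers return `path`
#'   invisibly.
#' @export
write_records <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    practice_id = readr::col_character(),
    farm_id = readr::col_character(),
    calf_id = readr::col_character(),
    birth_date = readr::col_date(),
    recording_date = readr::col_date(),
    age_days = readr::col_integer(),
    weight_kg = readr::col_double(),
    is_estimate = readr::col_logical(),
    is_birth_weight = readr::col_logical()))
}

#' @rdname write_records
#' @param birth_weights Tibble with columns `calf_id`, `weight_kg`.
#' @export
write_birth_weights <- function(birth_weights, path) {
  readr::write_csv(birth_weights, path)
  invisible(path)
}

#' @rdname write_records
#' @export
read_birth_weights <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    calf_id = readr::col_character(),
    weight_kg = readr::col_double()))
}

#' Write generator ground truth as YAML
#'
#' Serializes the generating parameters, realized random effects and
#' corruption tallies of a [simulate_population()] run to a structured
#' key-value text document, so tests and pipeline logs can consume ground
#' truth without R serialization.
#'
#' @param truth The `truth` element of a `calf_sim`.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  out <- list(
    fixed_effects = as.list(truth$fixed_effects),
    var_practice = truth$var_practice,
    cov_farm = list(var_int = truth$cov_farm[1, 1],
                    cov_int_slope = truth$cov_farm[1, 2],
                    var_slope = truth$cov_farm[2, 2]),
    var_residual = truth$var_residual,
    tallies = truth$tallies,
    practice_effects = as.list(truth$practice_effects),
    farm_effects = as.list(truth$farm_effects))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- yaml::read_yaml(path)
  x$practice_effects <- tibble::as_tibble(x$practice_effects)
  x$farm_effects <- tibble::as_tibble(x$farm_effects)
  x$cov_farm <- matrix(c(x$cov_farm$var_int, x$cov_farm$cov_int_slope,
                         x$cov_farm$cov_int_slope, x$cov_farm$var_slope), 2)
  x
}
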
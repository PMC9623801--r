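#' Record-selection filters for calf weight recordings
#'
#' The selection cascade mirrors the staged inclusion criteria used when
#' cleaning national calf weight-recording data: implausible recording ages
#' are removed, farms without a sustained recording history are dropped,
#' weights flagged as visual estimates are discarded, confirmed birth weights
#' are injected as day-0 recordings, and finally all weights are restricted to
#' a plausible range. Each filter is an ordinary data-frame verb so stages can
#' be tested, re-ordered or switched off individually; [run_selection()]
#' applies the full cascade and returns a per-stage inclusion report.
#'
#' @param records A tibble of weight records (see [read_records()] for the
#'   column contract).
#' @param min_age,max_age Inclusive age window in days (defaults 1 and 138).
#' @return The filtered records tibble.
#' @name selection-filters
NULL

#' @rdname selection-filters
#' @details `apply_age_window()` keeps records with
#'   `min_age <= age_days <= max_age`; records with missing age are dropped.
#' @export
apply_age_window <- function(records, min_age = 1L, max_age = 138L) {
  stopifnot(min_age <= max_age)
  dplyr::filter(records, !is.na(.data$age_days),
                .data$age_days >= min_age, .data$age_days <= max_age)
}

#' @rdname selection-filters
#' @param min_span_days Farms whose recording span (last minus first
#'   `recording_date`) is less than or equal to this many days are dropped
#'   entirely; the default 365 implements "more than 12 months of apparent
#'   monitoring activity".
#' @export
apply_farm_activity <- function(records, min_span_days = 365L) {
  records |>
    dplyr::group_by(.data$farm_id) |>
    dplyr::filter(as.numeric(max(.data$recording_date) -
                             min(.data$recording_date)) > min_span_days) |>
    dplyr::ungroup()
}

#' @rdname selection-filters
#' @export
remove_estimates <- function(records) {
  dplyr::filter(records, !.data$is_estimate)
}

#' @rdname selection-filters
#' @param birth_weights Tibble of confirmed birth weights (`calf_id`,
#'   `weight_kg`). For each calf already present in `records`, one day-0
#'   record is appended with `recording_date` equal to the birth date; calves
#'   absent from `records` gain no record. Duplicate birth weights for a calf
#'   keep the first entry (a message reports how many were dropped).
#' @export
append_birth_records <- function(records, birth_weights) {
  if (is.null(birth_weights) || nrow(birth_weights) == 0L) return(records)
  dup <- duplicated(birth_weights$calf_id)
  if (any(dup)) {
    message(sum(dup), " duplicate birth weight(s) ignored (first entry kept)")
    birth_weights <- birth_weights[!dup, ]
  }
  # calves that already carry an injected day-0 record gain no second one
  has_birth <- unique(records$calf_id[records$is_birth_weight])
  birth_weights <- dplyr::filter(birth_weights,
                                 !.data$calf_id %in% has_birth)
  calf_info <- records |>
    dplyr::filter(!.data$is_birth_weight) |>
    dplyr::distinct(.data$practice_id, .data$farm_id, .data$calf_id,
                    .data$birth_date)
  new_rows <- birth_weights |>
    dplyr::inner_join(calf_info, by = "calf_id") |>
    dplyr::transmute(.data$practice_id, .data$farm_id, .data$calf_id,
                     .data$birth_date, recording_date = .data$birth_date,
                     age_days = 0L, weight_kg = .data$weight_kg,
                     is_estimate = FALSE, is_birth_weight = TRUE)
  dplyr::bind_rows(records, new_rows)
}

#' @rdname selection-filters
#' @param lower_exclusive,upper_inclusive Weight bounds in kg; records are
#'   kept when `lower_exclusive < weight_kg <= upper_inclusive` (defaults 30
#'   and 225).
#' @export
apply_weight_bounds <- function(records, lower_exclusive = 30,
                                upper_inclusive = 225) {
  stopifnot(lower_exclusive < upper_inclusive)
  dplyr::filter(records, .data$weight_kg > lower_exclusive,
                .data$weight_kg <= upper_inclusive)
}

stage_counts <- function(records, stage) {
  tibble::tibble(
    stage = stage,
    practices = dplyr::n_distinct(records$practice_id),
    farms = dplyr::n_distinct(records$farm_id),
    calves = dplyr::n_distinct(records$calf_id),
    recordings = nrow(records))
}

#' Run the full selection cascade with an inclusion report
#'
#' Applies, in order: the recording-age window, the farm recording-activity
#' filter, removal of estimated weights, injection of confirmed birth weights
#' as day-0 recordings, and the weight-range restriction (so injected birth
#' weights are themselves range-checked). After each stage the surviving
#' numbers of practices, farms, calves and recordings are tallied.
#'
#' @inheritParams selection-filters
#' @param birth_weights Confirmed birth weights (`calf_id`, `weight_kg`), or
#'   `NULL` to skip injection.
#' @param min_age,max_age,min_span_days,lower_exclusive,upper_inclusive Stage
#'   thresholds, as in the individual filters.
#' @param drop_estimates Set `FALSE` to keep estimated weights (sensitivity
#'   analyses).
#' @return A list of class `calf_selection`: `records` (the selected table)
#'   and `report` (one row per stage with columns `stage`, `practices`,
#'   `farms`, `calves`, `recordings`).
#' @examples
#' sim <- simulate_population(sim_config(n_practices = 2,
#'   farms_per_practice = list(mean = 2, dispersion = 0),
#'   calves_per_farm = list(mean = 8, dispersion = 0), seed = 42))
#' sel <- run_selection(sim$records, sim$birth_weights)
#' sel$report
#' @export
run_selection <- function(records, birth_weights = NULL,
                          min_age = 1L, max_age = 138L,
                          min_span_days = 365L,
                          lower_exclusive = 30, upper_inclusive = 225,
                          drop_estimates = TRUE) {
  report <- stage_counts(records, "initial")
  # the age window filters weighing ages; previously injected day-0 birth
  # records are definitionally valid, which makes the cascade idempotent
  births <- dplyr::filter(records, .data$is_birth_weight)
  records <- dplyr::bind_rows(
    apply_age_window(dplyr::filter(records, !.data$is_birth_weight),
                     min_age, max_age),
    births)
  report <- dplyr::bind_rows(report, stage_counts(records,
    sprintf("age %d-%d d", min_age, max_age)))
  records <- apply_farm_activity(records, min_span_days)
  report <- dplyr::bind_rows(report, stage_counts(records,
    sprintf("farm activity > %d d", min_span_days)))
  if (drop_estimates) {
    records <- remove_estimates(records)
    report <- dplyr::bind_rows(report, stage_counts(records,
      "estimated weights removed"))
  }
  records <- append_birth_records(records, birth_weights)
  report <- dplyr::bind_rows(report, stage_counts(records,
    "birth weights as day-0 records"))
  records <- apply_weight_bounds(records, lower_exclusive, upper_inclusive)
  report <- dplyr::bind_rows(report, stage_counts(records,
    sprintf("weights >%g and <=%g kg", lower_exclusive, upper_inclusive)))
  structure(list(records = records, report = report),
            class = "calf_selection")
}

#' @export
print.calf_selection <- function(x, ...) {
  cat("<calf_selection>\n")
  print(x$report)
  invisible(x)
}
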
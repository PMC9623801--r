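#' End-to-end pipeline stages
#'
#' Thin file-in / file-out wrappers that chain the package's functions into
#' the reproducible sequence simulate -> fit -> summarize. Each stage logs
#' stage counts and timings via [message()] and writes plain-text outputs
#' (CSV tables, YAML metadata) into `out_dir`, so a complete analysis can be
#' reproduced from an empty directory with one seed:
#'
#' ```
#' pipeline_simulate(sim_config(seed = 1), out_dir = "run")
#' pipeline_fit("run", settings = mcmc_settings("desk", seed = 1))
#' pipeline_summarize("run")
#' ```
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return `pipeline_simulate()`: paths of `records.csv`,
#'   `birth_weights.csv` and `truth.yml` (invisibly, as a named list).
#' @name pipeline
#' @export
pipeline_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  sim <- simulate_population(config)
  paths <- list(records = file.path(out_dir, "records.csv"),
                birth_weights = file.path(out_dir, "birth_weights.csv"),
                truth = file.path(out_dir, "truth.yml"))
  write_records(sim$records, paths$records)
  write_birth_weights(sim$birth_weights, paths$birth_weights)
  write_truth(sim$truth, paths$truth)
  t <- sim$truth$tallies
  message(sprintf(
    "simulate: %d recordings | %d calves | %d farms | %d practices [%.1fs]",
    nrow(sim$records), dplyr::n_distinct(sim$records$calf_id),
    dplyr::n_distinct(sim$records$farm_id),
    dplyr::n_distinct(sim$records$practice_id),
    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  message(sprintf(
    "simulate: defects injected: age=%d estimate=%d weight=%d short-window farms=%d",
    t$age, t$estimate, t$weight, t$short_window_farms))
  invisible(paths)
}

#' @rdname pipeline
#' @param dir Directory holding `records.csv` and `birth_weights.csv` (as
#'   written by `pipeline_simulate()` or by hand); outputs are written next
#'   to them.
#' @param settings An [mcmc_settings()] schedule.
#' @param priors A [prior_spec()].
#' @param select Apply the [run_selection()] cascade before fitting
#'   (default `TRUE`).
#' @return `pipeline_fit()`: invisibly, a list with the fitted `chain`, the
#'   `selection` report, the `diagnostics` tibble and the `dic` result.
#'   Writes `chain.csv`, `selection_report.csv`, `diagnostics.csv` and
#'   `fit_meta.yml`.
#' @export
pipeline_fit <- function(dir, settings = mcmc_settings("desk"),
                         priors = prior_spec(), select = TRUE) {
  t0 <- Sys.time()
  records <- read_records(file.path(dir, "records.csv"))
  bw_path <- file.path(dir, "birth_weights.csv")
  birth_weights <- if (file.exists(bw_path)) read_birth_weights(bw_path)
                   else NULL
  if (select) {
    sel <- run_selection(records, birth_weights)
    records <- sel$records
    readr::write_csv(sel$report, file.path(dir, "selection_report.csv"))
    if (nrow(records) == 0L) {
      empty_stage <- sel$report$stage[which(sel$report$recordings == 0L)[1]]
      stop("no records left after selection (emptied at stage: ",
           empty_stage, ")", call. = FALSE)
    }
    message(sprintf("fit: selection kept %d of %d recordings",
                    nrow(records), sel$report$recordings[1]))
  } else {
    sel <- NULL
    records <- append_birth_records(records, birth_weights)
  }
  design <- build_design(records)
  chain <- run_mcmc(design, priors = priors, settings = settings)
  write_chain(chain, file.path(dir, "chain.csv"))
  diag_tbl <- diagnose_chain(chain)
  readr::write_csv(diag_tbl, file.path(dir, "diagnostics.csv"))
  dic_res <- dic(chain, design)
  yaml::write_yaml(list(
    seed = settings$seed, burn_in = settings$burn_in,
    total_iterations = settings$total_iterations, thin = settings$thin,
    priors = list(
      gamma_shape_practice = chain$priors$gamma_shape_practice,
      gamma_rate_practice = chain$priors$gamma_rate_practice,
      gamma_shape_residual = chain$priors$gamma_shape_residual,
      gamma_rate_residual = chain$priors$gamma_rate_residual,
      wishart_df = chain$priors$wishart_df,
      wishart_scale_inverse = as.list(as.data.frame(
        chain$priors$wishart_scale_inverse))),
    dic = dic_res$dic, p_d = dic_res$p_d,
    n_records = design$n, n_farms = design$n_farm,
    n_practices = design$n_practice),
    file.path(dir, "fit_meta.yml"), precision = 15)
  message(sprintf("fit: %d stored draws | DIC %.1f [%.1fs]",
                  nrow(chain$draws), dic_res$dic,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(chain = chain, selection = sel, diagnostics = diag_tbl,
                 dic = dic_res))
}

#' @rdname pipeline
#' @param ages Age grid (days) for the VPC profile.
#' @param horizon Horizon (days) for the cumulative growth rate.
#' @param quantiles Cluster quantiles for the coverage summaries.
#' @param plots Also write `vpc_profile.png` (default `FALSE`).
#' @return `pipeline_summarize()`: invisibly, a list with `vpc`, `growth`,
#'   `coverage`. Writes `vpc_profile.csv`, `growth_summary.csv`,
#'   `coverage.csv`.
#' @export
pipeline_summarize <- function(dir, ages = 0:130, horizon = 138,
                               quantiles = c(0.025, 0.975), plots = FALSE) {
  chain_path <- file.path(dir, "chain.csv")
  if (!file.exists(chain_path))
    stop("no stored chain at ", chain_path, "; run pipeline_fit() first",
         call. = FALSE)
  chain <- read_chain(chain_path)
  vpc <- vpc_profile(chain, ages = ages)
  growth <- dplyr::bind_rows(
    dplyr::mutate(growth_rate(chain, ages = c(1, horizon)),
                  quantity = "instantaneous_rate", .before = 1L),
    dplyr::mutate(
      dplyr::rename(cumulative_growth_rate(chain, horizon), age = "horizon"),
      quantity = "cumulative_rate", .before = 1L))
  coverage <- cluster_mean_coverage(chain, "birth_weight",
                                    quantiles = quantiles) |>
    dplyr::bind_rows(cluster_mean_coverage(chain, "cumulative_rate",
                                           quantiles = quantiles,
                                           horizon = horizon))
  readr::write_csv(vpc, file.path(dir, "vpc_profile.csv"))
  readr::write_csv(growth, file.path(dir, "growth_summary.csv"))
  readr::write_csv(coverage, file.path(dir, "coverage.csv"))
  if (plots) {
    ggplot2::ggsave(file.path(dir, "vpc_profile.png"), autoplot(vpc),
                    width = 7, height = 4.5, dpi = 150)
  }
  message(sprintf("summarize: VPC over %d ages | growth to %d d | %s",
                  length(ages), horizon,
                  paste0("coverage at q=", paste(quantiles, collapse = "/"))))
  invisible(list(vpc = vpc, growth = growth, coverage = coverage))
}
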
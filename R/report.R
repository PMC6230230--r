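# Report generation: run the base-case comparison or a sensitivity
# analysis and write all artifacts (summary tables, Kaplan-Meier curves,
# transition tables, run metadata) to a directory. Everything written is
# reproducible from (config, seed) alone.

.write_metadata <- function(path, params, extra = list()) {
  lines <- c(
    sprintf("package: ckdmicrosim %s", as.character(packageVersion("ckdmicrosim"))),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("parameter_hash: %s", hash(unclass(params))),
    vapply(names(extra), function(k) sprintf("%s: %s", k, format(extra[[k]])),
           character(1)),
    "parameters:",
    vapply(names(params), function(k) sprintf("  %s: %s", k, format(params[[k]])),
           character(1))
  )
  writeLines(lines, path)
}

.km_to_tibble <- function(km) {
  tibble(time = km$time, survival = km$survival, lower = km$lower,
         upper = km$upper, n_risk = km$n_risk)
}

#' Run the base-case comparison and write a report directory
#'
#' Runs [run_paired_comparison()] and writes: the comparison table
#' (means and SDs of life-years, discounted QALYs and costs for all four
#' cohorts, plus V0 and V1 per model), the four Kaplan-Meier renal-survival
#' curves, both per-arm transition tables, and a metadata file (seed,
#' cohort sizes, package version, parameter hash) sufficient to re-run.
#'
#' @param out_dir Output directory (created if missing).
#' @param params A [ckd_parameters()] object (see [load_parameters()] for
#'   config files).
#' @param n,n_calibration,seed Passed to [run_paired_comparison()].
#' @param verbose Print per-stage progress?
#' @return Invisibly, the `ckd_model_comparison`.
#' @export
run_base_case <- function(out_dir, params = ckd_parameters(),
                          n = params$cohort_size, n_calibration = n,
                          seed = params$seed, verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2) != 0) {
    abort(sprintf("output directory not writable: %s", out_dir))
  }
  cmp <- run_paired_comparison(params, n = n, n_calibration = n_calibration,
                               seed = seed, verbose = verbose)
  summary_tbl <- tidy(cmp) %>%
    mutate(v0 = ifelse(.data$model == "dg", cmp$dg$v0, cmp$kf$v0),
           v1 = ifelse(.data$model == "dg", cmp$dg$v1, cmp$kf$v1))
  readr::write_csv(summary_tbl, file.path(out_dir, "comparison.csv"))
  for (model in c("dg", "kf")) {
    for (arm in c("control", "intervention")) {
      oc <- cmp[[model]][[arm]]
      readr::write_csv(.km_to_tibble(oc$km),
                       file.path(out_dir,
                                 sprintf("km_%s_%s.csv", model, arm)))
    }
    }
  for (arm in c("control", "intervention")) {
    readr::write_csv(as_tibble(cmp$transitions[[arm]]),
                     file.path(out_dir,
                               sprintf("transitions_%s.csv", arm)))
  }
  .write_metadata(file.path(out_dir, "run_metadata.txt"), params,
                  extra = list(seed = seed, n = n,
                               n_calibration = n_calibration,
                               analysis = "base_case"))
  invisible(cmp)
}

#' Run a sensitivity analysis and write a report directory
#'
#' `mode = "one-way"` writes one CSV per varied parameter plus a combined
#' long-format file; `mode = "psa"` writes the per-draw results and a
#' percentile summary of the between-model differences (including the
#' 2.5th--97.5th percentile interval of the V0 and V1 differences).
#'
#' @param out_dir Output directory (created if missing).
#' @param mode `"one-way"` or `"psa"`.
#' @param params Base [ckd_parameters()].
#' @param n Cohort size per evaluation.
#' @param grid_points One-way grid points per parameter.
#' @param n_draws PSA draws.
#' @param seed Master seed.
#' @param verbose Print progress?
#' @return Invisibly, the result tibble.
#' @export
run_sensitivity <- function(out_dir, mode = c("one-way", "psa"),
                            params = ckd_parameters(), n = 2e4,
                            grid_points = 3, n_draws = 200,
                            seed = params$seed, verbose = TRUE) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2) != 0) {
    abort(sprintf("output directory not writable: %s", out_dir))
  }
  if (mode == "one-way") {
    res <- one_way_sa(params, grid_points = grid_points, n = n,
                      seed = seed, verbose = verbose)
    readr::write_csv(res, file.path(out_dir, "one_way_sa.csv"))
    for (nm in unique(res$parameter)) {
      readr::write_csv(res[res$parameter == nm, , drop = FALSE],
                       file.path(out_dir,
                                 sprintf("one_way_%s.csv", nm)))
    }
  } else {
    res <- probabilistic_sa(params, n_draws = n_draws, n = n, seed = seed,
                            verbose = verbose)
    readr::write_csv(res, file.path(out_dir, "psa_draws.csv"))
    readr::write_csv(psa_summary(res), file.path(out_dir, "psa_summary.csv"))
  }
  .write_metadata(file.path(out_dir, "run_metadata.txt"), params,
                  extra = list(seed = seed, n = n, analysis = mode,
                               grid_points = grid_points,
                               n_draws = n_draws))
  invisible(res)
}
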
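#' Load response series for a cluster analysis
#'
#' Reads the TEP arrays for one target from a simulation/run directory and
#' computes the requested reactivity time-series per subject: the z-scored
#' local ROI response (source space) or the GMFA (sensor space).
#'
#' @param dir Directory with `.tep` files.
#' @param target `"DLPFC"` or `"IPL"`.
#' @param measure `"local"` or `"global"`.
#' @param config [sim_config()] providing ROI definitions.
#' @return Named list of `response_series`, one per subject that completed
#'   the target.
#' @export
load_response_series <- function(dir, target, measure = c("local", "global"),
                                 config = sim_config()) {
  measure <- match.arg(measure)
  target <- match.arg(target, c("DLPFC", "IPL"))
  space <- if (measure == "local") "source_roi" else "sensor"
  files <- list.files(dir, pattern = sprintf("_%s_%s\\.tep$", target, space),
                      full.names = TRUE)
  if (length(files) == 0L)
    stopf("no %s %s TEP files for target %s in %s", space, measure, target,
          dir)
  roi <- make_roi(target, config)
  out <- list()
  for (f in files) {
    tep <- read_tep(f)
    out[[tep$subject_id]] <- if (measure == "local")
      local_response(tep, roi) else gmfa(tep)
  }
  out
}

# Split a named list of response series into resilient/vulnerable groups
# using a label table (subject_id, label).
split_by_label <- function(series, labels) {
  lab <- stats::setNames(labels$label, labels$subject_id)[names(series)]
  list(resilient = series[!is.na(lab) & lab == "resilient"],
       vulnerable = series[!is.na(lab) & lab == "vulnerable"])
}

cluster_test_json <- function(ct) {
  list(n_a = ct$n_a, n_b = ct$n_b, n_perm = ct$n_perm, alpha = ct$alpha,
       percentile = ct$percentile, null_mode = ct$null_mode, seed = ct$seed,
       time_ms = ct$time_ms, diff = ct$diff, pointwise_p = ct$pointwise_p,
       clusters = ct$clusters, surviving = ct$surviving,
       null_size = ct$null_size, null_magnitude = ct$null_magnitude)
}

fit_json <- function(f) {
  list(spec = f$spec_name, n = f$n, coefficients = f$coefficients,
       fstat = f$fstat, r2 = f$r2, r2adj = f$r2adj, loglik = f$loglik,
       aic = f$aic, bic = f$bic, lambda = f$lambda, shift = f$shift,
       residuals = unname(f$residuals))
}

#' Run the complete analysis pipeline
#'
#' Orchestrates simulate -> score -> classify -> cluster-test -> regress as
#' one reproducible run: simulates a cohort with TEP arrays, computes
#' reactivity scores, classifies subjects from their PHQ-4 trajectories,
#' runs the four cluster permutation analyses (DLPFC/IPL x local/global,
#' vulnerable minus resilient), fits the regression model suite, and writes
#' every output plus a manifest with seed and file checksums to `out_dir`.
#' The whole run is a pure function of `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Root integer seed for every stage.
#' @param n_perm Permutations per cluster test.
#' @param alpha Pointwise significance level.
#' @param percentile Cluster-null percentile.
#' @param null_mode Cluster null construction (see
#'   [cluster_permutation_test()]).
#' @return Invisibly, a list with `cohort`, `scores`, `labels`,
#'   `cluster_results` (nested by target and measure), `report`,
#'   `spearman_pss_phq`, and `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, seed = 1L,
                         n_perm = 1000, alpha = 0.05, percentile = 95,
                         null_mode = "max_per_perm") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tep_dir <- file.path(out_dir, "tep")
  log_line <- function(fmt, ...) message(sprintf(paste0("[tepflow] ", fmt), ...))

  log_line("simulate: n = %d subjects, seed = %d", config$n_subjects, seed)
  sim <- simulate_cohort(config, seed = seed, out_dir = tep_dir)
  cohort_csv <- file.path(out_dir, "cohort.csv")
  write_cohort(sim$cohort, cohort_csv, overwrite = TRUE)

  log_line("score: %d TEP files", length(sim$manifest$files))
  scores <- score_directory(tep_dir, config)
  scores_csv <- file.path(out_dir, "scores.csv")
  utils::write.csv(scores, scores_csv, row.names = FALSE, quote = FALSE)

  labels <- classify_cohort(sim$cohort)
  labels_csv <- file.path(out_dir, "labels.csv")
  utils::write.csv(labels, labels_csv, row.names = FALSE, quote = FALSE)
  log_line("classify: %d resilient, %d vulnerable",
           sum(labels$label == "resilient"),
           sum(labels$label == "vulnerable"))

  cluster_results <- list()
  cluster_files <- character(0)
  for (target in c("DLPFC", "IPL")) {
    for (measure in c("local", "global")) {
      series <- load_response_series(tep_dir, target, measure, config)
      grp <- split_by_label(series, labels)
      log_line("cluster-test %s/%s: %d resilient vs %d vulnerable",
               target, measure, length(grp$resilient),
               length(grp$vulnerable))
      ct <- cluster_permutation_test(
        grp$vulnerable, grp$resilient, n_perm = n_perm, alpha = alpha,
        percentile = percentile, null_mode = null_mode,
        seed = child_seed(seed, 1000L + match(target, c("DLPFC", "IPL")) * 2L +
                            match(measure, c("local", "global"))))
      cluster_results[[target]][[measure]] <- ct
      f <- file.path(out_dir,
                     sprintf("cluster_%s_%s.json", tolower(target), measure))
      jsonlite::write_json(cluster_test_json(ct), f, auto_unbox = TRUE,
                           digits = NA, dataframe = "columns")
      cluster_files <- c(cluster_files, f)
    }
  }

  log_line("regress: model suite")
  report <- run_model_suite(sim$cohort, scores, seed = child_seed(seed, 99L))
  report_file <- file.path(out_dir, "regression_report.json")
  jsonlite::write_json(
    list(fits = lapply(report$fits, fit_json), lrt = report$lrt,
         ic = report$ic, anova_pct = as.list(report$anova_pct),
         lilliefors = report$lilliefors,
         diagnostics = lapply(report$diagnostics, function(d)
           list(vif = as.list(d$vif), durbin_watson = d$durbin_watson,
                breusch_pagan_p = d$breusch_pagan_p))),
    report_file, auto_unbox = TRUE, digits = NA, dataframe = "columns")

  sp <- spearman_test(sim$cohort$pss14,
                      vapply(sim$cohort$phq_pandemic, mean_pandemic_score, 0))

  outputs <- c(cohort_csv, scores_csv, labels_csv, cluster_files, report_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("tepflow")),
    seed = seed, n_subjects = config$n_subjects,
    n_perm = n_perm, alpha = alpha, percentile = percentile,
    null_mode = null_mode,
    tep_files = basename(sim$manifest$files),
    outputs = basename(outputs),
    checksums = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                        basename(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  summary_lines <- c(
    sprintf("tepflow run, seed %d, %d subjects", seed, config$n_subjects),
    sprintf("resilient/vulnerable: %d/%d",
            sum(labels$label == "resilient"),
            sum(labels$label == "vulnerable")),
    sprintf("Spearman(PSS-14, mean pandemic PHQ-4): rho = %.3f, p = %.3g",
            sp$rho, sp$p),
    unlist(lapply(c("DLPFC", "IPL"), function(tg)
      lapply(c("local", "global"), function(ms) {
        ct <- cluster_results[[tg]][[ms]]
        surv <- ct$surviving
        if (nrow(surv) == 0L)
          sprintf("%s/%s: no surviving cluster", tg, ms)
        else sprintf("%s/%s: surviving cluster %g..%g ms (mass %.3g)", tg, ms,
                     surv$start_ms[1], surv$end_ms[1], surv$magnitude[1])
      }))),
    sprintf("reduced DLPFC model: R2adj = %.3f, lambda = %.3f",
            report$fits$reduced_dlpfc$r2adj,
            report$fits$reduced_dlpfc$lambda))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  invisible(list(cohort = sim$cohort, scores = scores, labels = labels,
                 cluster_results = cluster_results, report = report,
                 spearman_pss_phq = sp, manifest = manifest))
}
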
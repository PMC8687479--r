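#' Response series: global or local reactivity over time
#'
#' Internal constructor for the per-timepoint reactivity measures: the global
#' mean field amplitude (microvolts, sensor space) or the z-scored rectified
#' local ROI response (z units, source space).
#'
#' @keywords internal
response_series <- function(kind, values, time_ms, units,
                            baseline_mu = NULL, baseline_sigma = NULL) {
  structure(list(kind = kind, values = as.numeric(values),
                 time_ms = as.numeric(time_ms), units = units,
                 baseline_mu = baseline_mu, baseline_sigma = baseline_sigma),
            class = "response_series")
}

#' @export
print.response_series <- function(x, ...) {
  cat(sprintf("<response_series> %s (%s), %d samples, %g..%g ms\n", x$kind,
              x$units, length(x$values), x$time_ms[1],
              x$time_ms[length(x$time_ms)]))
  invisible(x)
}

#' Global mean field amplitude
#'
#' The per-timepoint dispersion of voltage across channels: at each sample
#' `GMFA(t) = sqrt(sum_i (V_i(t) - Vbar(t))^2 / N)` with `Vbar` the
#' instantaneous mean over the N channels — i.e. the population standard
#' deviation across channels, a reference-free measure of global evoked
#' response strength.
#'
#' @param tep A sensor-space [tep_series()] with at least 2 channels.
#' @param sample_sd Use the sample (N-1 denominator) standard deviation
#'   instead of the population one. Default FALSE.
#' @return A `response_series` of kind `"global_gmfa"` in microvolts.
#' @export
gmfa <- function(tep, sample_sd = FALSE) {
  stopifnot(inherits(tep, "tep"))
  n <- ncol(tep$data)
  if (n < 2L) stopf("GMFA is undefined for a single channel")
  centred <- tep$data - rowMeans(tep$data)
  denom <- if (sample_sd) n - 1L else n
  vals <- sqrt(rowSums(centred^2) / denom)
  response_series("global_gmfa", vals, tep_time(tep), "uV")
}

#' Local z-scored ROI response
#'
#' The source-space evoked series at the stimulated location: each ROI
#' vertex's series is rectified (absolute value), the rectified series are
#' averaged across vertices, and the average `s(t)` is normalized as
#' `z(t) = (s(t) - mu) / sigma`, where `mu` and `sigma` are the mean and
#' (population) standard deviation of `s` over the pre-stimulus baseline
#' window.
#'
#' @param tep A source-space [tep_series()].
#' @param roi A `roi` from [make_roi()] (or any list with `vertex_ids`); all
#'   ids must be present in the TEP.
#' @param baseline Baseline window in ms, default `c(-500, -3)`.
#' @return A `response_series` of kind `"local_z"` with `baseline_mu` and
#'   `baseline_sigma` recorded.
#' @export
local_response <- function(tep, roi, baseline = c(-500, -3)) {
  stopifnot(inherits(tep, "tep"))
  ids <- roi$vertex_ids %||% roi
  missing_ids <- setdiff(ids, tep$series_ids)
  if (length(missing_ids))
    stopf("ROI vertices not present in TEP: %s",
          paste(utils::head(missing_ids, 5), collapse = ", "))
  cols <- match(ids, tep$series_ids)
  s <- rowMeans(abs(tep$data[, cols, drop = FALSE]))
  tt <- tep_time(tep)
  b <- window_index(tt, baseline)
  mu <- mean(s[b])
  sigma <- sqrt(mean((s[b] - mu)^2))
  if (sigma == 0)
    stopf("degenerate baseline: zero variance in [%g, %g] ms",
          baseline[1], baseline[2])
  response_series("local_z", (s - mu) / sigma, tt, "z",
                  baseline_mu = mu, baseline_sigma = sigma)
}

#' Trapezoidal area under a response series
#'
#' Integrates the series over a closed time window (both endpoint samples
#' included) by the trapezoidal rule, with time in ms; the result is in
#' `units * ms` (z*ms for local, uV*ms for global). The default window,
#' 15-400 ms post-stimulus, starts after the interpolated pulse-artifact
#' interval and is the scalar "overall response" predictor used in the
#' regression stage.
#'
#' @param series A `response_series` (or a list with `values` and `time_ms`).
#' @param window Closed window in ms, default `c(15, 400)`.
#' @return Scalar AUC.
#' @export
auc <- function(series, window = c(15, 400)) {
  tt <- series$time_ms
  if (window[1] < tt[1] - 1e-9 || window[2] > tt[length(tt)] + 1e-9)
    stopf("window [%g, %g] ms outside the series span [%g, %g] ms",
          window[1], window[2], tt[1], tt[length(tt)])
  idx <- window_index(tt, window)
  x <- tt[idx]
  y <- series$values[idx]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Baseline pre-stimulus local activity
#'
#' Trapezoidal integral of the rectified, ROI-averaged source series (before
#' any z-scoring) over the pre-stimulus window — a control predictor
#' capturing how active the targeted patch already was before the pulse.
#'
#' @inheritParams local_response
#' @param window Baseline window in ms, default `c(-500, -3)`.
#' @return Scalar, rectified-amplitude * ms.
#' @export
baseline_activity <- function(tep, roi, window = c(-500, -3)) {
  stopifnot(inherits(tep, "tep"))
  ids <- roi$vertex_ids %||% roi
  missing_ids <- setdiff(ids, tep$series_ids)
  if (length(missing_ids))
    stopf("ROI vertices not present in TEP: %s",
          paste(utils::head(missing_ids, 5), collapse = ", "))
  cols <- match(ids, tep$series_ids)
  s <- rowMeans(abs(tep$data[, cols, drop = FALSE]))
  auc(list(values = s, time_ms = tep_time(tep)), window)
}

#' Scalar reactivity scores for one subject x target
#'
#' Bundles the three regression predictors: `local_auc` (AUC of the z-scored
#' local ROI response over 15-400 ms), `global_auc` (AUC of the sensor GMFA
#' over the same window) and `baseline_activity` (pre-stimulus rectified
#' local activity).
#'
#' @param tep_sensor Sensor-space [tep_series()].
#' @param tep_source Source-space [tep_series()] for the same subject and
#'   target.
#' @param roi ROI definition for the stimulated target.
#' @param window Response window in ms.
#' @return One-row data.frame: subject_id, target, local_auc, global_auc,
#'   baseline_activity.
#' @export
score_subject <- function(tep_sensor, tep_source, roi, window = c(15, 400)) {
  if (is.null(tep_sensor) || is.null(tep_source))
    stopf("missing sensor or source TEP for scoring")
  stopifnot(inherits(tep_sensor, "tep"), inherits(tep_source, "tep"))
  if (tep_sensor$subject_id != tep_source$subject_id ||
      tep_sensor$target != tep_source$target)
    stopf("sensor/source TEP subject or target mismatch (%s/%s vs %s/%s)",
          tep_sensor$subject_id, tep_sensor$target,
          tep_source$subject_id, tep_source$target)
  data.frame(
    subject_id = tep_source$subject_id,
    target = tep_source$target,
    local_auc = auc(local_response(tep_source, roi), window),
    global_auc = auc(gmfa(tep_sensor), window),
    baseline_activity = baseline_activity(tep_source, roi),
    stringsAsFactors = FALSE)
}

#' Score an in-memory simulated cohort
#'
#' Computes [score_subject()] for every subject x completed target of a
#' [simulate_cohort()] result that kept its evoked series in memory
#' (`out_dir = NULL`).
#'
#' @param sim Result of [simulate_cohort()] with non-NULL `teps`.
#' @param config The [sim_config()] used for the simulation.
#' @param window Response window in ms.
#' @return data.frame of reactivity scores, one row per subject x target.
#' @export
score_cohort <- function(sim, config = sim_config(), window = c(15, 400)) {
  if (is.null(sim$teps))
    stopf("simulation has no in-memory TEPs; use score_directory() on out_dir")
  rois <- list(DLPFC = make_roi("DLPFC", config),
               IPL = make_roi("IPL", config))
  rows <- list()
  for (id in names(sim$teps)) {
    for (tg in names(sim$teps[[id]])) {
      tp <- sim$teps[[id]][[tg]]
      rows[[length(rows) + 1L]] <-
        score_subject(tp$sensor, tp$source, rois[[tg]], window)
    }
  }
  do.call(rbind, rows)
}

#' Score every TEP file in a directory
#'
#' Walks a directory of `<subject>_<target>_<space>.tep` files (as written by
#' [simulate_cohort()]), pairs sensor and source arrays per subject x target,
#' and computes [score_subject()] for each complete pair.
#'
#' @param dir Directory containing `.tep` files.
#' @param config [sim_config()] providing the ROI definitions.
#' @param window Response window in ms.
#' @return data.frame of reactivity scores, one row per subject x target.
#' @export
score_directory <- function(dir, config = sim_config(), window = c(15, 400)) {
  files <- list.files(dir, pattern = "\\.tep$", full.names = TRUE)
  if (length(files) == 0L) stopf("no .tep files in %s", dir)
  meta <- do.call(rbind, lapply(files, function(f) {
    hdr <- jsonlite::fromJSON(readLines(f, n = 1L, warn = FALSE))
    data.frame(file = f, subject_id = hdr$subject_id, target = hdr$target,
               space = hdr$space, stringsAsFactors = FALSE)
  }))
  rois <- list(DLPFC = make_roi("DLPFC", config),
               IPL = make_roi("IPL", config))
  keys <- unique(meta[, c("subject_id", "target")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- meta[meta$subject_id == keys$subject_id[i] &
                  meta$target == keys$target[i], ]
    f_sen <- sub$file[sub$space == "sensor"]
    f_src <- sub$file[sub$space == "source_roi"]
    if (length(f_sen) != 1L || length(f_src) != 1L)
      stopf("subject %s target %s: need exactly one sensor and one source file",
            keys$subject_id[i], keys$target[i])
    score_subject(read_tep(f_sen), read_tep(f_src),
                  rois[[keys$target[i]]], window)
  })
  do.call(rbind, rows)
}
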
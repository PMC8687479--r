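#' TMS-evoked potential time-series
#'
#' Container for one subject's averaged evoked response to single-pulse TMS of
#' one cortical target, either in sensor space (channels, microvolts) or in
#' source space restricted to a set of vertices (unit current density).
#'
#' The time axis is expressed in milliseconds relative to the TMS pulse at
#' t = 0; sample `i` sits at `t0_ms + (i - 1) / fs_hz * 1000`. The epoch must
#' cover at least -900 ms to +400 ms so that the pre-stimulus baseline window
#' and the post-stimulus response window used downstream are always available.
#'
#' @param subject_id Character scalar, subject identifier.
#' @param target Stimulation target, `"DLPFC"` or `"IPL"`.
#' @param data Numeric matrix, samples in rows, channels/vertices in columns.
#' @param t0_ms Epoch start in ms relative to the pulse (e.g. -1000).
#' @param fs_hz Sampling rate in Hz (the acquisition standard is 1000).
#' @param space `"sensor"` or `"source_roi"`.
#' @param series_ids Character vector of channel names or vertex ids, one per
#'   column of `data`; must be unique.
#' @return An object of class `tep`.
#' @export
#' @examples
#' x <- matrix(rnorm(1301 * 4), 1301, 4)
#' tep <- tep_series("s01", "DLPFC", x, t0_ms = -900, fs_hz = 1000,
#'                   space = "sensor", series_ids = paste0("ch", 1:4))
#' range(tep_time(tep))
tep_series <- function(subject_id, target, data, t0_ms, fs_hz, space,
                       series_ids) {
  target <- match.arg(target, c("DLPFC", "IPL"))
  space <- match.arg(space, c("sensor", "source_roi"))
  if (!is.character(subject_id) || length(subject_id) != 1L || !nzchar(subject_id))
    stopf("subject_id must be a non-empty string")
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stopf("tep data contains non-finite values (subject %s)", subject_id)
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0)
    stopf("fs_hz must be a positive scalar")
  if (!is.numeric(t0_ms) || length(t0_ms) != 1L)
    stopf("t0_ms must be a numeric scalar")
  series_ids <- as.character(series_ids)
  if (length(series_ids) != ncol(data))
    stopf("series_ids length (%d) does not match number of series (%d)",
          length(series_ids), ncol(data))
  if (anyDuplicated(series_ids))
    stopf("series_ids must be unique")
  t_end <- t0_ms + (nrow(data) - 1L) / fs_hz * 1000
  if (t0_ms > -900 || t_end < 400)
    stopf("epoch [%g, %g] ms must cover at least [-900, 400] ms", t0_ms, t_end)
  structure(
    list(subject_id = subject_id, target = target, data = data,
         t0_ms = as.double(t0_ms), fs_hz = as.double(fs_hz), space = space,
         series_ids = series_ids),
    class = "tep")
}

#' @export
print.tep <- function(x, ...) {
  tt <- tep_time(x)
  cat(sprintf("<tep> subject %s, target %s, %s space\n", x$subject_id,
              x$target, x$space))
  cat(sprintf("  %d samples x %d series; %g..%g ms @ %g Hz\n",
              nrow(x$data), ncol(x$data), tt[1], tt[length(tt)], x$fs_hz))
  invisible(x)
}

#' Time axis of a TEP epoch, in ms relative to the pulse
#' @param tep A `tep` object.
#' @return Numeric vector, one entry per sample.
#' @export
tep_time <- function(tep) {
  tep$t0_ms + (seq_len(nrow(tep$data)) - 1L) * (1000 / tep$fs_hz)
}

# Indices of samples falling in the closed interval [window[1], window[2]] ms.
# A small tolerance absorbs float jitter in the time axis.
window_index <- function(time_ms, window) {
  if (window[1] > window[2]) stopf("window start exceeds end")
  eps <- 1e-9
  idx <- which(time_ms >= window[1] - eps & time_ms <= window[2] + eps)
  if (length(idx) == 0L)
    stopf("window [%g, %g] ms contains no samples", window[1], window[2])
  idx
}

#' Read / write a TEP array file
#'
#' One file holds one subject x target evoked response: the first line is a
#' JSON header carrying the metadata (`subject_id`, `target`, `t0_ms`,
#' `fs_hz`, `space`, `series_ids`) and every following line is one sample of
#' the tab-delimited numeric matrix (columns = series). The format is plain
#' text, diffable, and language neutral.
#'
#' @param path File path.
#' @return `read_tep` returns a validated [tep_series()] object.
#' @export
read_tep <- function(path) {
  if (!file.exists(path)) stopf("no such TEP file: %s", path)
  header_line <- readLines(path, n = 1L, warn = FALSE)
  hdr <- tryCatch(jsonlite::fromJSON(header_line),
                  error = function(e) stopf(
                    "malformed TEP header in %s: %s", path, conditionMessage(e)))
  for (field in c("subject_id", "target", "t0_ms", "fs_hz", "space", "series_ids"))
    if (is.null(hdr[[field]]))
      stopf("TEP header in %s is missing field '%s'", path, field)
  mat <- tryCatch(
    as.matrix(data.table::fread(path, skip = 1L, sep = "\t", header = FALSE)),
    error = function(e) stopf("malformed TEP matrix in %s: %s", path,
                              conditionMessage(e)))
  if (ncol(mat) != length(hdr$series_ids))
    stopf("TEP file %s: matrix has %d series but header names %d (field 'series_ids')",
          path, ncol(mat), length(hdr$series_ids))
  tep_series(hdr$subject_id, hdr$target, mat, hdr$t0_ms, hdr$fs_hz,
             hdr$space, hdr$series_ids)
}

#' @rdname read_tep
#' @param tep A `tep` object.
#' @param overwrite Refuse to clobber an existing file unless `TRUE`.
#' @export
write_tep <- function(tep, path, overwrite = FALSE) {
  stopifnot(inherits(tep, "tep"))
  if (file.exists(path) && !overwrite)
    stopf("file exists and overwrite = FALSE: %s", path)
  hdr <- jsonlite::toJSON(
    list(subject_id = tep$subject_id, target = tep$target, t0_ms = tep$t0_ms,
         fs_hz = tep$fs_hz, space = tep$space, series_ids = tep$series_ids),
    auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  writeLines(as.character(hdr), con)
  close(con)
  data.table::fwrite(data.table::as.data.table(tep$data), path, sep = "\t",
                     append = TRUE, col.names = FALSE)
  invisible(path)
}

# Canonical filename for a subject x target x space TEP array.
tep_filename <- function(subject_id, target, space) {
  sprintf("%s_%s_%s.tep", subject_id, target, space)
}

# ---- cohort table ----------------------------------------------------------

# Columns holding ';'-joined per-timepoint lists in the cohort CSV.
.cohort_list_cols <- c("phq_pandemic", "phq2_pandemic", "gad2_pandemic",
                       "completed_targets")

split_ints <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(v) {
    v <- v[nzchar(v)]
    if (length(v) == 0L) integer(0) else as.integer(v)
  })
}

join_vals <- function(x) vapply(x, paste, "", collapse = ";")

#' Validate a cohort table
#'
#' Checks the questionnaire and demographic invariants of a per-subject cohort
#' table: PHQ-4 totals in 0..12, subscale scores (PHQ-2 depression, GAD-2
#' anxiety) in 0..6 and summing to the total where present, one to three
#' pandemic timepoints, PSS-14 in 0..56, and categorical fields restricted to
#' their levels. Errors name the offending subjects.
#'
#' @param cohort A cohort data.frame as returned by [read_cohort()] or
#'   [simulate_cohort()].
#' @return The cohort, invisibly, if valid.
#' @export
validate_cohort <- function(cohort) {
  need <- c("subject_id", "phq_pre", "phq_pandemic", "pss14", "age", "gender",
            "education_years", "months_since_tms", "targeting_method")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stopf("cohort table is missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(cohort$subject_id))
    stopf("duplicated subject_id in cohort table")
  bad <- function(cond, what) {
    if (any(cond, na.rm = TRUE))
      stopf("cohort validation: %s for subject(s) %s", what,
            paste(cohort$subject_id[which(cond)], collapse = ", "))
  }
  bad(cohort$phq_pre < 0 | cohort$phq_pre > 12, "phq_pre outside 0..12")
  np <- lengths(cohort$phq_pandemic)
  bad(np < 1 | np > 3, "phq_pandemic must have 1..3 timepoints")
  pand_ok <- vapply(cohort$phq_pandemic,
                    function(v) all(v >= 0 & v <= 12), TRUE)
  bad(!pand_ok, "pandemic PHQ-4 score outside 0..12")
  if (all(c("phq2_pandemic", "gad2_pandemic") %in% names(cohort))) {
    sub_ok <- mapply(function(tot, p2, g2) {
      if (length(p2) == 0L && length(g2) == 0L) return(TRUE)
      length(p2) == length(tot) && length(g2) == length(tot) &&
        all(p2 >= 0 & p2 <= 6) && all(g2 >= 0 & g2 <= 6) &&
        all(p2 + g2 == tot)
    }, cohort$phq_pandemic, cohort$phq2_pandemic, cohort$gad2_pandemic)
    bad(!sub_ok, "PHQ-2/GAD-2 subscales out of 0..6 or not summing to the total")
  }
  bad(cohort$pss14 < 0 | cohort$pss14 > 56, "pss14 outside 0..56")
  bad(!cohort$gender %in% c("female", "male"), "gender not female/male")
  bad(!cohort$targeting_method %in% c("anatomical", "functional"),
      "targeting_method not anatomical/functional")
  tgt_ok <- vapply(cohort$completed_targets %||% list(),
                   function(v) all(v %in% c("DLPFC", "IPL")), TRUE)
  if (length(tgt_ok)) bad(!tgt_ok, "completed_targets outside {DLPFC, IPL}")
  invisible(cohort)
}

#' Read / write a cohort CSV
#'
#' The cohort lives in one flat CSV, one row per subject. Repeated
#' per-timepoint fields (the pandemic PHQ-4 totals and optional PHQ-2/GAD-2
#' subscale scores, and the completed stimulation targets) are ';'-joined
#' inside a single cell, e.g. `"2;1;2"`. Unknown columns are preserved on
#' read. The parsed table stores those fields as list-columns of integers
#' (character for `completed_targets`).
#'
#' @param path CSV file path.
#' @return `read_cohort` returns a validated data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stopf("no such cohort file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(.cohort_list_cols, names(df))) {
    df[[col]] <- if (col == "completed_targets") {
      lapply(strsplit(as.character(df[[col]]), ";", fixed = TRUE),
             function(v) v[nzchar(v)])
    } else split_ints(df[[col]])
  }
  validate_cohort(df)
  df
}

#' @rdname read_cohort
#' @param cohort Cohort data.frame.
#' @param overwrite Refuse to clobber an existing file unless `TRUE`.
#' @export
write_cohort <- function(cohort, path, overwrite = FALSE) {
  validate_cohort(cohort)
  if (file.exists(path) && !overwrite)
    stopf("file exists and overwrite = FALSE: %s", path)
  out <- cohort
  for (col in intersect(.cohort_list_cols, names(out)))
    out[[col]] <- join_vals(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
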
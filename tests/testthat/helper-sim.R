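# Small simulation profiles used throughout the suite: same generator,
# reduced spatial size so tests stay fast. Defaults elsewhere remain the
# study-scale configuration.

small_config <- function(n_subjects = 16, ...) {
  sim_config(n_subjects = n_subjects, epoch = c(-1000, 500), n_roi = 25,
             n_sensors = 16, ...)
}

# A deterministic noiseless TEP with hand-chosen values, for exact checks.
toy_tep <- function(data, t0_ms = -1000, fs_hz = 1000, space = "sensor",
                    target = "DLPFC", subject_id = "toy") {
  tep_series(subject_id, target, data, t0_ms, fs_hz, space,
             series_ids = if (space == "sensor")
               paste0("ch", seq_len(ncol(data)))
             else sprintf("v%04d", seq_len(ncol(data))))
}

# Flat response series on an explicit time axis (bypasses TEP plumbing).
toy_series <- function(values, time_ms) {
  structure(list(kind = "local_z", values = values, time_ms = time_ms,
                 units = "z"), class = "response_series")
}
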
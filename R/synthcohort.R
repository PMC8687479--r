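#' Simulation configuration for synthetic TMS-EEG cohorts
#'
#' Bundles every parameter of the synthetic cohort generator: evoked-response
#' shape, noise model, the latent-vulnerability links into the questionnaire
#' scores, and the sampling design (completion fractions, demographics).
#' Defaults describe a cohort of 74 middle-aged healthy adults stimulated over
#' L-DLPFC and L-IPL at 1 kHz with epochs of -1000..+2000 ms, a late local
#' response component near 230 ms whose amplitude carries the vulnerability
#' effect, and questionnaire trajectories whose pandemic increase tracks the
#' latent vulnerability and (negatively) years of education.
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param fs_hz Sampling rate, Hz.
#' @param epoch Epoch limits in ms relative to the pulse, `c(start, end)`.
#' @param components data.frame with columns `latency_ms`, `width_ms`
#'   (Gaussian SD), `amplitude_uv`, `roi_weight`; one evoked component per row.
#' @param late_window Window (ms) containing the late local component whose
#'   amplitude differs between vulnerable and resilient subjects.
#' @param effect_size Multiplicative amplitude increase of the late
#'   component(s) per unit latent vulnerability, applied to DLPFC ROI series
#'   only. The default gives a late-window standardized group difference
#'   (Cohen's d between emergent resilient/vulnerable groups) near 1.
#' @param noise_sd Marginal SD (microvolts) of the additive noise on each
#'   series, interpreted as the residual noise of a ~120-trial average.
#' @param noise_ar1 AR(1) coefficient of the coloured noise; makes adjacent
#'   samples dependent, which is what cluster correction exists for.
#' @param gain_cv Coefficient of variation of a per-subject lognormal gain
#'   multiplying all evoked amplitudes (between-subject amplitude
#'   variability).
#' @param vulnerability_link Slope tying latent vulnerability (standard
#'   normal) to the pandemic PHQ-4 increase, in PHQ points per SD.
#' @param education_effect Negative slope of the pandemic PHQ-4 increase on
#'   centred education years (PHQ points per year).
#' @param phq_intercept Constant offset of the pandemic PHQ-4 increase,
#'   chosen so roughly half the cohort classifies as resilient.
#' @param phq_noise_sd SD of the per-timepoint PHQ-4 increase noise.
#' @param phq_pre_prob Success probability of the Binomial(12) pre-pandemic
#'   PHQ-4 total.
#' @param pss_intercept,pss_slope,pss_noise_sd Linear link from the mean
#'   pandemic PHQ-4 to the PSS-14 perceived-stress score; the default noise
#'   is calibrated so that Spearman(PSS-14, mean pandemic PHQ-4) is about
#'   0.69 at large n.
#' @param timepoint_fractions Named fractions of subjects completing 3, 2 or
#'   1 pandemic questionnaires.
#' @param completion Named fractions completing the DLPFC target, the IPL
#'   target, and both.
#' @param age_mean,age_sd,age_range Demographics: age drawn from a rounded
#'   truncated normal.
#' @param edu_mean,edu_sd,edu_range Education years, same scheme.
#' @param female_fraction Fraction of female participants.
#' @param anatomical_fraction Fraction targeted anatomically (vs
#'   functionally).
#' @param months_range Range of months between the TMS session and the
#'   pandemic outbreak.
#' @param n_roi Vertices per stimulation-target region of interest in source
#'   space (the source arrays contain both ROIs).
#' @param n_sensors EEG channels in sensor space.
#' @param off_roi_weight Attenuation of component amplitudes on source
#'   vertices outside the stimulated target's ROI.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 74,
                       fs_hz = 1000,
                       epoch = c(-1000, 2000),
                       components = NULL,
                       late_window = c(202, 269),
                       effect_size = 0.4,
                       noise_sd = 2,
                       noise_ar1 = 0.95,
                       gain_cv = 0.2,
                       vulnerability_link = 1.2,
                       education_effect = 0.15,
                       phq_intercept = -0.3,
                       phq_noise_sd = 1,
                       phq_pre_prob = 0.15,
                       pss_intercept = 10,
                       pss_slope = 2.6,
                       pss_noise_sd = 3.7,
                       timepoint_fractions = c(`3` = 0.69, `2` = 0.23, `1` = 0.08),
                       completion = c(dlpfc = 0.76, ipl = 0.74, both = 0.50),
                       age_mean = 55, age_sd = 7.1, age_range = c(42, 66),
                       edu_mean = 18, edu_sd = 3.85, edu_range = c(8, 28),
                       female_fraction = 34 / 74,
                       anatomical_fraction = 29 / 74,
                       months_range = c(1, 20),
                       n_roi = 100,
                       n_sensors = 64,
                       off_roi_weight = 0.25) {
  if (is.null(components))
    components <- data.frame(
      latency_ms   = c(30, 45, 60, 100, 185, 230),
      width_ms     = c(6, 8, 10, 18, 25, 28),
      amplitude_uv = c(3, -2.5, 2.5, -2, 2, 2.5),
      roi_weight   = c(1, 1, 1, 0.8, 0.8, 1))
  cfg <- list(
    n_subjects = as.integer(n_subjects), fs_hz = fs_hz, epoch = epoch,
    components = components, late_window = late_window,
    effect_size = effect_size, noise_sd = noise_sd, noise_ar1 = noise_ar1,
    gain_cv = gain_cv, vulnerability_link = vulnerability_link,
    education_effect = education_effect, phq_intercept = phq_intercept,
    phq_noise_sd = phq_noise_sd, phq_pre_prob = phq_pre_prob,
    pss_intercept = pss_intercept, pss_slope = pss_slope,
    pss_noise_sd = pss_noise_sd,
    timepoint_fractions = timepoint_fractions, completion = completion,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    edu_mean = edu_mean, edu_sd = edu_sd, edu_range = edu_range,
    female_fraction = female_fraction,
    anatomical_fraction = anatomical_fraction, months_range = months_range,
    n_roi = as.integer(n_roi), n_sensors = as.integer(n_sensors),
    off_roi_weight = off_roi_weight)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_subjects < 4L) stopf("n_subjects must be >= 4")
  if (cfg$effect_size < 0) stopf("effect_size must be >= 0")
  if (cfg$epoch[1] > -900 || cfg$epoch[2] < 400)
    stopf("epoch must cover at least [-900, 400] ms")
  need_cols <- c("latency_ms", "width_ms", "amplitude_uv", "roi_weight")
  if (!all(need_cols %in% names(cfg$components)))
    stopf("components must have columns %s", paste(need_cols, collapse = ", "))
  win_in <- function(w) w[1] >= cfg$epoch[1] && w[2] <= cfg$epoch[2]
  if (!win_in(cfg$late_window)) stopf("late_window must lie inside the epoch")
  tf <- cfg$timepoint_fractions
  if (any(tf < 0) || abs(sum(tf) - 1) > 1e-8)
    stopf("timepoint_fractions must be non-negative and sum to 1")
  cp <- cfg$completion
  if (any(cp < 0 | cp > 1)) stopf("completion fractions must be in [0, 1]")
  if (cp[["both"]] > min(cp[["dlpfc"]], cp[["ipl"]]))
    stopf("completion['both'] cannot exceed either single-target fraction")
  if (cp[["dlpfc"]] + cp[["ipl"]] - cp[["both"]] > 1 + 1e-8)
    stopf("infeasible completion fractions: union exceeds 1")
  if (abs(cfg$noise_ar1) >= 1) stopf("noise_ar1 must be in (-1, 1)")
  if (cfg$n_roi < 1L || cfg$n_sensors < 2L)
    stopf("need n_roi >= 1 and n_sensors >= 2")
  invisible(cfg)
}

# Vertex id helpers: source arrays carry both ROIs back to back.
source_vertex_ids <- function(cfg) sprintf("v%04d", seq_len(2L * cfg$n_roi))

#' Region of interest for a stimulation target
#'
#' Returns the fixed list of source-space vertex ids the generator uses for a
#' target: vertices 1..n_roi belong to the DLPFC ROI, n_roi+1..2*n_roi to the
#' IPL ROI, mirroring a ~10 cm^2 patch of 100 vertices around each
#' stimulation coordinate.
#'
#' @param target `"DLPFC"` or `"IPL"`.
#' @param config A [sim_config()].
#' @return List of class `roi` with fields `target` and `vertex_ids`.
#' @export
make_roi <- function(target, config = sim_config()) {
  target <- match.arg(target, c("DLPFC", "IPL"))
  n <- config$n_roi
  idx <- if (target == "DLPFC") seq_len(n) else n + seq_len(n)
  structure(list(target = target,
                 vertex_ids = source_vertex_ids(config)[idx]),
            class = "roi")
}

# Gaussian bump basis over the epoch time axis: one column per component.
component_basis <- function(time_ms, components) {
  vapply(seq_len(nrow(components)), function(c_i) {
    exp(-(time_ms - components$latency_ms[c_i])^2 /
          (2 * components$width_ms[c_i]^2))
  }, numeric(length(time_ms)))
}

# AR(1)-filtered Gaussian noise, marginal SD `sd`, as a samples x series
# matrix. A warm-up stretch is discarded so the process is near-stationary
# from the first retained sample.
ar1_noise <- function(n_samples, n_series, sd, phi, warmup = 200L) {
  innov_sd <- sd * sqrt(1 - phi^2)
  eps <- matrix(stats::rnorm((n_samples + warmup) * n_series, sd = innov_sd),
                n_samples + warmup, n_series)
  filt <- stats::filter(eps, phi, method = "recursive")
  mat <- matrix(as.numeric(filt), n_samples + warmup, n_series)
  mat[warmup + seq_len(n_samples), , drop = FALSE]
}

# Fixed sensor topography: component c projects onto channel j with a smooth
# sinusoidal pattern whose phase depends on the target, mean ~0 across
# channels (average-reference-like).
sensor_weights <- function(n_sensors, n_components, target) {
  phase <- if (target == "DLPFC") 0 else pi / 3
  outer(seq_len(n_sensors) - 0.5, seq_len(n_components),
        function(j, c_i) sin(2 * pi * c_i * j / n_sensors + phase))
}

#' Simulate one subject's evoked response to one target
#'
#' Builds the subject-average evoked series as a sum of Gaussian-bump
#' components projected onto source vertices and sensor channels, plus
#' AR(1)-coloured noise. For `target = "DLPFC"` the amplitude of every
#' component whose latency falls inside `config$late_window` is scaled by
#' `1 + effect_size * vulnerability` on the DLPFC ROI vertices; the IPL
#' target and the sensor projection carry no vulnerability dependence. The
#' pre-stimulus baseline contains noise only (component bumps are negligible
#' before the pulse).
#'
#' @param profile List with `subject_id`, `vulnerability` (latent score) and
#'   optionally `gain` (per-subject amplitude multiplier, default 1).
#' @param target `"DLPFC"` or `"IPL"`.
#' @param config A [sim_config()].
#' @param seed Optional integer; when given, output is a pure function of
#'   (profile, target, config, seed).
#' @param spaces Which spaces to simulate, subset of
#'   `c("source", "sensor")`.
#' @return Named list with elements `source` and/or `sensor`, each a
#'   [tep_series()].
#' @export
simulate_subject_tep <- function(profile, target, config = sim_config(),
                                 seed = NULL,
                                 spaces = c("source", "sensor")) {
  validate_sim_config(config)
  target <- match.arg(target, c("DLPFC", "IPL"))
  spaces <- match.arg(spaces, c("source", "sensor"), several.ok = TRUE)
  gain <- profile$gain %||% 1
  with_seed(seed, {
    time_ms <- seq(config$epoch[1], config$epoch[2], by = 1000 / config$fs_hz)
    n_samples <- length(time_ms)
    comp <- config$components
    basis <- component_basis(time_ms, comp)       # T x C
    amp <- comp$amplitude_uv * gain               # per component, subject gain
    late <- comp$latency_ms >= config$late_window[1] &
      comp$latency_ms <= config$late_window[2]
    out <- list()
    if ("source" %in% spaces) {
      n_v <- 2L * config$n_roi
      roi_cols <- if (target == "DLPFC") seq_len(config$n_roi)
                  else config$n_roi + seq_len(config$n_roi)
      w <- matrix(rep(comp$roi_weight * config$off_roi_weight, each = n_v),
                  n_v, nrow(comp))                # vertices x components
      w[roi_cols, ] <- rep(comp$roi_weight, each = length(roi_cols))
      amp_mat <- matrix(rep(amp, each = n_v), n_v, nrow(comp))
      if (target == "DLPFC" && any(late)) {
        scale <- 1 + config$effect_size * profile$vulnerability
        amp_mat[roi_cols, late] <- amp_mat[roi_cols, late] * scale
      }
      signal <- basis %*% t(w * amp_mat)          # T x vertices
      noise <- ar1_noise(n_samples, n_v, config$noise_sd, config$noise_ar1)
      out$source <- tep_series(profile$subject_id, target, signal + noise,
                               config$epoch[1], config$fs_hz, "source_roi",
                               source_vertex_ids(config))
    }
    if ("sensor" %in% spaces) {
      w_s <- sensor_weights(config$n_sensors, nrow(comp), target)
      signal <- basis %*% (t(w_s) * amp)          # T x channels
      noise <- ar1_noise(n_samples, config$n_sensors, config$noise_sd,
                         config$noise_ar1)
      out$sensor <- tep_series(profile$subject_id, target, signal + noise,
                               config$epoch[1], config$fs_hz, "sensor",
                               sprintf("ch%02d", seq_len(config$n_sensors)))
    }
    out
  })
}

# Draw exact per-category counts from fractions (largest-remainder style via
# round, then random assignment).
assign_completion <- function(n, completion) {
  n_both <- round(completion[["both"]] * n)
  n_dl <- round(completion[["dlpfc"]] * n) - n_both
  n_ip <- round(completion[["ipl"]] * n) - n_both
  if (n_dl < 0 || n_ip < 0 || n_both + n_dl + n_ip > n)
    stopf("infeasible completion fractions for n = %d", n)
  lab <- c(rep("both", n_both), rep("dlpfc", n_dl), rep("ipl", n_ip),
           rep("none", n - n_both - n_dl - n_ip))
  sample(lab)
}

rtrunc_round <- function(n, mean, sd, range) {
  x <- round(stats::rnorm(n, mean, sd))
  as.integer(pmin(range[2], pmax(range[1], x)))
}

#' Simulate a full synthetic cohort
#'
#' Generates latent subject profiles (standard-normal vulnerability, lognormal
#' amplitude gain), demographics, PHQ-4 trajectories, PSS-14 scores and —
#' unless `cohort_only = TRUE` — the evoked time-series for every completed
#' subject x target. Pandemic PHQ-4 totals are
#' `clip(pre + round(vulnerability_link * vulnerability -
#' education_effect * (education - mean education) + intercept + noise),
#' 0, 12)` per completed timepoint; PHQ-2/GAD-2 subscales are a binomial
#' split of each total. Resilient/vulnerable ground truth is not drawn: it is
#' obtained by applying [classify_resilience()] to the generated trajectories.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the whole cohort is a pure function of
#'   (config, seed).
#' @param out_dir If non-NULL, TEP arrays are written there as
#'   `<subject>_<target>_<space>.tep` files and not kept in memory.
#' @param cohort_only If TRUE, skip evoked-series generation entirely
#'   (questionnaire-level studies and calibrations).
#' @param spaces Spaces to simulate for each completed target.
#' @return List with `cohort` (data.frame, see [read_cohort()]), `profiles`
#'   (data.frame: subject_id, vulnerability, gain, group_truth,
#'   n_pandemic_timepoints), `manifest` (seed + written files), and `teps`
#'   (nested list subject -> target -> space, only when `out_dir` is NULL and
#'   `cohort_only` is FALSE).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L, out_dir = NULL,
                            cohort_only = FALSE,
                            spaces = c("source", "sensor")) {
  validate_sim_config(config)
  n <- config$n_subjects
  ids <- sprintf("sub%03d", seq_len(n))
  with_seed(seed, {
    vulnerability <- stats::rnorm(n)
    sdlog <- sqrt(log(1 + config$gain_cv^2))
    gain <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    age <- rtrunc_round(n, config$age_mean, config$age_sd, config$age_range)
    education <- rtrunc_round(n, config$edu_mean, config$edu_sd,
                              config$edu_range)
    gender <- sample(c("female", "male"), n, replace = TRUE,
                     prob = c(config$female_fraction,
                              1 - config$female_fraction))
    method <- sample(c("anatomical", "functional"), n, replace = TRUE,
                     prob = c(config$anatomical_fraction,
                              1 - config$anatomical_fraction))
    months <- sample(seq(config$months_range[1], config$months_range[2]), n,
                     replace = TRUE)
    phq_pre <- stats::rbinom(n, 12L, config$phq_pre_prob)
    n_tp <- sample(as.integer(names(config$timepoint_fractions)), n,
                   replace = TRUE, prob = config$timepoint_fractions)
    edu_c <- education - mean(education)
    phq_pandemic <- lapply(seq_len(n), function(i) {
      delta <- round(config$vulnerability_link * vulnerability[i] -
                       config$education_effect * edu_c[i] +
                       config$phq_intercept +
                       stats::rnorm(n_tp[i], sd = config$phq_noise_sd))
      as.integer(pmin(12L, pmax(0L, phq_pre[i] + delta)))
    })
    phq2_pandemic <- lapply(phq_pandemic, function(tot) {
      p2 <- stats::rbinom(length(tot), tot, 0.5)
      as.integer(pmin(6L, pmax(tot - 6L, p2)))
    })
    gad2_pandemic <- mapply(function(tot, p2) as.integer(tot - p2),
                            phq_pandemic, phq2_pandemic, SIMPLIFY = FALSE)
    mean_pand <- vapply(phq_pandemic, mean, 0)
    pss14 <- as.integer(pmin(56, pmax(0, round(
      config$pss_intercept + config$pss_slope * mean_pand +
        stats::rnorm(n, sd = config$pss_noise_sd)))))
    comp_lab <- assign_completion(n, config$completion)
    completed <- lapply(comp_lab, function(l)
      switch(l, both = c("DLPFC", "IPL"), dlpfc = "DLPFC", ipl = "IPL",
             none = character(0)))
    cohort <- data.frame(subject_id = ids, phq_pre = phq_pre,
                         pss14 = pss14, age = age, gender = gender,
                         education_years = education,
                         months_since_tms = months,
                         targeting_method = method,
                         stringsAsFactors = FALSE)
    cohort$phq_pandemic <- phq_pandemic
    cohort$phq2_pandemic <- phq2_pandemic
    cohort$gad2_pandemic <- gad2_pandemic
    cohort$completed_targets <- completed
    validate_cohort(cohort)
    labels <- vapply(seq_len(n), function(i)
      classify_resilience(phq_pre[i], phq_pandemic[[i]])$label, "")
    profiles <- data.frame(subject_id = ids, vulnerability = vulnerability,
                           gain = gain, group_truth = labels,
                           n_pandemic_timepoints = n_tp,
                           stringsAsFactors = FALSE)
    manifest <- list(seed = seed, n_subjects = n, files = character(0))
    teps <- NULL
    if (!cohort_only) {
      if (!is.null(out_dir) && !dir.exists(out_dir))
        dir.create(out_dir, recursive = TRUE)
      teps <- stats::setNames(vector("list", n), ids)
      for (i in seq_len(n)) {
        prof <- list(subject_id = ids[i], vulnerability = vulnerability[i],
                     gain = gain[i])
        for (tg in completed[[i]]) {
          tp <- simulate_subject_tep(prof, tg, config,
                                     seed = child_seed(seed, i * 2L +
                                                         (tg == "IPL")),
                                     spaces = spaces)
          if (is.null(out_dir)) {
            teps[[i]][[tg]] <- tp
          } else {
            for (sp in names(tp)) {
              f <- file.path(out_dir,
                             tep_filename(ids[i], tg, tp[[sp]]$space))
              write_tep(tp[[sp]], f, overwrite = TRUE)
              manifest$files <- c(manifest$files, f)
            }
          }
        }
      }
      if (!is.null(out_dir)) teps <- NULL
    }
    list(cohort = cohort, profiles = profiles, manifest = manifest,
         teps = teps)
  })
}
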
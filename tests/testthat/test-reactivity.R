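test_that("GMFA equals the per-sample population SD across channels", {
  # identical channels: zero dispersion
  flat <- toy_tep(matrix(7, 1401, 3))
  expect_true(all(gmfa(flat)$values == 0))
  # two channels at +1/-1: GMFA = 1
  two <- toy_tep(cbind(rep(1, 1401), rep(-1, 1401)))
  expect_true(all(gmfa(two)$values == 1))
  # random matrix vs brute-force loop oracle
  set.seed(42)
  m <- matrix(rnorm(1401 * 5), 1401, 5)
  tp <- toy_tep(m)
  oracle <- vapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]; sqrt(sum((v - mean(v))^2) / length(v))
  }, 0)
  expect_equal(gmfa(tp)$values, oracle, tolerance = 1e-12)
  # sample-SD variant and column-permutation invariance
  expect_equal(gmfa(tp, sample_sd = TRUE)$values,
               apply(m, 1, stats::sd), tolerance = 1e-12)
  perm <- toy_tep(m[, c(3, 1, 5, 2, 4)])
  expect_equal(gmfa(perm)$values, gmfa(tp)$values, tolerance = 1e-12)
  expect_error(gmfa(toy_tep(m[, 1, drop = FALSE])), "single channel")
})

test_that("local z-response implements (s - mu) / sigma on the baseline", {
  # baseline alternating mu +/- c, post-stimulus samples at known offsets
  n <- 1401
  tt <- -1000 + seq_len(n) - 1
  mu <- 2; cc <- 0.5
  s <- rep(mu, n)
  bl <- which(tt >= -500 & tt <= -3)
  s[bl] <- mu + cc * rep_len(c(1, -1), length(bl))
  tp <- toy_tep(matrix(s, n, 2), space = "source_roi")
  roi <- list(vertex_ids = c("v0001", "v0002"))
  z <- local_response(tp, roi)
  expect_equal(z$baseline_mu, mu)
  expect_equal(z$baseline_sigma, cc)
  post <- which(tt == 100)
  expect_equal(z$values[post], 0)            # s = mu there
  s2 <- s; s2[post] <- mu + 2 * cc
  z2 <- local_response(toy_tep(matrix(s2, n, 2), space = "source_roi"), roi)
  expect_equal(z2$values[post], 2)
  # rectification precedes averaging: vertices +a and -a give |a|
  a <- abs(rnorm(n)) + 0.5
  tp3 <- toy_tep(cbind(a, -a), space = "source_roi")
  z3 <- local_response(tp3, roi)
  s3 <- a   # mean(|a|, |-a|) = a
  expect_equal(z3$values,
               (s3 - mean(s3[bl])) / sqrt(mean((s3[bl] - mean(s3[bl]))^2)),
               tolerance = 1e-12)
})

test_that("generated z-series have baseline mean 0 and SD 1", {
  cfg <- small_config()
  roi <- make_roi("DLPFC", cfg)
  for (s in 1:5) {
    tp <- simulate_subject_tep(list(subject_id = "s", vulnerability = 1),
                               "DLPFC", cfg, seed = s)$source
    z <- local_response(tp, roi)
    bl <- z$time_ms >= -500 & z$time_ms <= -3
    expect_equal(mean(z$values[bl]), 0, tolerance = 1e-10)
    expect_equal(sqrt(mean(z$values[bl]^2)), 1, tolerance = 1e-10)
  }
})

test_that("local response validates its ROI and baseline", {
  tp <- toy_tep(matrix(3, 1401, 2), space = "source_roi")
  expect_error(local_response(tp, list(vertex_ids = c("v0001", "v9999"))),
               "v9999")
  expect_error(local_response(tp, list(vertex_ids = c("v0001", "v0002"))),
               "degenerate baseline")
  # vertex order does not matter
  set.seed(7)
  m <- matrix(rnorm(1401 * 4), 1401, 4)
  tp4 <- toy_tep(m, space = "source_roi")
  f <- local_response(tp4, list(vertex_ids = sprintf("v%04d", 1:4)))
  r <- local_response(tp4, list(vertex_ids = sprintf("v%04d", c(4, 2, 1, 3))))
  expect_equal(f$values, r$values, tolerance = 1e-12)
})

test_that("trapezoidal AUC matches closed forms and is linear", {
  n <- 1401
  tt <- -1000 + seq_len(n) - 1
  expect_equal(auc(toy_series(rep(1, n), tt)), 385)       # unit over 385 ms
  # linear ramp: exact quadratic integral
  ramp <- toy_series(tt / 100, tt)
  expect_equal(auc(ramp), (400^2 - 15^2) / 200, tolerance = 1e-9)
  # trapezoid is exact for linear data at any sampling rate whose grid
  # still hits the window endpoints
  tt2 <- seq(-1000, 400, by = 5)
  ramp2 <- toy_series(tt2 / 100, tt2)
  expect_equal(auc(ramp2), auc(ramp), tolerance = 1e-9)
  # linearity: auc(a x + b y) = a auc(x) + b auc(y)
  set.seed(1)
  for (k in 1:5) {
    x <- toy_series(rnorm(n), tt); y <- toy_series(rnorm(n), tt)
    a <- rnorm(1); b <- rnorm(1)
    comb <- toy_series(a * x$values + b * y$values, tt)
    expect_equal(auc(comb), a * auc(x) + b * auc(y), tolerance = 1e-9)
  }
  expect_error(auc(toy_series(rep(1, n), tt), window = c(15, 500)),
               "outside the series span")
})

test_that("baseline activity integrates the rectified ROI mean", {
  n <- 1401
  roi <- list(vertex_ids = c("v0001", "v0002"))
  zero <- toy_tep(matrix(0, n, 2), space = "source_roi")
  expect_equal(baseline_activity(zero, roi), 0)
  const <- toy_tep(matrix(-3, n, 2), space = "source_roi")  # |s| = 3
  expect_equal(baseline_activity(const, roi), 3 * 497)
  # brute-force trapezoid oracle on generator output
  cfg <- small_config()
  tp <- simulate_subject_tep(list(subject_id = "s", vulnerability = 0),
                             "DLPFC", cfg, seed = 3)$source
  roi_dl <- make_roi("DLPFC", cfg)
  s <- rowMeans(abs(tp$data[, match(roi_dl$vertex_ids, tp$series_ids)]))
  tt <- tep_time(tp)
  idx <- which(tt >= -500 & tt <= -3)
  oracle <- 0
  for (i in idx[-length(idx)])
    oracle <- oracle + (tt[i + 1] - tt[i]) * (s[i] + s[i + 1]) / 2
  expect_equal(baseline_activity(tp, roi_dl), oracle, tolerance = 1e-9)
})

test_that("subject scoring composes the three measures", {
  cfg <- small_config()
  roi <- make_roi("DLPFC", cfg)
  tp <- simulate_subject_tep(list(subject_id = "s07", vulnerability = 1),
                             "DLPFC", cfg, seed = 13)
  sc <- score_subject(tp$sensor, tp$source, roi)
  expect_equal(sc$local_auc, auc(local_response(tp$source, roi)))
  expect_equal(sc$global_auc, auc(gmfa(tp$sensor)))
  expect_equal(sc$baseline_activity, baseline_activity(tp$source, roi))
  expect_identical(sc$subject_id, "s07")
  expect_error(score_subject(NULL, tp$source, roi), "missing")
  other <- simulate_subject_tep(list(subject_id = "s08", vulnerability = 1),
                                "DLPFC", cfg, seed = 14)
  expect_error(score_subject(other$sensor, tp$source, roi), "mismatch")
})

test_that("cohort scoring covers every completed subject x target", {
  cfg <- small_config(n_subjects = 10)
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(cfg, seed = 8, out_dir = dir)
  sc <- score_directory(dir, cfg)
  expected <- sum(lengths(sim$cohort$completed_targets))
  expect_identical(nrow(sc), expected)
  expect_identical(anyDuplicated(sc[, c("subject_id", "target")]), 0L)
  # in-memory scoring agrees with the file-based path
  sim2 <- simulate_cohort(cfg, seed = 8)
  sc2 <- score_cohort(sim2, cfg)
  key <- function(d) d[order(d$subject_id, d$target), ]
  expect_equal(key(sc)$local_auc, key(sc2)$local_auc, tolerance = 1e-9)
  expect_equal(key(sc)$global_auc, key(sc2)$global_auc, tolerance = 1e-9)
})
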
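make_scores <- function(ids, target = "DLPFC", local = NULL) {
  n <- length(ids)
  data.frame(subject_id = ids, target = target,
             local_auc = if (is.null(local)) rnorm(n, 100, 20) else local,
             global_auc = rnorm(n, 500, 60),
             baseline_activity = rnorm(n, 800, 50),
             stringsAsFactors = FALSE)
}

test_that("design matrices code predictors as documented", {
  sim <- simulate_cohort(sim_config(n_subjects = 30), seed = 4,
                         cohort_only = TRUE)
  co <- sim$cohort
  co$completed_targets <- rep(list("DLPFC"), nrow(co))
  set.seed(1)
  sc <- make_scores(co$subject_id)
  full <- build_design(co, sc, model_spec("full_dlpfc"))
  expect_identical(ncol(full$data), 9L)   # response + 8 predictors
  expect_setequal(setdiff(names(full$data), "response"),
                  model_spec("full_dlpfc")$predictors)
  red <- build_design(co, sc, model_spec("reduced_dlpfc"))
  expect_identical(ncol(red$data), 3L)    # response + 2 predictors
  # hand-built 3-subject check
  toy <- co[1:3, ]
  toy$phq2_pandemic <- NULL
  toy$gad2_pandemic <- NULL
  toy$gender <- c("female", "male", "female")
  toy$targeting_method <- c("anatomical", "functional", "functional")
  toy$phq_pandemic <- list(c(2L, 4L), 1L, c(0L, 1L, 2L))
  sc3 <- make_scores(toy$subject_id)
  d <- build_design(toy, sc3, model_spec("full_dlpfc"))$data
  expect_equal(d$response, c(3, 1, 1))
  expect_equal(d$gender, c(0, 1, 0))
  expect_equal(d$local_auc_x_method, sc3$local_auc * c(0, 1, 1))
  expect_equal(d$global_auc_x_method, sc3$global_auc * c(0, 1, 1))
  expect_equal(d$age, toy$age)
  # subjects without the target are dropped
  co2 <- co; co2$completed_targets[[1]] <- "IPL"
  expect_message(build_design(co2, sc[-1, ], model_spec("full_dlpfc")),
                 "dropped 1 of 30")
})

test_that("Box-Cox profile likelihood recovers generative exponents", {
  set.seed(11)
  # identity case: normal response prefers lambda near 1
  y1 <- rnorm(500, mean = 10, sd = 3)
  bc1 <- boxcox_fit(y1)
  expect_lt(abs(bc1$lambda - 1), 0.3)
  # log case: exp(normal) prefers lambda near 0
  y0 <- exp(rnorm(500, sd = 0.5))
  bc0 <- boxcox_fit(y0)
  expect_lt(abs(bc0$lambda), 0.3)
  # lambda = 1 transform is y - 1 exactly
  expect_equal(boxcox_fit(y1, grid = 1)$y, y1 - 1)
  # shift activates only for non-positive values
  expect_equal(boxcox_fit(y1)$shift, 0)
  yz <- c(0, 1, 3, 2, 5, 4)
  bcz <- boxcox_fit(yz)
  expect_equal(bcz$shift, 1)
  # monotone for every lambda: ranks preserved
  for (lam in c(-2, -0.5, 0, 0.5, 2))
    expect_identical(order(boxcox_fit(yz, grid = lam)$y), order(yz))
  # agrees with the MASS profile-likelihood oracle
  skip_if_not_installed("MASS")
  grid <- seq(-2, 2, by = 0.01)
  mb <- MASS::boxcox(y ~ 1, data = data.frame(y = y0), lambda = grid,
                     plotit = FALSE)
  expect_equal(boxcox_fit(y0, grid = grid)$lambda, mb$x[which.max(mb$y)],
               tolerance = 1e-8)
  expect_error(boxcox_fit(rep(2, 10)), "constant")
})

test_that("OLS fits match the normal-equations oracle", {
  # exact linear data
  x <- seq(0, 10, length.out = 20)
  fit <- suppressWarnings(fit_ols(data.frame(x = x), response = 3 + 2 * x))
  expect_equal(fit$coefficients$estimate, c(3, 2), tolerance = 1e-10)
  expect_equal(fit$r2, 1)
  expect_equal(unname(fit$residuals), rep(0, 20), tolerance = 1e-10)
  # random instances vs pseudoinverse brute force
  set.seed(21)
  for (k in 1:10) {
    n <- 50; p <- 3
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, c("a", "b", "c")))
    y <- rnorm(n)
    f <- fit_ols(as.data.frame(X), response = y)
    Xi <- cbind(1, X)
    beta <- unname(drop(solve(t(Xi) %*% Xi, t(Xi) %*% y)))
    expect_equal(f$coefficients$estimate, beta, tolerance = 1e-8)
    res <- y - Xi %*% beta
    s2 <- sum(res^2) / (n - p - 1)
    se <- unname(sqrt(diag(solve(t(Xi) %*% Xi)) * s2))
    expect_equal(f$coefficients$se, se, tolerance = 1e-8)
    expect_equal(f$coefficients$t, beta / se, tolerance = 1e-8)
    # F against intercept-only, R2adj, information criteria from loglik
    tss <- sum((y - mean(y))^2); rss <- sum(res^2)
    Fo <- ((tss - rss) / p) / (rss / (n - p - 1))
    expect_equal(f$fstat$F, Fo, tolerance = 1e-8)
    expect_equal(f$r2adj, 1 - (1 - (1 - rss / tss)) * (n - 1) / (n - p - 1),
                 tolerance = 1e-8)
    ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
    expect_equal(f$loglik, ll, tolerance = 1e-8)
    expect_equal(f$aic, -2 * ll + 2 * (p + 2), tolerance = 1e-8)
    expect_equal(f$bic, -2 * ll + (p + 2) * log(n), tolerance = 1e-8)
  }
  # rank deficiency is an explicit error
  X2 <- data.frame(a = 1:10, b = (1:10) * 2)
  expect_error(fit_ols(X2, response = rnorm(10)), "singular")
})

test_that("OLS coefficient estimates are unbiased under the true model", {
  set.seed(31)
  beta <- c(1, 2, -1.5)
  est <- replicate(200, {
    X <- matrix(rnorm(100 * 2), 100, 2, dimnames = list(NULL, c("a", "b")))
    y <- beta[1] + X %*% beta[-1] + rnorm(100, sd = 2)
    fit_ols(as.data.frame(X), response = drop(y))$coefficients$estimate
  })
  bias <- rowMeans(est) - beta
  se_mc <- apply(est, 1, sd) / sqrt(ncol(est))
  expect_true(all(abs(bias) < 3 * se_mc + 1e-3))
})

test_that("Lilliefors statistic matches nortest and is affine invariant", {
  set.seed(41)
  x <- rnorm(60, mean = 5, sd = 3)
  got <- lilliefors_test(x, nsim = 2000, seed = 1)
  skip_if_not_installed("nortest")
  expect_equal(got$D, unname(nortest::lillie.test(x)$statistic),
               tolerance = 1e-10)
  resc <- lilliefors_test(7 - 2.5 * x, nsim = 500, seed = 1)
  expect_equal(resc$D, got$D, tolerance = 1e-12)
  # clearly non-normal data is flagged
  y <- rexp(100)
  expect_lt(lilliefors_test(y, nsim = 2000, seed = 2)$p, 0.01)
  # p-value roughly calibrated under the null
  rejections <- vapply(1:60, function(s) {
    lilliefors_test(rnorm(40), nsim = 400, seed = s)$p < 0.05
  }, TRUE)
  expect_lt(abs(mean(rejections) - 0.05), 0.10)
})

test_that("likelihood ratio test satisfies its algebraic identities", {
  set.seed(51)
  n <- 60
  X <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(NULL, paste0("x", 1:8)))
  y <- 1 + X[, 1] - X[, 2] + rnorm(n)
  full <- fit_ols(as.data.frame(X), response = y)
  red <- fit_ols(as.data.frame(X[, 1:2]), response = y)
  lrt <- likelihood_ratio_test(full, red)
  expect_identical(lrt$df, 6L)
  expect_equal(lrt$chi2, n * log(red$rss / full$rss), tolerance = 1e-8)
  expect_equal(lrt$chi2, 2 * (full$loglik - red$loglik), tolerance = 1e-8)
  # degenerate comparison: same model
  same <- likelihood_ratio_test(full, full)
  expect_equal(same$chi2, 0, tolerance = 1e-10)
  expect_equal(same$p, 1)
  # guards
  other <- fit_ols(as.data.frame(X[, 1:2]), response = rev(y))
  expect_error(likelihood_ratio_test(full, other), "different response")
  expect_error(likelihood_ratio_test(
    red, fit_ols(data.frame(z = rnorm(n)), response = y)), "not nested")
  expect_error(likelihood_ratio_test(
    full, fit_ols(as.data.frame(X[1:30, 1:2]), response = y[1:30])),
    "different sample sizes")
})

test_that("sequential variance decomposition sums to 100 and matches RSS decrements", {
  set.seed(61)
  n <- 80
  df <- data.frame(a = rnorm(n), b = rnorm(n))
  df$y <- 2 * df$a + rnorm(n, sd = 0.1)
  fit <- fit_ols(df[, c("a", "b")], response = df$y)
  pct <- anova_percent_variance(fit, order = c("a", "b"))
  expect_equal(sum(pct), 100, tolerance = 1e-8)
  expect_gt(pct[["a"]], 95)
  expect_lt(pct[["b"]], 2)
  # brute-force nested-RSS oracle
  rss <- function(fml) sum(resid(lm(fml, data = cbind(df, .y = df$y)))^2)
  tss <- sum((df$y - mean(df$y))^2)
  ss_a <- rss(.y ~ 1) - rss(.y ~ a)
  ss_b <- rss(.y ~ a) - rss(.y ~ a + b)
  expect_equal(pct[["a"]], 100 * ss_a / tss, tolerance = 1e-8)
  expect_equal(pct[["b"]], 100 * ss_b / tss, tolerance = 1e-8)
  # predictors orthogonal to each other and the intercept: order invariant
  m <- qr.Q(qr(cbind(1, matrix(rnorm(n * 2), n, 2))))[, 2:3]
  dfo <- data.frame(a = m[, 1], b = m[, 2])
  yo <- m %*% c(1, 2) + rnorm(n, sd = 0.5)
  fo <- fit_ols(dfo, response = drop(yo))
  p1 <- anova_percent_variance(fo, order = c("a", "b"))
  p2 <- anova_percent_variance(fo, order = c("b", "a"))
  expect_equal(p1[["a"]], p2[["a"]], tolerance = 1e-6)
  expect_error(anova_percent_variance(fo, order = c("a", "z")),
               "permutation")
})

test_that("assumption diagnostics behave on known designs", {
  set.seed(71)
  n <- 500
  m <- qr.Q(qr(cbind(1, matrix(rnorm(n * 2), n, 2))))[, 2:3]
  df <- data.frame(a = m[, 1], b = m[, 2])
  y <- drop(m %*% c(1, -1)) + rnorm(n)
  fit <- fit_ols(df, response = y)
  d <- ols_diagnostics(fit)
  expect_equal(unname(d$vif), c(1, 1), tolerance = 1e-6)
  expect_lt(abs(d$durbin_watson - 2), 0.3)
  expect_gt(d$breusch_pagan_p, 0.001)
  # heteroscedastic residuals are detected most of the time
  hits <- vapply(1:20, function(s) {
    set.seed(200 + s)
    x <- runif(200, 1, 5)
    yh <- x + rnorm(200, sd = 0.4 * x)
    ols_diagnostics(fit_ols(data.frame(x = x, x2 = rnorm(200)),
                            response = yh))$breusch_pagan_p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.8)
  # single-predictor model reports unit VIF
  expect_equal(unname(ols_diagnostics(
    fit_ols(data.frame(x = rnorm(30)), response = rnorm(30)))$vif), 1)
})

test_that("the model suite fits all four models coherently", {
  cfg <- small_config(n_subjects = 40)
  sim <- simulate_cohort(cfg, seed = 17)
  scores <- score_cohort(sim, cfg)
  report <- suppressMessages(
    run_model_suite(sim$cohort, scores, lilliefors_nsim = 200, seed = 3))
  expect_named(report$fits, c("full_dlpfc", "reduced_dlpfc", "full_ipl",
                              "reduced_plus_baseline"))
  expect_identical(report$lrt$df, 6L)
  # reduced fitted on the same subjects as full: LRT is well defined
  expect_identical(report$fits$full_dlpfc$n, report$fits$reduced_dlpfc$n)
  expect_gte(report$lrt$chi2, 0)
  expect_equal(sum(report$anova_pct), 100, tolerance = 1e-8)
  expect_identical(names(report$anova_pct)[1:2],
                   c("local_auc", "education_years"))
  for (f in report$fits) {
    expect_true(is.finite(f$aic) && is.finite(f$bic))
    expect_lte(f$r2adj, f$r2)
    expect_identical(f$df_model + f$df_resid + 1L, f$n)
    expect_false(is.null(f$lambda))
  }
  expect_identical(report$fits$full_dlpfc$df_model, 8L)
  expect_identical(report$fits$reduced_plus_baseline$df_model, 3L)
  # deterministic given the same inputs
  report2 <- suppressMessages(
    run_model_suite(sim$cohort, scores, lilliefors_nsim = 200, seed = 3))
  expect_equal(report$ic, report2$ic, tolerance = 1e-12)
  expect_equal(report$lilliefors, report2$lilliefors, tolerance = 1e-12)
})
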
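#' Model specifications for the mental-health regressions
#'
#' Four named predictor sets, all with the mean pandemic PHQ-4 score as
#' response:
#' * `full_dlpfc` — local and global DLPFC reactivity AUCs, their
#'   interactions with the targeting method, age, gender, education years and
#'   months since the TMS session (8 predictors).
#' * `reduced_dlpfc` — local DLPFC reactivity and education years only.
#' * `full_ipl` — the full set with reactivity measured at the IPL control
#'   target.
#' * `reduced_plus_baseline` — the reduced set plus the pre-stimulus local
#'   baseline activity.
#'
#' @param name One of the four model names.
#' @return List with `name`, `target` and `predictors`.
#' @export
model_spec <- function(name = c("full_dlpfc", "reduced_dlpfc", "full_ipl",
                                "reduced_plus_baseline")) {
  name <- match.arg(name)
  full <- c("local_auc", "global_auc", "local_auc_x_method",
            "global_auc_x_method", "age", "gender", "education_years",
            "months_since_tms")
  reduced <- c("local_auc", "education_years")
  switch(name,
    full_dlpfc = list(name = name, target = "DLPFC", predictors = full),
    reduced_dlpfc = list(name = name, target = "DLPFC", predictors = reduced),
    full_ipl = list(name = name, target = "IPL", predictors = full),
    reduced_plus_baseline = list(name = name, target = "DLPFC",
                                 predictors = c(reduced, "baseline_activity")))
}

#' Build a regression design from cohort and reactivity scores
#'
#' Joins the cohort table with the reactivity scores for the model's target,
#' codes gender (female = 0, male = 1) and targeting method (anatomical = 0,
#' functional = 1), forms the method interactions as products with the AUC
#' predictors, and computes the response as each subject's mean pandemic
#' PHQ-4 score. Subjects missing the target or any required field are
#' dropped (count reported).
#'
#' @param cohort Cohort data.frame.
#' @param scores Reactivity scores from [score_subject()]/[score_directory()].
#' @param spec A [model_spec()].
#' @return List with `data` (data.frame: `response` plus one column per
#'   predictor), `spec`, `subject_id`, and `n_dropped`.
#' @export
build_design <- function(cohort, scores, spec) {
  validate_cohort(cohort)
  sc <- scores[scores$target == spec$target, , drop = FALSE]
  merged <- merge(cohort, sc, by = "subject_id")
  n_candidates <- nrow(cohort)
  if (nrow(merged) == 0L)
    stopf("no subjects with completed %s target", spec$target)
  merged$response <- vapply(merged$phq_pandemic, mean_pandemic_score, 0)
  merged$gender <- as.numeric(merged$gender == "male")
  merged$method <- as.numeric(merged$targeting_method == "functional")
  merged$local_auc_x_method <- merged$local_auc * merged$method
  merged$global_auc_x_method <- merged$global_auc * merged$method
  need <- c("response", spec$predictors)
  complete <- stats::complete.cases(merged[, need])
  dropped <- sum(!complete) + (n_candidates - nrow(merged))
  merged <- merged[complete, , drop = FALSE]
  if (nrow(merged) == 0L) stopf("empty design after filtering")
  if (dropped > 0)
    message(sprintf("build_design(%s): dropped %d of %d subjects",
                    spec$name, dropped, n_candidates))
  list(data = merged[, need, drop = FALSE], spec = spec,
       subject_id = merged$subject_id, n_dropped = dropped)
}

#' Box-Cox transformation by profile likelihood
#'
#' Estimates the Box-Cox exponent by maximizing the profile log-likelihood
#' `-n/2 * log(sigma_hat^2(lambda)) + (lambda - 1) * sum(log y)` on a grid
#' over \[-5, 5\] (step 0.001), after shifting the data by `1 - min(y)` when
#' any value is non-positive. The transform is `(y^lambda - 1) / lambda` for
#' `lambda != 0` and `log(y)` at `lambda = 0`; it is monotone for every
#' lambda, so ranks are preserved.
#'
#' @param y Numeric vector (positive after the automatic shift).
#' @param grid Candidate lambda values.
#' @return List with `y` (transformed values), `lambda`, `shift`, and
#'   `loglik` (profile log-likelihood at the optimum).
#' @export
boxcox_fit <- function(y, grid = seq(-5, 5, by = 1e-3)) {
  if (length(y) < 3L) stopf("need at least 3 observations")
  if (stats::sd(y) == 0) stopf("Box-Cox transform undefined for constant y")
  shift <- if (min(y) <= 0) 1 - min(y) else 0
  ys <- y + shift
  n <- length(ys)
  logy <- log(ys)
  slog <- sum(logy)
  ll <- vapply(grid, function(l) {
    yt <- if (abs(l) < 1e-12) logy else (exp(l * logy) - 1) / l
    v <- mean((yt - mean(yt))^2)
    if (v <= 0) return(-Inf)
    -n / 2 * log(v) + (l - 1) * slog
  }, 0)
  best <- which.max(ll)
  lambda <- grid[best]
  yt <- if (abs(lambda) < 1e-12) logy else (exp(lambda * logy) - 1) / lambda
  list(y = yt, lambda = lambda, shift = shift, loglik = ll[best])
}

#' Ordinary least squares fit with inference summaries
#'
#' Fits `response ~ predictors` by least squares (via [stats::lm()]) and
#' collects per-coefficient t statistics and two-sided p-values, the overall
#' F test against the intercept-only model, adjusted R-squared, the Gaussian
#' log-likelihood, and AIC/BIC counting the intercept, slopes and the error
#' variance as parameters (`AIC = -2*ll + 2*k`, `BIC = -2*ll + k*log(n)`
#' with `k = p + 2` for p predictors).
#'
#' @param design Output of [build_design()], or a data.frame of predictors
#'   (then `response` must be given).
#' @param response Numeric response vector when `design` is a plain
#'   data.frame; overrides the design's response column (e.g. a Box-Cox
#'   transformed version).
#' @param lambda,shift Optional Box-Cox parameters recorded in the fit.
#' @return Object of class `tep_fit`.
#' @export
fit_ols <- function(design, response = NULL, lambda = NULL, shift = NULL) {
  if (is.list(design) && !is.null(design$data)) {
    df <- design$data
    spec_name <- design$spec$name
    subject_id <- design$subject_id
  } else {
    df <- as.data.frame(design)
    if (is.null(response) && !"response" %in% names(df))
      stopf("supply a response vector or a 'response' column")
    spec_name <- NULL
    subject_id <- NULL
  }
  if (!is.null(response)) df$response <- response
  predictors <- setdiff(names(df), "response")
  n <- nrow(df)
  if (n <= length(predictors) + 1L)
    stopf("need n > number of predictors + 1 (n = %d, p = %d)", n,
          length(predictors))
  fit <- stats::lm(response ~ ., data = df)
  if (anyNA(stats::coef(fit)))
    stopf("singular design matrix: %s",
          paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                collapse = ", "))
  sm <- summary(fit)
  coefs <- as.data.frame(sm$coefficients)
  names(coefs) <- c("estimate", "se", "t", "p")
  coefs <- cbind(term = rownames(coefs), coefs, stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  ll <- as.numeric(stats::logLik(fit))
  fstat <- if (is.null(sm$fstatistic)) NULL else list(
    F = unname(sm$fstatistic[1]), df1 = unname(sm$fstatistic[2]),
    df2 = unname(sm$fstatistic[3]),
    p = unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                         sm$fstatistic[3], lower.tail = FALSE)))
  structure(list(
    coefficients = coefs, fstat = fstat, r2 = sm$r.squared,
    r2adj = sm$adj.r.squared, loglik = ll,
    aic = stats::AIC(fit), bic = stats::BIC(fit),
    residuals = stats::residuals(fit), fitted = stats::fitted(fit),
    rss = sum(stats::residuals(fit)^2), n = n,
    df_model = length(predictors), df_resid = fit$df.residual,
    predictors = predictors, lambda = lambda, shift = shift,
    spec_name = spec_name, subject_id = subject_id,
    data = df, lm = fit), class = "tep_fit")
}

#' @export
print.tep_fit <- function(x, ...) {
  cat(sprintf("<tep_fit>%s n = %d, %d predictors\n",
              if (is.null(x$spec_name)) "" else paste0(" ", x$spec_name),
              x$n, x$df_model))
  if (!is.null(x$fstat))
    cat(sprintf("  F(%d, %d) = %.3g, p = %.3g, R2adj = %.3f\n",
                x$fstat$df1, x$fstat$df2, x$fstat$F, x$fstat$p, x$r2adj))
  cat(sprintf("  AIC = %.2f, BIC = %.2f, logLik = %.2f", x$aic, x$bic,
              x$loglik))
  if (!is.null(x$lambda))
    cat(sprintf(", Box-Cox lambda = %.3f", x$lambda))
  cat("\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Lilliefors normality test with Monte-Carlo p-value
#'
#' Kolmogorov-Smirnov statistic of the sample against a normal distribution
#' with mean and standard deviation estimated from the sample itself; the
#' p-value comes from a seeded Monte-Carlo null of the same sample size
#' (composite-null KS tables are not valid when parameters are estimated).
#' The statistic is invariant to affine rescaling of the input.
#'
#' @param x Numeric vector, n >= 5.
#' @param nsim Number of Monte-Carlo null samples (default 10000).
#' @param seed Seed for the null simulation.
#' @return List with `D`, `p`, `n`, `nsim`.
#' @export
lilliefors_test <- function(x, nsim = 10000, seed = 1L) {
  n <- length(x)
  if (n < 5L) stopf("need at least 5 observations")
  ks_d <- function(v) {
    z <- sort((v - mean(v)) / stats::sd(v))
    cdf <- stats::pnorm(z)
    i <- seq_len(length(v))
    max(i / length(v) - cdf, cdf - (i - 1) / length(v))
  }
  D <- ks_d(x)
  with_seed(seed, {
    d_null <- vapply(seq_len(nsim), function(b) ks_d(stats::rnorm(n)), 0)
    list(D = D, p = (sum(d_null >= D) + 1) / (nsim + 1), n = n, nsim = nsim)
  })
}

#' Likelihood ratio test between nested OLS fits
#'
#' For Gaussian OLS on the same response, `chi2 = 2 * (ll_full - ll_reduced)`
#' equals `n * log(RSS_reduced / RSS_full)`; the p-value is taken from the
#' chi-square distribution on `df = p_full - p_reduced` degrees of freedom.
#'
#' @param full,reduced `tep_fit` objects on the same subjects and response;
#'   the reduced model's predictors must be a subset of the full model's.
#' @return List with `chi2`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "tep_fit"), inherits(reduced, "tep_fit"))
  if (full$n != reduced$n)
    stopf("models fitted on different sample sizes (%d vs %d)", full$n,
          reduced$n)
  if (!all(reduced$predictors %in% full$predictors))
    stopf("models are not nested: reduced predictors must be a subset")
  if (max(abs(full$data$response - reduced$data$response)) > 1e-10)
    stopf("models were fitted on different response vectors")
  df <- full$df_model - reduced$df_model
  if (df < 0) stopf("full model must have at least as many predictors")
  chi2 <- 2 * (full$loglik - reduced$loglik)
  # identical predictor sets: the models coincide, chi2 = 0, p = 1
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Sequential (Type-I) variance decomposition
#'
#' Percentage of the total sum of squares explained by each predictor when
#' entered in the given order (successive RSS reductions), plus the residual
#' percentage; the percentages sum to 100.
#'
#' @param fit A `tep_fit`.
#' @param order Predictor names in entry order; default is the order they
#'   appear in the model.
#' @return Named numeric vector of percentages, ending with `Residuals`.
#' @export
anova_percent_variance <- function(fit, order = NULL) {
  stopifnot(inherits(fit, "tep_fit"))
  order <- order %||% fit$predictors
  if (!setequal(order, fit$predictors) ||
      length(order) != length(fit$predictors))
    stopf("order must be a permutation of the fitted predictors")
  fml <- stats::reformulate(order, response = "response")
  an <- stats::anova(stats::lm(fml, data = fit$data))
  ss <- an[["Sum Sq"]]
  pct <- 100 * ss / sum(ss)
  stats::setNames(pct, rownames(an))
}

#' Regression assumption diagnostics
#'
#' Variance inflation factors (multicollinearity; via auxiliary regressions
#' as implemented in `car::vif`), the Durbin-Watson statistic on the residual
#' sequence (autocorrelation), and the Breusch-Pagan test p-value
#' (heteroscedasticity).
#'
#' @param fit A `tep_fit`.
#' @return List with `vif` (named vector; all 1 for a single predictor),
#'   `durbin_watson`, `breusch_pagan_p`.
#' @export
ols_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "tep_fit"))
  vif <- if (fit$df_model >= 2L) car::vif(fit$lm)
         else stats::setNames(1, fit$predictors)
  dw <- unname(lmtest::dwtest(fit$lm)$statistic)
  bp <- unname(lmtest::bptest(fit$lm)$p.value)
  list(vif = vif, durbin_watson = dw, breusch_pagan_p = bp)
}

#' Fit the full regression model suite
#'
#' Runs the four models on a scored cohort, each on its own Box-Cox
#' transformed response: the full and reduced DLPFC models (reduced fitted on
#' the same subjects as the full, so the two are directly comparable), the
#' IPL control model, and the reduced model plus pre-stimulus baseline
#' activity. Reports the likelihood-ratio test of full vs reduced DLPFC,
#' AIC/BIC for both, the sequential variance decomposition of the reduced
#' model (reactivity entered before education), Lilliefors residual
#' normality and assumption diagnostics for every model.
#'
#' @param cohort Cohort data.frame.
#' @param scores Reactivity score data.frame.
#' @param models Model names to fit.
#' @param lilliefors_nsim Monte-Carlo samples for the residual normality
#'   test.
#' @param seed Seed for the normality test's null simulation.
#' @return Object of class `tep_report`: `fits`, `lrt`, `ic` (AIC/BIC
#'   table), `anova_pct`, `lilliefors`, `diagnostics`, `n_subjects`.
#' @export
run_model_suite <- function(cohort, scores,
                            models = c("full_dlpfc", "reduced_dlpfc",
                                       "full_ipl", "reduced_plus_baseline"),
                            lilliefors_nsim = 2000, seed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  fits <- list()
  designs <- list()
  for (m in models) {
    sp <- model_spec(m)
    des <- if (m %in% c("reduced_dlpfc", "reduced_plus_baseline") &&
               !is.null(designs$full_dlpfc)) {
      # same subjects as the full DLPFC model so nested comparisons are valid
      full_des <- designs$full_dlpfc
      merged <- build_design(cohort, scores, sp)
      keep <- merged$subject_id %in% full_des$subject_id
      list(data = merged$data[keep, , drop = FALSE], spec = sp,
           subject_id = merged$subject_id[keep],
           n_dropped = merged$n_dropped + sum(!keep))
    } else build_design(cohort, scores, sp)
    designs[[m]] <- des
    bc <- boxcox_fit(des$data$response)
    fits[[m]] <- fit_ols(des, response = bc$y, lambda = bc$lambda,
                         shift = bc$shift)
  }
  lrt <- if (all(c("full_dlpfc", "reduced_dlpfc") %in% models))
    likelihood_ratio_test(fits$full_dlpfc, fits$reduced_dlpfc) else NULL
  ic <- data.frame(model = names(fits),
                   n = vapply(fits, `[[`, 0, "n"),
                   aic = vapply(fits, `[[`, 0, "aic"),
                   bic = vapply(fits, `[[`, 0, "bic"),
                   r2adj = vapply(fits, `[[`, 0, "r2adj"),
                   lambda = vapply(fits, `[[`, 0, "lambda"),
                   stringsAsFactors = FALSE)
  anova_pct <- if ("reduced_dlpfc" %in% models)
    anova_percent_variance(fits$reduced_dlpfc,
                           order = c("local_auc", "education_years")) else NULL
  lil <- lapply(fits, function(f)
    lilliefors_test(f$residuals, nsim = lilliefors_nsim, seed = seed))
  diag <- lapply(fits, ols_diagnostics)
  structure(list(fits = fits, lrt = lrt, ic = ic, anova_pct = anova_pct,
                 lilliefors = lil, diagnostics = diag,
                 n_subjects = vapply(fits, `[[`, 0, "n")),
            class = "tep_report")
}

#' @export
print.tep_report <- function(x, ...) {
  cat("<tep_report>\n")
  print(x$ic, digits = 4, row.names = FALSE)
  if (!is.null(x$lrt))
    cat(sprintf("LRT full vs reduced DLPFC: chi2(%d) = %.3f, p = %.3g\n",
                x$lrt$df, x$lrt$chi2, x$lrt$p))
  if (!is.null(x$anova_pct)) {
    cat("Reduced-model variance decomposition (%):\n")
    print(round(x$anova_pct, 2))
  }
  invisible(x)
}
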
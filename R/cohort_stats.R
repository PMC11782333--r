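# Cohort-level statistics on visit records. A visit record is one row per
# patient-visit with the acoustic features (hlpr, max_peak_amplitude) and,
# when available, osi_area_percent and the ultrasound BFVs. Quantiles
# everywhere use linear interpolation between order statistics (R type 7).

#' Canonical follow-up visit order
#'
#' Visits in the follow-up schedule are ordered 3 days < 3 weeks <
#' 3 months < 6 months < 9 months < 1 year, regardless of file order.
#' @export
VISIT_LEVELS <- c("3d", "3w", "3m", "6m", "9m", "1y")

#' Median-split subgroup comparison of HLPR by high-OSI area
#'
#' Splits visit records at the overall median of `osi_area_percent`
#' (linear-interpolation quantile): records strictly above the threshold
#' form the extensive-high-OSI subgroup, the rest the limited subgroup.
#' Reports per-group HLPR medians and interquartile ranges (same quantile
#' convention) and a two-sample t-test on HLPR between the groups.
#'
#' @param records `data.frame` with at least `hlpr` and
#'   `osi_area_percent`; rows missing either are dropped (>= 4 must
#'   remain).
#' @param var_equal Pooled-variance Student t-test when `TRUE` (default);
#'   `FALSE` gives Welch.
#' @return A `subgroup_comparison`: list with `threshold`, `high`/`low`
#'   (each: `records`, `n`, `median`, `q1`, `q3`), `t_statistic`,
#'   `p_value`.
#' @export
median_split_comparison <- function(records, var_equal = TRUE) {
  keep <- !is.na(records$hlpr) & !is.na(records$osi_area_percent)
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(n_drop, " record(s) without both HLPR and OSI area dropped")
  records <- records[keep, , drop = FALSE]
  if (nrow(records) < 4)
    stop("need at least 4 records with both hlpr and osi_area_percent")
  threshold <- unname(stats::quantile(records$osi_area_percent, 0.5, type = 7))
  hi <- records[records$osi_area_percent > threshold, , drop = FALSE]
  lo <- records[records$osi_area_percent <= threshold, , drop = FALSE]
  if (nrow(hi) == 0 || nrow(lo) == 0)
    stop("median split left a subgroup empty")
  summ <- function(g) {
    q <- unname(stats::quantile(g$hlpr, c(0.25, 0.5, 0.75), type = 7))
    list(records = g, n = nrow(g), median = q[2], q1 = q[1], q3 = q[3])
  }
  tt <- stats::t.test(hi$hlpr, lo$hlpr, var.equal = var_equal)
  structure(list(threshold = threshold,
                 high = summ(hi), low = summ(lo),
                 t_statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 var_equal = var_equal),
            class = "subgroup_comparison")
}

#' @export
print.subgroup_comparison <- function(x, ...) {
  cat(sprintf("Median split at %%area OSI > 0.1 = %.2f\n", x$threshold))
  cat(sprintf("  extensive (n=%d): HLPR median %.2f [%.2f-%.2f]\n",
              x$high$n, x$high$median, x$high$q1, x$high$q3))
  cat(sprintf("  limited   (n=%d): HLPR median %.2f [%.2f-%.2f]\n",
              x$low$n, x$low$median, x$low$q1, x$low$q3))
  cat(sprintf("  %s t-test: t = %.3f, p = %.4f\n",
              if (x$var_equal) "Student" else "Welch", x$t_statistic, x$p_value))
  invisible(x)
}

#' Random-intercept mixed model with cluster-bootstrap CI on the slope
#'
#' Fits `y = b0 + b1 x + u_patient + e` with a normally distributed
#' per-patient random intercept, by REML (`lme4`). The 95% confidence
#' interval on the slope comes from a case-resampling bootstrap over
#' patients (clusters resampled with replacement, model refit, percentile
#' interval). The slope p-value uses the Satterthwaite approximation
#' (`lmerTest`). When every patient contributes a single observation the
#' random intercept is unidentifiable and the fit degenerates to ordinary
#' least squares (patient sd reported as 0). A singular fit (zero
#' between-patient variance) is reported, not raised.
#'
#' @param y,x Numeric outcome and predictor per record.
#' @param groups Patient identifiers per record.
#' @param n_boot Bootstrap replicates, default 1000.
#' @param seed Integer seed for the bootstrap (required for
#'   reproducibility).
#' @param conf Confidence level, default 0.95.
#' @return A `mixed_model_fit`: list with `slope`, `intercept`,
#'   `p_value_slope`, `patient_intercept_sd`, `residual_sd`, `ci_low`,
#'   `ci_high`, `boot_slopes`, `n_obs`, `n_patients`.
#' @export
fit_random_intercept_model <- function(y, x, groups, n_boot = 1000, seed,
                                       conf = 0.95) {
  stopifnot(length(y) == length(x), length(y) == length(groups))
  ok <- !is.na(y) & !is.na(x) & !is.na(groups)
  d <- data.frame(y = y[ok], x = x[ok], g = factor(groups[ok]))
  if (nlevels(d$g) < 2) stop("need at least 2 patients")
  fit0 <- .ri_fit(d)
  set.seed(seed)
  sp <- split(seq_len(nrow(d)), d$g)
  boot_slopes <- vapply(seq_len(n_boot), function(b) {
    ids <- sample(names(sp), replace = TRUE)
    rows <- unlist(sp[ids], use.names = FALSE)
    dd <- data.frame(y = d$y[rows], x = d$x[rows],
                     g = factor(rep(seq_along(ids), lengths(sp[ids]))))
    fb <- tryCatch(.ri_fit(dd, pvalue = FALSE), error = function(e) NULL)
    if (is.null(fb)) NA_real_ else fb$slope
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot_slopes, c(alpha, 1 - alpha),
                               na.rm = TRUE, type = 7))
  structure(c(fit0,
              list(ci_low = ci[1], ci_high = ci[2],
                   boot_slopes = boot_slopes,
                   n_obs = nrow(d), n_patients = nlevels(d$g))),
            class = "mixed_model_fit")
}

# Single random-intercept fit; OLS fallback when the random intercept is
# unidentifiable (one observation per cluster).
.ri_fit <- function(d, pvalue = TRUE) {
  if (max(table(d$g)) < 2 || nlevels(d$g) >= nrow(d)) {
    f <- stats::lm(y ~ x, data = d)
    co <- stats::coef(f)
    return(list(slope = unname(co[2]), intercept = unname(co[1]),
                p_value_slope =
                  if (pvalue) summary(f)$coefficients[2, 4] else NA_real_,
                patient_intercept_sd = 0,
                residual_sd = summary(f)$sigma))
  }
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit <- suppressMessages(
    lme4::lmer(y ~ x + (1 | g), data = d, REML = TRUE, control = ctrl))
  vc <- as.data.frame(lme4::VarCorr(fit))
  p <- NA_real_
  if (pvalue) {
    ft <- suppressMessages(
      lmerTest::lmer(y ~ x + (1 | g), data = d, REML = TRUE))
    p <- stats::coef(summary(ft))["x", "Pr(>|t|)"]
  }
  fe <- lme4::fixef(fit)
  list(slope = unname(fe["x"]), intercept = unname(fe["(Intercept)"]),
       p_value_slope = p,
       patient_intercept_sd = vc$sdcor[vc$grp == "g"],
       residual_sd = vc$sdcor[vc$grp == "Residual"])
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("Random-intercept model (%d obs, %d patients)\n",
              x$n_obs, x$n_patients))
  cat(sprintf("  slope %.4g [bootstrap 95%% CI %.4g, %.4g], p = %.3g\n",
              x$slope, x$ci_low, x$ci_high, x$p_value_slope))
  cat(sprintf("  patient intercept sd %.4g, residual sd %.4g\n",
              x$patient_intercept_sd, x$residual_sd))
  invisible(x)
}

#' Consecutive-visit changes per patient
#'
#' Orders each patient's visits by the canonical schedule and returns one
#' row per consecutive pair of attended visits with both quantities
#' present; deltas are later minus earlier. Patients with fewer than two
#' usable visits contribute no rows.
#'
#' @param records `data.frame` with `patient_id`, `visit` (levels of
#'   [VISIT_LEVELS]), `hlpr` and `brachial_bfv_ml_min`.
#' @return `data.frame` with `patient_id`, `visit_from`, `visit_to`,
#'   `delta_bfv`, `delta_hlpr`.
#' @export
longitudinal_deltas <- function(records) {
  stopifnot(all(records$visit %in% VISIT_LEVELS))
  out <- lapply(split(records, records$patient_id), function(g) {
    g <- g[order(match(g$visit, VISIT_LEVELS)), , drop = FALSE]
    if (anyDuplicated(g$visit)) stop("duplicate visit for patient ",
                                     g$patient_id[1])
    ok <- !is.na(g$hlpr) & !is.na(g$brachial_bfv_ml_min)
    g <- g[ok, , drop = FALSE]
    if (nrow(g) < 2) return(NULL)
    i <- seq_len(nrow(g) - 1)
    data.frame(patient_id = g$patient_id[i],
               visit_from = g$visit[i], visit_to = g$visit[i + 1],
               delta_bfv = diff(g$brachial_bfv_ml_min),
               delta_hlpr = diff(g$hlpr))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(patient_id = character(), visit_from = character(),
                      visit_to = character(), delta_bfv = numeric(),
                      delta_hlpr = numeric())
  rownames(out) <- NULL
  out
}

#' Inter-operator agreement for paired HLPR series
#'
#' Pearson correlation with a Fisher-z 95% confidence interval,
#' Shapiro-Wilk normality checks on each series, and Bland-Altman
#' statistics (mean difference and mean +/- 1.96 sd limits of agreement,
#' differences taken as `x - y`).
#'
#' @param x,y Paired HLPR series (e.g. expert and novice operator),
#'   equal length, n >= 3, each with non-zero variance.
#' @return An `agreement_result`: list with `pearson_r`, `r_ci_low`,
#'   `r_ci_high`, `p_value`, `shapiro_p_x`, `shapiro_p_y`,
#'   `mean_difference`, `loa_low`, `loa_high`, `differences`.
#' @export
operator_agreement <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the series")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  n <- length(x)
  z <- atanh(r); se <- 1 / sqrt(n - 3)
  d <- x - y
  sdd <- stats::sd(d)
  structure(list(pearson_r = r,
                 r_ci_low = tanh(z - 1.96 * se),
                 r_ci_high = tanh(z + 1.96 * se),
                 p_value = ct$p.value,
                 shapiro_p_x = stats::shapiro.test(x)$p.value,
                 shapiro_p_y = stats::shapiro.test(y)$p.value,
                 mean_difference = mean(d),
                 loa_low = mean(d) - 1.96 * sdd,
                 loa_high = mean(d) + 1.96 * sdd,
                 differences = d),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Pearson R = %.3f [%.3f, %.3f], p = %.3g\n",
              x$pearson_r, x$r_ci_low, x$r_ci_high, x$p_value))
  cat(sprintf("Bland-Altman: mean diff %.4g, limits [%.4g, %.4g]\n",
              x$mean_difference, x$loa_low, x$loa_high))
  invisible(x)
}

#' Slope-recovery simulation for the random-intercept bootstrap CI
#'
#' Validation experiment for [fit_random_intercept_model()]: repeatedly
#' generates cohorts with known slope and the reference variance
#' components (between-patient sd 14.97, residual sd 31.05), fits the
#' model, and records whether the cluster-bootstrap 95% percentile CI
#' covers the generating slope. Cohorts are simulated with 20 patients by
#' default: percentile cluster-bootstrap intervals only reach near-nominal
#' coverage once the number of clusters is moderately large, so the
#' method check is run where its asymptotics apply (see the methods
#' vignette for the few-cluster caveat).
#'
#' @param n_replicates Simulated cohorts, default 100.
#' @param slopes Known slopes cycled over the replicates.
#' @param n_patients,visits_per_patient Cohort shape per replicate.
#' @param patient_sd,residual_sd Generating variance components.
#' @param n_boot Bootstrap replicates per fit, default 200.
#' @param seed Integer seed for the whole experiment.
#' @return List with `coverage_count`, `n_replicates`, `coverage`
#'   (fraction), and the per-replicate `data.frame` `details`
#'   (true slope, estimate, CI bounds, covered).
#' @export
slope_recovery_simulation <- function(n_replicates = 100,
                                      slopes = c(0.103, 0.05, 0.25),
                                      n_patients = 20,
                                      visits_per_patient = 6,
                                      patient_sd = 14.97,
                                      residual_sd = 31.05,
                                      n_boot = 200, seed) {
  set.seed(seed)
  sub_seeds <- sample.int(2^31 - 1, 2 * n_replicates)
  rows <- lapply(seq_len(n_replicates), function(r) {
    beta <- slopes[(r - 1) %% length(slopes) + 1]
    co <- gen_cohort(n_patients = n_patients,
                     visits_per_patient = visits_per_patient,
                     true_slope = beta, patient_sd = patient_sd,
                     residual_sd = residual_sd, seed = sub_seeds[2 * r - 1])
    fit <- fit_random_intercept_model(co$records$max_peak_amplitude,
                                      co$records$brachial_bfv_ml_min,
                                      co$records$patient_id,
                                      n_boot = n_boot,
                                      seed = sub_seeds[2 * r])
    data.frame(true_slope = beta, estimate = fit$slope,
               ci_low = fit$ci_low, ci_high = fit$ci_high,
               covered = fit$ci_low <= beta & beta <= fit$ci_high)
  })
  details <- do.call(rbind, rows)
  list(coverage_count = sum(details$covered),
       n_replicates = n_replicates,
       coverage = mean(details$covered),
       details = details)
}
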
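# Method-agreement statistics battery: paired t + Cohen's d, two-way mixed
# ICC (single and average; consistency or absolute-agreement) with 95% CIs,
# SEM, CV% with chi-square CI, minimal detectable change, Bland-Altman
# limits of agreement, and a Shapiro-Wilk normality gate.

#' Build a paired sample of one F-v parameter under two methods
#'
#' Subjects with a missing value under either method are removed pairwise
#' (the dropped count is recorded); order must match across methods.
#'
#' @param reference Values under the reference method (e.g. 9-point linear).
#' @param candidate Values under the comparator, same subjects, same order.
#' @param parameter_label Optional label (`"F0"`, `"v0"`, `"Sfv"`, `"Pmax"`).
#' @return List of class `paired_sample` with `reference`, `candidate`, `n`,
#'   `n_dropped`, `parameter_label`.
#' @export
paired_sample <- function(reference, candidate, parameter_label = NA_character_) {
  if (length(reference) != length(candidate)) {
    abort_isofv("reference and candidate must have equal length", "isofv_error_precondition")
  }
  keep <- is.finite(reference) & is.finite(candidate)
  n_dropped <- sum(!keep)
  reference <- reference[keep]
  candidate <- candidate[keep]
  if (length(reference) < 3L) {
    abort_isofv("need at least 3 complete pairs", "isofv_error_insufficient_sample")
  }
  structure(
    list(reference = reference, candidate = candidate, n = length(reference),
         n_dropped = n_dropped, parameter_label = parameter_label),
    class = "paired_sample"
  )
}

as_paired <- function(reference, candidate = NULL, parameter_label = NA_character_) {
  if (inherits(reference, "paired_sample")) return(reference)
  paired_sample(reference, candidate, parameter_label)
}

#' Paired comparison: bias, t-test and Cohen's d
#'
#' Differences are taken as reference minus candidate. Cohen's d for the
#' paired design is the mean difference divided by the SD of the
#' differences. With zero-variance differences the t statistic degenerates:
#' all-zero differences give t = 0, p = 1; a constant nonzero difference
#' gives signed infinity with p = 0.
#'
#' @param reference Reference values or a [paired_sample()].
#' @param candidate Comparator values (ignored if `reference` is a
#'   `paired_sample`).
#' @param parameter_label Optional label.
#' @return List: `bias`, `sd_bias`, `t`, `p`, `df`, `effect_size`, `n`.
#' @export
paired_comparison <- function(reference, candidate = NULL, parameter_label = NA_character_) {
  s <- as_paired(reference, candidate, parameter_label)
  d <- s$reference - s$candidate
  bias <- mean(d)
  sd_bias <- stats::sd(d)
  df <- s$n - 1L
  # differences at floating-point noise level are treated as exact zeros so
  # that analytically identical methods compare as identical
  eps <- 1e-10 * max(abs(c(s$reference, s$candidate)), 1)
  if (sd_bias <= eps) {
    sd_bias <- 0
    if (abs(bias) <= eps) bias <- 0
  }
  if (sd_bias == 0) {
    if (bias == 0) {
      t <- 0; p <- 1; es <- 0
    } else {
      t <- sign(bias) * Inf; p <- 0; es <- sign(bias) * Inf
    }
  } else {
    t <- bias / (sd_bias / sqrt(s$n))
    p <- 2 * stats::pt(-abs(t), df)
    es <- bias / sd_bias
  }
  list(bias = bias, sd_bias = sd_bias, t = t, p = p, df = df,
       effect_size = es, n = s$n)
}

# Two-way (subjects x methods) ANOVA mean squares computed from explicit
# sums of squares; the oracle test re-derives these via stats::aov.
two_way_mean_squares <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  g <- mean(mat)
  rm <- rowMeans(mat); cm <- colMeans(mat)
  msr <- k * sum((rm - g)^2) / (n - 1)
  msc <- n * sum((cm - g)^2) / (k - 1)
  resid <- mat - outer(rm, rep(1, k)) - outer(rep(1, n), cm) + g
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  list(msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' Two-way mixed intraclass correlation with 95% confidence interval
#'
#' Shrout-Fleiss / McGraw-Wong two-way mixed-effects ICC for a subjects x
#' methods table (here k = 2 methods). `form = "single"` rates a single
#' method's measurement, `form = "average"` the average of the k methods.
#' `definition = "consistency"` (ICC(3,1)/ICC(3,k); insensitive to a fixed
#' offset between methods) or `"agreement"` (absolute agreement; an offset
#' lowers it). Confidence intervals follow the F-distribution method; the
#' absolute-agreement interval uses the McGraw-Wong approximation for the
#' single form and a Spearman-Brown step-up of those bounds for the average
#' form.
#'
#' @param reference,candidate The two methods' values, or a
#'   [paired_sample()] as first argument.
#' @param form `"single"` or `"average"`.
#' @param definition `"consistency"` (default) or `"agreement"`.
#' @param conf Confidence level (default 0.95).
#' @return List: `estimate`, `lower`, `upper`, `form`, `definition`.
#' @export
icc_two_way <- function(reference, candidate = NULL,
                        form = c("single", "average"),
                        definition = c("consistency", "agreement"),
                        conf = 0.95) {
  form <- match.arg(form)
  definition <- match.arg(definition)
  s <- as_paired(reference, candidate)
  if (s$n < 5L) {
    warn_isofv(sprintf("ICC confidence interval is unstable for n = %d (< 5)", s$n),
               "isofv_warning_small_sample")
  }
  ms <- two_way_mean_squares(cbind(s$reference, s$candidate))
  n <- ms$n; k <- ms$k
  if (ms$msr <= .Machine$double.eps * max(1, abs(mean(s$reference)))^2) {
    abort_isofv("zero between-subject variance: ICC undefined", "isofv_error_icc_undefined")
  }
  alpha <- 1 - conf
  # Zero residual variance: perfect consistency (and, if the methods also
  # coincide, perfect agreement). The F-based interval collapses onto the
  # point estimate; the absolute-agreement formulas below remain valid when
  # only the method effect is nonzero.
  if (ms$mse == 0 && (definition == "consistency" || ms$msc == 0)) {
    return(list(estimate = 1, lower = 1, upper = 1,
                form = form, definition = definition))
  }
  if (definition == "consistency") {
    fobs <- ms$msr / ms$mse
    fl <- fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    if (form == "single") {
      est <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
      lower <- (fl - 1) / (fl + k - 1)
      upper <- (fu - 1) / (fu + k - 1)
    } else {
      est <- (ms$msr - ms$mse) / ms$msr
      lower <- 1 - 1 / fl
      upper <- 1 - 1 / fu
    }
  } else {
    est1 <- (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
    a <- (k * est1) / (n * (1 - est1))
    b <- 1 + (k * est1 * (n - 1)) / (n * (1 - est1))
    v <- (a * ms$msc + b * ms$mse)^2 /
      ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
    f1 <- stats::qf(1 - alpha / 2, n - 1, v)
    f2 <- stats::qf(1 - alpha / 2, v, n - 1)
    lower1 <- n * (ms$msr - f1 * ms$mse) /
      (f1 * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    upper1 <- n * (f2 * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * f2 * ms$msr)
    sb <- function(x) k * x / (1 + (k - 1) * x)
    if (form == "single") {
      est <- est1; lower <- lower1; upper <- upper1
    } else {
      est <- sb(est1); lower <- sb(lower1); upper <- sb(upper1)
    }
  }
  list(estimate = est, lower = lower, upper = upper,
       form = form, definition = definition)
}

#' Standard error of measurement and coefficient of variation
#'
#' SEM is taken as the SD of the between-method differences divided by
#' sqrt(2) (the within-subject SD of a two-trial design); CV% = 100 x SEM /
#' |grand mean| where the grand mean averages the two method means. The CV
#' confidence interval uses chi-square scaling with n - 1 degrees of
#' freedom. `sem_n` (sd_bias / sqrt(n), the SE of the mean difference) is
#' also reported for completeness; CV and MDC are built on `sem`.
#'
#' @inheritParams paired_comparison
#' @param conf Confidence level for the CV interval (default 0.95).
#' @return List: `sem`, `sem_n`, `cv_percent`, `cv_lower`, `cv_upper`, `n`.
#' @export
sem_cv <- function(reference, candidate = NULL, parameter_label = NA_character_,
                   conf = 0.95) {
  s <- as_paired(reference, candidate, parameter_label)
  d <- s$reference - s$candidate
  sd_bias <- stats::sd(d)
  if (sd_bias <= 1e-10 * max(abs(c(s$reference, s$candidate)), 1)) sd_bias <- 0
  grand <- (mean(s$reference) + mean(s$candidate)) / 2
  if (abs(grand) < 1e-9) {
    abort_isofv("grand mean is (near) zero: CV undefined", "isofv_error_cv_undefined")
  }
  sem <- sd_bias / sqrt(2)
  cv <- 100 * sem / abs(grand)
  df <- s$n - 1L
  alpha <- 1 - conf
  lo <- cv * sqrt(df / stats::qchisq(1 - alpha / 2, df))
  hi <- cv * sqrt(df / stats::qchisq(alpha / 2, df))
  list(sem = sem, sem_n = sd_bias / sqrt(s$n),
       cv_percent = cv, cv_lower = lo, cv_upper = hi, n = s$n)
}

#' Minimal detectable change
#'
#' `MDC = 1.96 * sqrt(2) * SEM`: the smallest change exceeding measurement
#' noise with 95% confidence.
#'
#' @param sem Standard error of measurement (>= 0).
#' @return MDC in the same units.
#' @export
mdc <- function(sem) {
  if (any(sem < 0)) abort_isofv("sem must be >= 0", "isofv_error_precondition")
  1.96 * sqrt(2) * sem
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' @inheritParams paired_comparison
#' @return List: `bias`, `sd_bias`, `loa_lower`, `loa_upper`, and `pairs`
#'   (data.frame of per-subject mean and difference, for plotting).
#' @export
bland_altman <- function(reference, candidate = NULL, parameter_label = NA_character_) {
  s <- as_paired(reference, candidate, parameter_label)
  d <- s$reference - s$candidate
  bias <- mean(d)
  sd_bias <- stats::sd(d)
  list(bias = bias, sd_bias = sd_bias,
       loa_lower = bias - 1.96 * sd_bias,
       loa_upper = bias + 1.96 * sd_bias,
       pairs = data.frame(mean = (s$reference + s$candidate) / 2, difference = d))
}

#' Shapiro-Wilk normality gate
#'
#' Standard Shapiro-Wilk test with a pass flag at alpha = 0.05. Used to
#' decide whether raw values can be analysed parametrically; per-subject
#' correlation coefficients that fail the gate are Fisher z-transformed
#' before testing.
#'
#' @param values Numeric sample, 3 to 5000 values with nonzero variance.
#' @param alpha Significance level for the pass flag (default 0.05).
#' @return List of class `normality_result`: `statistic`, `p_value`, `passed`.
#' @export
shapiro_gate <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 3L || length(values) > 5000L) {
    abort_isofv("Shapiro-Wilk requires 3 to 5000 finite values",
                "isofv_error_insufficient_sample")
  }
  if (stats::sd(values) == 0) {
    abort_isofv("sample is constant: Shapiro-Wilk W undefined",
                "isofv_error_insufficient_variation")
  }
  sw <- stats::shapiro.test(values)
  structure(
    list(statistic = unname(sw$statistic), p_value = sw$p.value,
         passed = sw$p.value > alpha),
    class = "normality_result"
  )
}

#' Full agreement report for one parameter under two methods
#'
#' Assembles the complete battery: method means/SDs, bias with paired t and
#' Cohen's d, single and average two-way mixed ICC with 95% CIs, SEM, CV%
#' with chi-square CI, MDC and Bland-Altman limits.
#'
#' @inheritParams paired_comparison
#' @param icc_definition `"consistency"` (default) or `"agreement"`.
#' @return List of class `agreement_report`.
#' @export
agreement_report <- function(reference, candidate = NULL,
                             parameter_label = NA_character_,
                             icc_definition = c("consistency", "agreement")) {
  icc_definition <- match.arg(icc_definition)
  s <- as_paired(reference, candidate, parameter_label)
  pc <- paired_comparison(s)
  iccs <- icc_two_way(s, form = "single", definition = icc_definition)
  icca <- icc_two_way(s, form = "average", definition = icc_definition)
  sc <- sem_cv(s)
  ba <- bland_altman(s)
  structure(
    list(parameter_label = s$parameter_label, n = s$n, n_dropped = s$n_dropped,
         mean_ref = mean(s$reference), sd_ref = stats::sd(s$reference),
         mean_cand = mean(s$candidate), sd_cand = stats::sd(s$candidate),
         bias = pc$bias, sd_bias = pc$sd_bias, t_statistic = pc$t,
         p_value = pc$p, df = pc$df, effect_size = pc$effect_size,
         icc_single = iccs$estimate, icc_single_ci = c(iccs$lower, iccs$upper),
         icc_average = icca$estimate, icc_average_ci = c(icca$lower, icca$upper),
         icc_definition = icc_definition,
         sem = sc$sem, sem_n = sc$sem_n,
         cv_percent = sc$cv_percent, cv_ci = c(sc$cv_lower, sc$cv_upper),
         mdc = mdc(sc$sem),
         loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
         bland_altman_pairs = ba$pairs),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %s (n = %d%s)\n",
              if (is.na(x$parameter_label)) "parameter" else x$parameter_label,
              x$n, if (x$n_dropped) sprintf(", %d dropped", x$n_dropped) else ""))
  cat(sprintf("  ref %.3f (%.3f) vs cand %.3f (%.3f)\n",
              x$mean_ref, x$sd_ref, x$mean_cand, x$sd_cand))
  cat(sprintf("  bias %.3f (%.3f), t(%d) = %.2f, p = %.3f, d = %.2f\n",
              x$bias, x$sd_bias, x$df, x$t_statistic, x$p_value, x$effect_size))
  cat(sprintf("  ICCs %.3f (%.3f-%.3f), ICCa %.3f (%.3f-%.3f) [%s]\n",
              x$icc_single, x$icc_single_ci[1], x$icc_single_ci[2],
              x$icc_average, x$icc_average_ci[1], x$icc_average_ci[2],
              x$icc_definition))
  cat(sprintf("  SEM %.3f, CV %.2f%% (%.2f-%.2f), MDC %.3f, LoA (%.3f, %.3f)\n",
              x$sem, x$cv_percent, x$cv_ci[1], x$cv_ci[2], x$mdc,
              x$loa_lower, x$loa_upper))
  invisible(x)
}
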
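# Agreement battery: paired t / Cohen's d, ICC with CI (vs an independent
# aov-based oracle), SEM / CV% with chi-square CI, MDC and Bland-Altman.
# Published-table worked examples are reconstructed from their printed
# summary statistics via moment-exact samples, so every value is computed
# through the package path.

test_that("paired comparison reproduces printed t statistics from summaries", {
  # mean diff -0.2, SD 0.44, n 22  ->  t = -2.13
  d <- moment_sample(22, -0.2, 0.44)
  pc <- paired_comparison(d, rep(0, 22))
  expect_equal(round(pc$t, 2), -2.13)
  expect_equal(pc$df, 21)

  # mean diff -0.54, SD 0.75, n 22  ->  t = -3.38
  pc2 <- paired_comparison(moment_sample(22, -0.54, 0.75), rep(0, 22))
  expect_equal(round(pc2$t, 2), -3.38)

  # mean diff -0.46, SD 0.41, n 22  ->  t = -5.26, d = -1.12
  pc3 <- paired_comparison(moment_sample(22, -0.46, 0.41), rep(0, 22))
  expect_equal(round(pc3$t, 2), -5.26)
  expect_equal(round(pc3$effect_size, 2), -1.12)
})

test_that("paired comparison degenerate and identity cases", {
  x <- moment_sample(10, 5, 1)
  id <- paired_comparison(x, x)
  expect_equal(id$bias, 0)
  expect_equal(id$t, 0)
  expect_equal(id$p, 1)

  const <- paired_comparison(x + 2, x)
  expect_equal(const$t, Inf)
  expect_equal(const$p, 0)

  expect_error(paired_comparison(1:2, 2:3), class = "isofv_error_insufficient_sample")
})

test_that("t, bias and effect size are antisymmetric under method swap", {
  withr::with_seed(14, {
    a <- rnorm(22, 20, 3); b <- a + rnorm(22, 0.4, 1)
  })
  f <- paired_comparison(a, b)
  g <- paired_comparison(b, a)
  expect_equal(f$bias, -g$bias)
  expect_equal(f$t, -g$t)
  expect_equal(f$effect_size, -g$effect_size)
  expect_equal(f$p, g$p)
})

test_that("ICC matches a brute-force aov decomposition on random tables", {
  icc_oracle <- function(x, y) {
    # independent route: stats::aov two-way decomposition
    dat <- data.frame(score = c(x, y),
                      subject = factor(rep(seq_along(x), 2)),
                      method = factor(rep(1:2, each = length(x))))
    ms <- summary(stats::aov(score ~ subject + method, data = dat))[[1]][, "Mean Sq"]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    n <- length(x); k <- 2
    c(cons_single = (msr - mse) / (msr + (k - 1) * mse),
      cons_avg = (msr - mse) / msr,
      agr_single = (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)))
  }
  withr::with_seed(23, {
    for (i in 1:100) {
      x <- rnorm(6, 20, 4)
      y <- x + rnorm(6, 0.5, 1.2)
      o <- icc_oracle(x, y)
      expect_equal(suppressWarnings(icc_two_way(x, y, "single"))$estimate,
                   unname(o["cons_single"]), tolerance = 1e-10)
      expect_equal(suppressWarnings(icc_two_way(x, y, "average"))$estimate,
                   unname(o["cons_avg"]), tolerance = 1e-10)
      expect_equal(suppressWarnings(icc_two_way(x, y, "single", "agreement"))$estimate,
                   unname(o["agr_single"]), tolerance = 1e-10)
    }
  })
})

test_that("ICC offset behaviour separates consistency from agreement", {
  withr::with_seed(8, x <- rnorm(22, 20, 4))
  y <- x + 3
  cons <- icc_two_way(x, y, "single", "consistency")
  agr <- icc_two_way(x, y, "single", "agreement")
  expect_equal(cons$estimate, 1)
  expect_lt(agr$estimate, 1)

  idn <- icc_two_way(x, x, "single", "consistency")
  expect_equal(idn$estimate, 1)
  expect_equal(icc_two_way(x, x, "average", "agreement")$estimate, 1)

  expect_error(icc_two_way(rep(3, 8), rep(3, 8)), class = "isofv_error_icc_undefined")
})

test_that("ICC confidence intervals contain the estimate and behave sanely", {
  withr::with_seed(99, {
    for (i in 1:25) {
      x <- rnorm(22, 20, 4)
      y <- x + rnorm(22, 0, 1)
      for (form in c("single", "average")) {
        for (def in c("consistency", "agreement")) {
          r <- icc_two_way(x, y, form, def)
          expect_lte(r$lower, r$estimate + 1e-12)
          expect_gte(r$upper, r$estimate - 1e-12)
          expect_lte(r$upper, 1)
        }
      }
    }
  })
})

test_that("SEM and CV reproduce the printed worked examples", {
  # means 15.01 / 15.27, sd of differences 0.63, n 22 -> CV = 2.94%
  ref <- moment_sample(22, 15.01, 2.35)
  cand <- ref - moment_sample(22, 15.01 - 15.27, 0.63)
  sc <- sem_cv(ref, cand)
  expect_equal(round(sc$cv_percent, 2), 2.94)

  # means 27.98 / 28.13, sd of differences 1.72, n 22 -> CV = 4.33%
  ref2 <- moment_sample(22, 27.98, 3.28)
  cand2 <- ref2 - moment_sample(22, 27.98 - 28.13, 1.72)
  sc2 <- sem_cv(ref2, cand2)
  # printed value 4.33 was computed from unrounded data; the summary-level
  # reconstruction lands within one unit in the last printed digit
  expect_equal(sc2$cv_percent, 4.33, tolerance = 0.005)
  expect_equal(sc2$sem, 1.72 / sqrt(2), tolerance = 1e-12)
  expect_equal(sc2$sem_n, 1.72 / sqrt(22), tolerance = 1e-12)

  # zero differences: sem and cv collapse to zero
  sc3 <- sem_cv(ref, ref)
  expect_equal(sc3$sem, 0)
  expect_equal(sc3$cv_percent, 0)

  expect_error(sem_cv(moment_sample(10, 0, 1), moment_sample(10, 0, 1)),
               class = "isofv_error_cv_undefined")
})

test_that("CV chi-square interval has the fixed n = 22 ratio structure", {
  lo_ratio <- sqrt(21 / qchisq(0.975, 21))
  hi_ratio <- sqrt(21 / qchisq(0.025, 21))
  expect_equal(round(lo_ratio, 4), 0.7694, tolerance = 1e-4)
  expect_equal(round(hi_ratio, 4), 1.4291, tolerance = 1e-4)
  ref <- moment_sample(22, 22.25, 5.33)
  cand <- ref - moment_sample(22, 0.25, 1.03)
  sc <- sem_cv(ref, cand)
  expect_equal(sc$cv_lower / sc$cv_percent, lo_ratio, tolerance = 1e-12)
  expect_equal(sc$cv_upper / sc$cv_percent, hi_ratio, tolerance = 1e-12)
  # reproduces the printed 2.54 -> 1.95 lower bound
  expect_equal(round(2.54 * lo_ratio, 2), 1.95)
})

test_that("MDC is 1.96*sqrt(2)*SEM", {
  expect_equal(round(mdc(0.17), 2), 0.47)
  expect_equal(round(mdc(0.04), 2), 0.11)
  expect_equal(mdc(0), 0)
  sems <- c(0.01, 0.3, 2.7)
  expect_equal(mdc(sems) / sems, rep(1.96 * sqrt(2), 3))
  expect_error(mdc(-1), class = "isofv_error_precondition")
})

test_that("Bland-Altman limits match the closed form and nominal coverage", {
  # bias -0.35, sd 1.42 -> limits (-3.13, 2.43)
  ref <- moment_sample(22, 27.98, 3.28)
  cand <- ref - moment_sample(22, -0.35, 1.42)
  ba <- bland_altman(ref, cand)
  expect_equal(round(ba$loa_lower, 2), -3.13)
  expect_equal(round(ba$loa_upper, 2), 2.43)
  expect_equal(nrow(ba$pairs), 22)

  idn <- bland_altman(ref, ref)
  expect_equal(idn$bias, 0)
  expect_equal(idn$loa_lower, 0)
  expect_equal(idn$loa_upper, 0)

  withr::with_seed(101, {
    d <- rnorm(10000)
    ba2 <- bland_altman(d, rep(0, 10000))
    cover <- mean(d > ba2$loa_lower & d < ba2$loa_upper)
  })
  expect_lt(abs(cover - 0.95), 0.01)
})

test_that("Shapiro gate: size under normality, power under skew, degenerate input", {
  withr::with_seed(55, {
    pass_norm <- mean(replicate(1000, shapiro_gate(rnorm(22))$passed))
    reject_exp <- mean(!replicate(1000, shapiro_gate(rexp(22))$passed))
  })
  expect_gt(pass_norm, 0.92)
  expect_lt(pass_norm, 0.98)
  expect_gt(reject_exp, 0.30)

  expect_error(shapiro_gate(rep(2, 10)), class = "isofv_error_insufficient_variation")
  expect_error(shapiro_gate(c(1, 2)), class = "isofv_error_insufficient_sample")
})

test_that("agreement_report assembles a consistent battery", {
  withr::with_seed(77, {
    ref <- rnorm(22, 28, 3.3)
    cand <- ref + rnorm(22, -0.3, 1.4)
  })
  rep_ <- agreement_report(ref, cand, parameter_label = "F0")
  expect_s3_class(rep_, "agreement_report")
  expect_equal(rep_$loa_lower, rep_$bias - 1.96 * rep_$sd_bias)
  expect_equal(rep_$loa_upper, rep_$bias + 1.96 * rep_$sd_bias)
  expect_equal(rep_$mdc / rep_$sem, 1.96 * sqrt(2))
  expect_true(rep_$icc_single_ci[1] <= rep_$icc_single &&
                rep_$icc_single <= rep_$icc_single_ci[2])
  expect_true(rep_$cv_ci[1] < rep_$cv_percent && rep_$cv_percent < rep_$cv_ci[2])
  expect_equal(rep_$df, 21)
  expect_output(print(rep_), "ICCs")
})
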
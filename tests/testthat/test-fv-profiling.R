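# Normalization, profile fitting (linear / polynomial / two-point) and the
# derived-parameter identities.

test_that("torque converts to normalized force and linear velocity", {
  a <- anthropometrics("S01", body_mass = 64, lever_length = 0.4)
  p <- to_fv_point(100, 0, a)
  expect_equal(p$force_n_per_kg23, 250 / 16)  # 64^(2/3) = 16
  expect_equal(p$velocity_mps, 0)

  a2 <- anthropometrics("S02", body_mass = 63.1, lever_length = 0.382)
  p2 <- to_fv_point(80, 300, a2)
  expect_equal(p2$velocity_mps, 300 * pi / 180 * 0.382, tolerance = 1e-12)
  expect_equal(round(p2$velocity_mps, 4), 2.0001)

  expect_error(anthropometrics("S03", 64, 0), class = "isofv_error_invalid_parameter")
  expect_error(to_fv_point(-5, 60, a), class = "isofv_error_invalid_measurement")
})

test_that("linear fit recovers an exact line and its derived parameters", {
  pts <- line_points(28, -9)
  pr <- fit_linear(pts)
  expect_equal(pr$method, "linear_9pt")
  expect_equal(pr$F0, 28, tolerance = 1e-9)
  expect_equal(pr$Sfv, -9, tolerance = 1e-9)
  expect_equal(pr$v0, 28 / 9, tolerance = 1e-9)
  expect_equal(pr$Pmax, 28 * (28 / 9) / 4, tolerance = 1e-9)
  expect_equal(pr$fit$r, -1, tolerance = 1e-9)
  expect_equal(pr$fit$r_squared, 1, tolerance = 1e-9)
  expect_true(is.infinite(pr$fit$z_prime))
  expect_true("perfect_fit" %in% pr$flags)
})

test_that("equal perturbation of velocity-symmetric points leaves the slope unchanged", {
  # OLS slope depends on sum(delta_i * (v_i - vbar)): equal same-sign
  # nudges at a velocity-symmetric pair cancel there, moving only the
  # intercept by their mean contribution
  omegas <- seq(30, 270, by = 30)  # mean 150: (60, 240) is a symmetric pair
  pts <- line_points(28, -9, omegas = omegas)
  delta <- 0.8
  pts2 <- pts
  for (om in c(60, 240)) {
    pts2$force_n_per_kg23[pts2$angular_velocity_dps == om] <-
      pts2$force_n_per_kg23[pts2$angular_velocity_dps == om] + delta
  }
  p1 <- fit_linear(pts)
  p2 <- suppressWarnings(fit_linear(pts2))
  expect_equal(p2$Sfv, p1$Sfv, tolerance = 1e-9)
  expect_equal(p2$F0, p1$F0 + 2 * delta / 9, tolerance = 1e-9)
})

test_that("linear fit rejects degenerate and non-physical inputs", {
  pts <- line_points(28, -9)[1:2, ]
  pts$velocity_mps <- pts$velocity_mps[1]
  pts$angular_velocity_dps <- pts$angular_velocity_dps[1]
  expect_error(fit_linear(pts), class = "isofv_error_rank_deficient")

  rising <- line_points(10, +3)
  expect_error(fit_linear(rising), class = "isofv_error_nonphysical")
})

test_that("quadratic fit interpolates an exact quadratic and nests the line", {
  v <- seq(0.2, 2, by = 0.2)
  pts <- data.frame(subject_id = "S01", task = "KE",
                    angular_velocity_dps = v * 180 / pi / 0.382,
                    velocity_mps = v,
                    force_n_per_kg23 = 30 - 10 * v + 0.5 * v^2)
  pr <- fit_polynomial(pts)
  expect_equal(pr$coefficients, c(30, -10, 0.5), tolerance = 1e-9)
  expect_equal(pr$F0, 30, tolerance = 1e-9)
  v0_expected <- (10 - sqrt(100 - 4 * 0.5 * 30))  # smallest root of the quadratic
  expect_equal(pr$v0, v0_expected, tolerance = 1e-9)
  expect_equal(pr$Pmax, pr$F0 * pr$v0 / 4, tolerance = 1e-12)

  # straight-line input: quadratic coefficient collapses, F0 matches linear
  lpts <- line_points(28, -9)
  pq <- fit_polynomial(lpts)
  expect_equal(pq$coefficients[3], 0, tolerance = 1e-8)
  expect_equal(pq$F0, fit_linear(lpts)$F0, tolerance = 1e-7)
})

test_that("concave-up quadratic without a forward root flags v0 as undefined", {
  v <- seq(0.5, 2, by = 0.25)
  pts <- data.frame(velocity_mps = v, force_n_per_kg23 = 20 - 4 * v + 1.5 * v^2)
  pr <- fit_polynomial(pts)
  expect_true("v0_undefined" %in% pr$flags)
  expect_true(is.na(pr$v0))
  expect_true(is.na(pr$Pmax))
})

test_that("polynomial fits Hill-curved data better than the line (z' direction)", {
  co <- sample_cohort(cohort_config(seed = 202))
  pts <- cohort_points(co, "KE")
  z <- vapply(split(pts, pts$subject_id), function(s) {
    c(lin = fit_linear(s)$fit$z_prime, pol = fit_polynomial(s)$fit$z_prime)
  }, c(lin = 0, pol = 0))
  expect_true(all(is.finite(z)))
  expect_gt(mean(z["pol", ]) , mean(z["lin", ]))
  expect_true(all(z["pol", ] >= z["lin", ] - 1e-10))  # nested least squares
})

test_that("two-point profile matches the closed form and the OLS oracle", {
  p <- two_point_profile(list(velocity_mps = 1, force_n_per_kg23 = 20),
                         list(velocity_mps = 3, force_n_per_kg23 = 4))
  expect_equal(p$Sfv, -8)
  expect_equal(p$F0, 28)
  expect_equal(p$v0, 3.5)
  expect_equal(p$Pmax, 24.5)

  # collinearity: any two points of an exact line reproduce the 9-point fit
  pts <- line_points(28, -9)
  full <- fit_linear(pts)
  pair <- two_point_profile(pts[2, ], pts[8, ])
  expect_rel_equal(profile_params(pair), profile_params(full), 1e-9)

  expect_error(two_point_profile(pts[3, ], pts[3, ]), class = "isofv_error_degenerate_pair")
  expect_error(
    two_point_profile(list(velocity_mps = 1, force_n_per_kg23 = 5),
                      list(velocity_mps = 2, force_n_per_kg23 = 9)),
    class = "isofv_error_nonphysical"
  )
})

test_that("two_point_profile equals OLS restricted to the same two points", {
  withr::with_seed(99, {
    for (i in 1:200) {
      v <- sort(runif(2, 0.1, 3))
      f <- sort(runif(2, 1, 40), decreasing = TRUE)
      pts <- data.frame(velocity_mps = v, force_n_per_kg23 = f)
      tp <- two_point_profile(pts[1, ], pts[2, ])
      ls <- fit_linear(pts)
      expect_rel_equal(profile_params(tp), profile_params(ls), 1e-9)
    }
  })
})

test_that("derived parameters obey the slope and power identities", {
  dp <- derive_parameters(28, -8)
  expect_equal(dp$v0, 3.5)
  expect_equal(dp$Pmax, 24.5)
  expect_error(derive_parameters(28, 0.1), class = "isofv_error_nonphysical")

  # group means of parameters differ from parameters of group means:
  # Pmax computed from mean F0 and mean v0 understates the mean of
  # per-subject Pmax whenever F0 and v0 covary positively
  expect_equal(round(27.98 * 3.16 / 4, 2), 22.10)
  co <- sample_cohort(cohort_config(seed = 77))
  pts <- cohort_points(co, "KE")
  prof <- lapply(split(pts, pts$subject_id), fit_linear)
  F0s <- vapply(prof, function(p) p$F0, 0)
  v0s <- vapply(prof, function(p) p$v0, 0)
  Pmaxs <- vapply(prof, function(p) p$Pmax, 0)
  expect_false(isTRUE(all.equal(mean(Pmaxs), mean(F0s) * mean(v0s) / 4)))

  # limit: Pmax -> 0 as F0 -> 0
  expect_lt(derive_parameters(1e-9, -8)$Pmax, 1e-18)
})

test_that("every emitted profile satisfies the v0 and Pmax identities", {
  co <- sample_cohort(cohort_config(seed = 31))
  for (task in c("KE", "KF")) {
    pts <- cohort_points(co, task)
    for (s in split(pts, pts$subject_id)) {
      lin <- fit_linear(s)
      expect_rel_equal(lin$v0, -lin$F0 / lin$Sfv, 1e-9)
      expect_rel_equal(lin$Pmax, lin$F0 * lin$v0 / 4, 1e-9)
      tp <- two_point_profile(s[s$angular_velocity_dps == 30, ],
                              s[s$angular_velocity_dps == 300, ])
      expect_rel_equal(tp$v0, -tp$F0 / tp$Sfv, 1e-9)
      expect_rel_equal(tp$Pmax, tp$F0 * tp$v0 / 4, 1e-9)
    }
  }
})

test_that("fisher_z is atanh with domain checks and antisymmetry", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.96), 0.5 * log(1.96 / 0.04))
  expect_equal(round(fisher_z(0.96), 4), 1.9459)
  r <- seq(-0.95, 0.95, by = 0.19)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_error(fisher_z(1), class = "isofv_error_domain")
  expect_error(fisher_z(-1.2), class = "isofv_error_domain")
})

test_that("F0 vs isometric comparison and its cohort-level direction", {
  cmp <- compare_f0_to_isometric(28, 32)
  expect_equal(cmp$difference, -4)
  expect_equal(cmp$ratio, 0.875)
  eq <- compare_f0_to_isometric(30, 30)
  expect_equal(eq$difference, 0)
  expect_equal(eq$ratio, 1)

  co <- sample_cohort(cohort_config(seed = 12))
  pts <- cohort_points(co, "KE")
  iso <- cohort_isometric(co, "KE")
  F0s <- vapply(split(pts, pts$subject_id), function(s) fit_linear(s)$F0, 0)
  ratios <- compare_f0_to_isometric(F0s, iso$iso_force_n_per_kg23)$ratio
  expect_lt(mean(ratios), 1)  # extrapolated F0 underestimates isometric force
})
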
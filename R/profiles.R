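# F-v profile fitting: linear (any number of points >= 2), quadratic
# polynomial, and the exact two-point line. A profile carries the four
# canonical parameters (F0, v0, Sfv, Pmax) plus fit quality (r, R^2, z').
#
# Conventions. Sfv is the fitted slope, negative for physically meaningful
# profiles; v0 = -F0/Sfv and Pmax = F0*v0/4 hold by construction for linear
# fits. Fit-quality r is the signed force-velocity correlation for linear
# and two-point fits (so a descending line has r = -1) and the
# observed-vs-fitted correlation for the polynomial; z' = atanh(|r|) is the
# variance-stabilized fit quality used for between-method comparisons, and
# is +Inf (flag "perfect_fit") for exact fits.

new_fv_profile <- function(method, F0, Sfv, v0, Pmax, velocities_used,
                           r, r_squared, z_prime, flags = character(),
                           subject_id = NA_character_, task = NA_character_,
                           coefficients = NULL) {
  structure(
    list(method = method, F0 = F0, Sfv = Sfv, v0 = v0, Pmax = Pmax,
         velocities_used = velocities_used,
         fit = list(r = r, r_squared = r_squared, z_prime = z_prime),
         flags = flags, subject_id = subject_id, task = task,
         coefficients = coefficients),
    class = "fv_profile"
  )
}

#' @export
print.fv_profile <- function(x, ...) {
  cat(sprintf("<fv_profile:%s>%s F0 = %.3f N kg^-2/3 | v0 = %s m/s | Sfv = %.3f | Pmax = %s W kg^-2/3\n",
              x$method,
              if (!is.na(x$subject_id)) paste0(" [", x$subject_id, "]") else "",
              x$F0,
              if (is.na(x$v0)) "undefined" else sprintf("%.3f", x$v0),
              x$Sfv,
              if (is.na(x$Pmax)) "undefined" else sprintf("%.3f", x$Pmax)))
  cat(sprintf("  fit: r = %.4f, R^2 = %.4f, z' = %.4f%s\n",
              x$fit$r, x$fit$r_squared, x$fit$z_prime,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

fit_quality_z <- function(r) {
  if (!is.finite(r)) return(NA_real_)
  if (abs(r) >= 1 - 1e-12) Inf else atanh(abs(r))
}

#' Fit the linear F-v profile by ordinary least squares
#'
#' Regresses normalized force on linear velocity across the isokinetic
#' points (isometric points, `angular_velocity_dps == 0`, are excluded: the
#' profile is fitted to isokinetic data only, and its force intercept F0 is
#' an extrapolation that can then be compared with measured isometric force).
#'
#' @param points F-v points data.frame (see [to_fv_point()]).
#' @param min_points Minimum number of distinct velocities (default 2).
#' @return An `fv_profile` with `method` `"linear_9pt"` when fitted on nine
#'   velocities, otherwise `"linear_kpt"`.
#' @export
fit_linear <- function(points, min_points = 2) {
  check_fv_points(points)
  pts <- drop_isometric(points)
  v <- pts$velocity_mps
  f <- pts$force_n_per_kg23
  if (length(unique(v)) < min_points) {
    if (length(v) >= min_points) {
      abort_isofv("duplicate velocities: design is rank deficient",
                  "isofv_error_rank_deficient")
    }
    abort_isofv(sprintf("need >= %d distinct velocities", min_points),
                "isofv_error_precondition")
  }
  fit <- stats::lm.fit(cbind(1, v), f)
  F0 <- unname(fit$coefficients[1])
  Sfv <- unname(fit$coefficients[2])
  if (!is.finite(Sfv) || Sfv >= 0) {
    abort_isofv("fitted slope is non-negative: non-physical F-v profile (v0 undefined)",
                "isofv_error_nonphysical")
  }
  dp <- derive_parameters(F0, Sfv)
  r <- stats::cor(v, f)
  z <- fit_quality_z(r)
  method <- if (length(unique(v)) == 9L) "linear_9pt" else "linear_kpt"
  new_fv_profile(
    method, F0, Sfv, dp$v0, dp$Pmax,
    velocities_used = sort(unique(pts$angular_velocity_dps %||% v)),
    r = r, r_squared = r^2, z_prime = z,
    flags = if (is.infinite(z)) "perfect_fit" else character(),
    subject_id = pts$subject_id[1] %||% NA_character_,
    task = pts$task[1] %||% NA_character_
  )
}

#' Fit a quadratic polynomial F-v profile
#'
#' Least-squares degree-`degree` (default 2) polynomial of force on
#' velocity. F0 is the value at v = 0. v0 is the smallest real root beyond
#' the largest observed velocity when one exists, otherwise undefined
#' (flag `"v0_undefined"`, no error): a concave-up quadratic need not cross
#' zero. Sfv is reported as the polynomial slope at the midpoint of the
#' observed velocity range; Pmax = F0 v0 / 4 only when v0 is defined.
#'
#' @param points F-v points data.frame.
#' @param degree Polynomial degree (default 2).
#' @return An `fv_profile` with `method` `"polynomial_9pt"`.
#' @export
fit_polynomial <- function(points, degree = 2) {
  check_fv_points(points)
  pts <- drop_isometric(points)
  v <- pts$velocity_mps
  f <- pts$force_n_per_kg23
  if (length(unique(v)) < degree + 1) {
    abort_isofv(sprintf("need >= %d distinct velocities for degree %d", degree + 1, degree),
                "isofv_error_precondition")
  }
  X <- stats::poly(v, degree = degree, raw = TRUE)
  fit <- stats::lm(f ~ X)
  coefs <- unname(stats::coef(fit))  # c0, c1, ..., c_degree
  F0 <- coefs[1]
  vmid <- (min(v) + max(v)) / 2
  dpow <- seq_len(degree)
  Sfv <- sum(coefs[-1] * dpow * vmid^(dpow - 1))
  roots <- polyroot(coefs)
  real_roots <- Re(roots[abs(Im(roots)) < 1e-8 * (1 + abs(Re(roots)))])
  cand <- sort(real_roots[real_roots > max(v)])
  flags <- character()
  if (length(cand)) {
    v0 <- cand[1]
    Pmax <- F0 * v0 / 4
  } else {
    v0 <- NA_real_
    Pmax <- NA_real_
    flags <- "v0_undefined"
  }
  fitted_f <- stats::fitted(fit)
  r <- if (stats::sd(fitted_f) > 0) stats::cor(f, fitted_f) else NA_real_
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((f - mean(f))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  z <- fit_quality_z(r)
  if (is.infinite(z)) flags <- c(flags, "perfect_fit")
  new_fv_profile(
    "polynomial_9pt", F0, Sfv, v0, Pmax,
    velocities_used = sort(unique(pts$angular_velocity_dps %||% v)),
    r = r, r_squared = r2, z_prime = z, flags = flags,
    subject_id = pts$subject_id[1] %||% NA_character_,
    task = pts$task[1] %||% NA_character_,
    coefficients = coefs
  )
}

#' Two-point F-v profile (exact line through two measurements)
#'
#' @param p_low,p_high Single F-v points (one-row data.frames or lists with
#'   `velocity_mps` and `force_n_per_kg23`), with `p_low` the slower, higher
#'   force point.
#' @return An `fv_profile` with `method` `"two_point"`.
#' @export
two_point_profile <- function(p_low, p_high) {
  v1 <- p_low$velocity_mps; f1 <- p_low$force_n_per_kg23
  v2 <- p_high$velocity_mps; f2 <- p_high$force_n_per_kg23
  if (!all(is.finite(c(v1, f1, v2, f2)))) {
    abort_isofv("two-point inputs must be finite", "isofv_error_malformed_input")
  }
  if (v1 == v2) {
    abort_isofv("the two velocities are equal: degenerate pair", "isofv_error_degenerate_pair")
  }
  if (v1 > v2) {
    abort_isofv("p_low must be the slower point", "isofv_error_precondition")
  }
  if (f1 <= 0 || f2 <= 0) {
    abort_isofv("forces must be positive", "isofv_error_invalid_measurement")
  }
  if (f1 <= f2) {
    abort_isofv("force must decrease with velocity: non-physical two-point profile",
                "isofv_error_nonphysical")
  }
  Sfv <- (f2 - f1) / (v2 - v1)
  F0 <- f1 - Sfv * v1
  dp <- derive_parameters(F0, Sfv)
  new_fv_profile(
    "two_point", F0, Sfv, dp$v0, dp$Pmax,
    velocities_used = c(p_low$angular_velocity_dps %||% v1,
                        p_high$angular_velocity_dps %||% v2),
    r = -1, r_squared = 1, z_prime = Inf, flags = "perfect_fit",
    subject_id = p_low$subject_id %||% NA_character_,
    task = p_low$task %||% NA_character_
  )
}

#' Derive v0 and Pmax from F0 and the slope
#'
#' `v0 = -F0 / Sfv` (velocity-axis intercept of the line) and
#' `Pmax = F0 * v0 / 4` (apex of the parabolic power-velocity curve implied
#' by a linear F-v relationship).
#'
#' @param F0 Force intercept (> 0).
#' @param Sfv Fitted slope (< 0).
#' @return List with `v0` and `Pmax`.
#' @export
derive_parameters <- function(F0, Sfv) {
  if (!is.finite(F0) || F0 < 0) {
    abort_isofv("F0 must be finite and >= 0", "isofv_error_nonphysical")
  }
  if (!is.finite(Sfv) || Sfv >= 0) {
    abort_isofv("Sfv must be negative: non-physical profile", "isofv_error_nonphysical")
  }
  v0 <- -F0 / Sfv
  list(v0 = v0, Pmax = F0 * v0 / 4)
}

#' Fisher z-transformation of a correlation coefficient
#'
#' @param r Correlation in (-1, 1).
#' @return `atanh(r)`.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    abort_isofv("|r| must be < 1 for the Fisher z-transformation", "isofv_error_domain")
  }
  atanh(r)
}

#' Compare extrapolated F0 with measured isometric force
#'
#' @param profile_F0 Extrapolated force intercept, N kg^-2/3.
#' @param isometric_force Measured normalized isometric force, N kg^-2/3.
#' @return List with `difference` (F0 - isometric) and `ratio`
#'   (F0 / isometric; < 1 means the profile underestimates isometric force).
#' @export
compare_f0_to_isometric <- function(profile_F0, isometric_force) {
  if (any(profile_F0 <= 0) || any(isometric_force <= 0)) {
    abort_isofv("both forces must be positive", "isofv_error_precondition")
  }
  list(difference = profile_F0 - isometric_force,
       ratio = profile_F0 / isometric_force)
}

drop_isometric <- function(points) {
  if ("angular_velocity_dps" %in% names(points)) {
    points <- points[is.na(points$angular_velocity_dps) | points$angular_velocity_dps > 0, ,
                     drop = FALSE]
  }
  points[points$velocity_mps > 0, , drop = FALSE]
}

# Collect the four parameters of a profile as a named numeric vector.
profile_params <- function(p) {
  c(F0 = p$F0, v0 = p$v0, Sfv = p$Sfv, Pmax = p$Pmax)
}
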
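# Shared fixtures, all generated in code.

paper_velocities <- c(30, 60, 90, 120, 150, 180, 210, 240, 300)

# Deterministic sample with exact mean and SD (stats::sd denominator n - 1).
moment_sample <- function(n, mean, sd) {
  x <- seq_len(n)
  x <- (x - base::mean(x)) / stats::sd(x)
  mean + sd * x
}

# Points on an exact line F = f0 + slope * v at given angular velocities.
line_points <- function(f0, slope, omegas = paper_velocities, lever = 0.382,
                        subject_id = "S01", task = "KE") {
  v <- omegas * pi / 180 * lever
  data.frame(subject_id = subject_id, task = task,
             angular_velocity_dps = omegas, velocity_mps = v,
             force_n_per_kg23 = f0 + slope * v)
}

# A noiseless collinear cohort: per-subject exact lines with varying F0/Sfv.
collinear_cohort <- function(n_subjects = 8, omegas = paper_velocities,
                             task = "KE", seed = 11) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_subjects), function(i) {
      line_points(f0 = 24 + 2 * stats::rnorm(1), slope = -(8 + stats::rnorm(1)),
                  omegas = omegas, subject_id = sprintf("S%02d", i), task = task)
    }))
  })
}

# Trapezoidal velocity profile: ramp up, hold, ramp down (+ optional tail).
trapezoid_velocity <- function(v_plateau, plateau_s, ramp_s = 0.2, tail_s = 0.2,
                               fs = 500) {
  c(seq(0, v_plateau, length.out = round(ramp_s * fs)),
    rep(v_plateau, round(plateau_s * fs)),
    seq(v_plateau, 0, length.out = round(ramp_s * fs)),
    rep(0, round(tail_s * fs)))
}

expect_rel_equal <- function(actual, expected, tol = 1e-9) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}

# internal helpers used across tests
profile_params <- function(p) isofv:::profile_params(p)
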
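# Synthetic Hill-muscle cohort generator.
#
# Ground truth per subject and task is the classical rectangular-hyperbola
# torque-velocity relation (T + a)(w + b) = (T_iso + a) b with a = c*T_iso
# and b = c*w_max, concave-up and decreasing on [0, w_max]. Over the
# protocol range (30-300 deg/s) it is quasilinear, so a straight line fits
# with high R^2 while its force intercept falls short of true isometric
# torque -- the two empirical regimes the analysis pipeline must reproduce.
# Measurement noise is multiplicative Gaussian on peak torque.

#' Hill torque-velocity hyperbola
#'
#' `T(w) = (T_iso + a) * b / (w + b) - a` with `a = curvature * T_iso` and
#' `b = curvature * max_velocity`; `T(0) = T_iso` and `T(max_velocity) = 0`.
#'
#' @param iso_torque True isometric torque T_iso, N m (> 0).
#' @param curvature Dimensionless curvature `a / T_iso`, in `[0.1, 0.6]`
#'   (smaller = more curved).
#' @param max_velocity True zero-torque angular velocity, deg/s (> 300).
#' @param omega Angular velocity query, deg/s, in `[0, max_velocity)`;
#'   vectorized.
#' @return Torque in N m.
#' @export
hill_torque <- function(iso_torque, curvature, max_velocity, omega) {
  if (iso_torque <= 0 || curvature < 0.1 || curvature > 0.6 || max_velocity <= 300) {
    abort_isofv("invalid Hill parameters (need iso_torque > 0, 0.1 <= curvature <= 0.6, max_velocity > 300)",
                "isofv_error_invalid_parameter")
  }
  if (any(omega < 0) || any(omega >= max_velocity)) {
    abort_isofv("omega must lie in [0, max_velocity)", "isofv_error_domain")
  }
  a <- curvature * iso_torque
  b <- curvature * max_velocity
  (iso_torque + a) * b / (omega + b) - a
}

#' Configuration for a synthetic cohort
#'
#' Defaults emulate the reference cohort: n = 22 physically active adults
#' (body mass 63.1 +/- 4.4 kg), tested at 30-300 deg/s plus isometric, with
#' 3% multiplicative measurement noise on peak torque. Task-specific Hill
#' ranges are generator choices calibrated so the normalized knee-extension
#' profile lands at F0 ~ 23-33 N kg^-2/3 and v0 ~ 3-3.5 m/s and knee
#' flexion at F0 ~ 11-19 with a flatter slope; lever length ~ N(0.35, 0.03)
#' m maps 300 deg/s to ~1.8 m/s.
#'
#' @param n_subjects Cohort size (default 22).
#' @param body_mass_mean,body_mass_sd Body mass distribution, kg.
#' @param lever_mean,lever_sd Lever-arm distribution, m.
#' @param ke,kf Per-task Hill parameter distributions: lists with
#'   `iso_torque_mean`, `iso_torque_sd`, `curvature_range`,
#'   `omega_max_mean`, `omega_max_sd`.
#' @param noise_cv Multiplicative peak-torque noise SD (default 0.03).
#' @param trace_noise_sd Additive white-noise SD for generated traces, N m.
#' @param velocities Protocol angular velocities, deg/s.
#' @param seed Integer seed; mandatory, every stochastic call derives from it.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 22,
                          body_mass_mean = 63.1, body_mass_sd = 4.4,
                          lever_mean = 0.35, lever_sd = 0.03,
                          ke = list(iso_torque_mean = 172, iso_torque_sd = 18,
                                    curvature_range = c(0.15, 0.45),
                                    omega_max_mean = 1250, omega_max_sd = 150),
                          kf = list(iso_torque_mean = 88, iso_torque_sd = 12,
                                    curvature_range = c(0.25, 0.55),
                                    omega_max_mean = 1150, omega_max_sd = 150),
                          noise_cv = 0.03, trace_noise_sd = 1.5,
                          velocities = c(30, 60, 90, 120, 150, 180, 210, 240, 300),
                          seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort_isofv("a scalar integer seed is mandatory", "isofv_error_config")
  }
  bad <- character()
  if (n_subjects < 2) bad <- c(bad, "n_subjects")
  if (body_mass_mean <= 0 || body_mass_sd < 0) bad <- c(bad, "body_mass")
  if (lever_mean <= 0.1 || lever_mean >= 0.6 || lever_sd < 0) bad <- c(bad, "lever")
  if (noise_cv < 0) bad <- c(bad, "noise_cv")
  if (length(velocities) < 2 || any(velocities <= 0)) bad <- c(bad, "velocities")
  for (task in c("ke", "kf")) {
    p <- get(task)
    if (p$iso_torque_mean <= 0 || p$iso_torque_sd < 0 ||
        p$curvature_range[1] < 0.1 || p$curvature_range[2] > 0.6 ||
        p$curvature_range[1] > p$curvature_range[2] ||
        p$omega_max_mean <= max(velocities)) {
      bad <- c(bad, task)
    }
  }
  if (length(bad)) {
    abort_isofv(paste0("invalid cohort configuration fields: ", paste(bad, collapse = ", ")),
                "isofv_error_config")
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         body_mass_mean = body_mass_mean, body_mass_sd = body_mass_sd,
         lever_mean = lever_mean, lever_sd = lever_sd,
         ke = ke, kf = kf, noise_cv = noise_cv, trace_noise_sd = trace_noise_sd,
         velocities = sort(velocities), seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Truncated-normal draws (+/- 3 SD) by rejection; degenerate SD passes through.
rtruncnorm3 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[abs(x - mean) <= 3 * sd])
  }
  out[seq_len(n)]
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Sample a synthetic cohort
#'
#' Deterministic given the config seed. Draws anthropometrics and per-task
#' Hill parameters from truncated normal (+/- 3 SD) / uniform distributions,
#' evaluates noiseless peak torques at the protocol velocities plus
#' isometric, and overlays multiplicative noise `T * (1 + eps)`,
#' `eps ~ N(0, noise_cv)`, independently per subject x task x velocity.
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort`: `anthro` (data.frame),
#'   `hill` (data.frame of per-subject, per-task Hill parameters), `torque`
#'   (long data.frame: subject, task, angular velocity with 0 = isometric,
#'   noiseless and noisy N m), and the `config`.
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_subjects
    ids <- sprintf("S%02d", seq_len(n))
    anthro <- data.frame(
      subject_id = ids,
      body_mass = rtruncnorm3(n, config$body_mass_mean, config$body_mass_sd),
      lever_length = pmin(pmax(rtruncnorm3(n, config$lever_mean, config$lever_sd), 0.101), 0.599)
    )
    hill <- do.call(rbind, lapply(c("KE", "KF"), function(task) {
      p <- if (task == "KE") config$ke else config$kf
      data.frame(
        subject_id = ids, task = task,
        iso_torque = rtruncnorm3(n, p$iso_torque_mean, p$iso_torque_sd),
        curvature = stats::runif(n, p$curvature_range[1], p$curvature_range[2]),
        max_velocity = pmax(rtruncnorm3(n, p$omega_max_mean, p$omega_max_sd),
                            max(config$velocities) + 50)
      )
    }))
    omegas <- c(0, config$velocities)
    torque <- do.call(rbind, lapply(seq_len(nrow(hill)), function(i) {
      h <- hill[i, ]
      noiseless <- hill_torque(h$iso_torque, h$curvature, h$max_velocity, omegas)
      data.frame(subject_id = h$subject_id, task = h$task,
                 angular_velocity_dps = omegas, noiseless = noiseless)
    }))
    torque$noisy <- torque$noiseless *
      (1 + stats::rnorm(nrow(torque), 0, config$noise_cv))
    structure(list(anthro = anthro, hill = hill, torque = torque, config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> n = %d subjects, %d velocities + isometric, noise CV %g, seed %d\n",
              x$config$n_subjects, length(x$config$velocities),
              x$config$noise_cv, x$config$seed))
  invisible(x)
}

subject_anthro <- function(cohort, subject_id) {
  a <- cohort$anthro[cohort$anthro$subject_id == subject_id, ]
  anthropometrics(a$subject_id, a$body_mass, a$lever_length)
}

#' Normalized F-v points of a synthetic cohort
#'
#' @param cohort A [sample_cohort()] result.
#' @param task `"KE"`, `"KF"` or both.
#' @param noisy Use the noisy (default) or noiseless torque table.
#' @param include_isometric Keep the 0 deg/s rows (default `FALSE`; profile
#'   fits exclude them anyway).
#' @return F-v points data.frame (see [to_fv_point()]).
#' @export
cohort_points <- function(cohort, task = c("KE", "KF"), noisy = TRUE,
                          include_isometric = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  task <- match.arg(task, several.ok = TRUE)
  tq <- cohort$torque[cohort$torque$task %in% task, , drop = FALSE]
  if (!include_isometric) tq <- tq[tq$angular_velocity_dps > 0, , drop = FALSE]
  out <- lapply(split(tq, interaction(tq$subject_id, tq$task, drop = TRUE)), function(s) {
    anth <- subject_anthro(cohort, s$subject_id[1])
    to_fv_point(if (noisy) s$noisy else s$noiseless,
                s$angular_velocity_dps, anth, task = s$task[1])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$task, res$subject_id, res$angular_velocity_dps), , drop = FALSE]
}

#' Normalized isometric force of each subject
#'
#' @inheritParams cohort_points
#' @return data.frame: `subject_id`, `task`, `iso_force_n_per_kg23`.
#' @export
cohort_isometric <- function(cohort, task = c("KE", "KF"), noisy = TRUE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  task <- match.arg(task, several.ok = TRUE)
  tq <- cohort$torque[cohort$torque$task %in% task &
                        cohort$torque$angular_velocity_dps == 0, , drop = FALSE]
  force <- vapply(seq_len(nrow(tq)), function(i) {
    anth <- subject_anthro(cohort, tq$subject_id[i])
    t_iso <- if (noisy) tq$noisy[i] else tq$noiseless[i]
    (t_iso / anth$lever_length) / anth$body_mass^(2 / 3)
  }, numeric(1))
  data.frame(subject_id = tq$subject_id, task = tq$task,
             iso_force_n_per_kg23 = force)
}

#' Ground-truth linear profile of one subject
#'
#' The least-squares line through the noiseless normalized points -- the
#' recovery target for fits on noisy data.
#'
#' @param cohort A synthetic cohort.
#' @param subject_id Subject identifier.
#' @param task `"KE"` or `"KF"`.
#' @param velocities Velocities to use (default: full protocol).
#' @return An `fv_profile`.
#' @export
true_linear_profile <- function(cohort, subject_id, task = c("KE", "KF"),
                                velocities = NULL) {
  task <- match.arg(task)
  pts <- cohort_points(cohort, task = task, noisy = FALSE)
  pts <- pts[pts$subject_id == subject_id, , drop = FALSE]
  if (!nrow(pts)) abort_isofv("unknown subject", "isofv_error_precondition")
  if (!is.null(velocities)) {
    pts <- pts[pts$angular_velocity_dps %in% velocities, , drop = FALSE]
  }
  fit_linear(pts)
}

#' Generate a raw torque-time trace for one synthetic trial
#'
#' Isokinetic trials (omega > 0) contain 6 repetitions, each an
#' acceleration ramp, an isokinetic plateau whose torque rises to the Hill
#' peak (modulated per repetition by +/-2% and by the multiplicative noise
#' model) with a flat top, and a deceleration, separated by rest gaps; the
#' velocity channel carries the trapezoidal profile. Isometric trials
#' (omega = 0) are a 5-s ramp-and-hold at T_iso. White noise
#' (`trace_noise_sd`) is added to the torque before output; set
#' `noisy = FALSE` for a fully deterministic noiseless trace.
#'
#' @param cohort A synthetic cohort.
#' @param subject_id Subject identifier.
#' @param task `"KE"` or `"KF"`.
#' @param omega Protocol angular velocity (one of the protocol set, or 0).
#' @param noisy Add measurement noise (default `TRUE`).
#' @param sampling_rate Hz (default 500).
#' @param n_reps Repetitions per isokinetic set (default 6).
#' @return A [torque_trace()]; attribute `"true_peaks"` holds the noiseless
#'   per-repetition peak torques (isokinetic) or T_iso (isometric).
#' @export
generate_trace <- function(cohort, subject_id, task = c("KE", "KF"), omega,
                           noisy = TRUE, sampling_rate = 500, n_reps = 6) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  task <- match.arg(task)
  if (!(omega == 0 || omega %in% cohort$config$velocities)) {
    abort_isofv("omega must be 0 or a protocol velocity", "isofv_error_precondition")
  }
  h <- cohort$hill[cohort$hill$subject_id == subject_id & cohort$hill$task == task, ]
  if (!nrow(h)) abort_isofv("unknown subject/task", "isofv_error_precondition")
  sub_idx <- match(subject_id, cohort$anthro$subject_id)
  trial_seed <- (cohort$config$seed + 7919L * sub_idx + 13L * as.integer(omega) +
                   1000003L * (task == "KF")) %% .Machine$integer.max
  with_seed(trial_seed, {
    dt <- 1 / sampling_rate
    if (omega == 0) {
      t_total <- 5
      tt <- seq(0, t_total - dt, by = dt)
      ramp_dur <- 1.5
      shape <- ifelse(tt < ramp_dur, 0.5 * (1 - cos(pi * tt / ramp_dur)), 1)
      torque <- h$iso_torque * shape
      velocity <- rep(0, length(tt))
      true_peaks <- h$iso_torque
    } else {
      accel <- 0.15            # s, velocity ramp up/down
      plateau <- max(1.4, 80 / omega)  # s, >= ~80 deg of isokinetic range of motion
      gap <- 0.4               # s, rest between repetitions
      edge <- 0.55             # s, raised-cosine torque rise/fall inside plateau
                               # (slow relative to the 5 Hz filter so the
                               # zero-phase pass neither rings nor clips the top)
      peak_base <- hill_torque(h$iso_torque, h$curvature, h$max_velocity, omega)
      rep_mod <- 1 + stats::runif(n_reps, -0.02, 0.02)
      noise_mod <- if (noisy) 1 + stats::rnorm(n_reps, 0, cohort$config$noise_cv) else 1
      true_peaks <- peak_base * rep_mod
      peaks <- peak_base * rep_mod * noise_mod
      rep_v <- function() {
        c(seq(0, omega, length.out = round(accel * sampling_rate)),
          rep(omega, round(plateau * sampling_rate)),
          seq(omega, 0, length.out = round(accel * sampling_rate)),
          rep(0, round(gap * sampling_rate)))
      }
      rep_torque <- function(peak) {
        np <- round(plateau * sampling_rate)
        ne <- round(edge * sampling_rate)
        core <- rep(1, np)
        core[seq_len(ne)] <- 0.5 * (1 - cos(pi * seq_len(ne) / ne))
        core[np - seq_len(ne) + 1L] <- core[seq_len(ne)]
        c(numeric(round(accel * sampling_rate)), peak * core,
          numeric(round(accel * sampling_rate)), numeric(round(gap * sampling_rate)))
      }
      velocity <- unlist(lapply(seq_len(n_reps), function(i) rep_v()), use.names = FALSE)
      torque <- unlist(lapply(seq_len(n_reps), function(i) rep_torque(peaks[i])),
                       use.names = FALSE)
    }
    if (noisy) torque <- torque + stats::rnorm(length(torque), 0, cohort$config$trace_noise_sd)
    tr <- torque_trace(torque, sampling_rate = sampling_rate,
                       protocol_velocity = omega, task = task,
                       velocity = velocity, subject_id = subject_id)
    attr(tr, "true_peaks") <- true_peaks
    tr
  })
}
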
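# Exhaustive screening of two-velocity combinations against the multi-point
# reference profile, with the validity criteria applied per parameter.

#' All two-velocity combinations of a protocol
#'
#' @param velocities Angular velocities in deg/s (duplicates are removed
#'   with a warning). The standard 9-velocity protocol yields 36 pairs.
#' @return data.frame with columns `low`, `high`, sorted by `(low, high)`.
#' @export
enumerate_combinations <- function(velocities) {
  v <- sort(velocities)
  if (anyDuplicated(v)) {
    warn_isofv("duplicate velocities removed", "isofv_warning_duplicates")
    v <- unique(v)
  }
  if (length(v) < 2L) {
    return(data.frame(low = numeric(0), high = numeric(0)))
  }
  pairs <- utils::combn(v, 2)
  data.frame(low = pairs[1, ], high = pairs[2, ])
}

#' Validity criteria for a two-point method
#'
#' A combination is valid for a parameter when agreement is good to
#' excellent (lower bound of the single ICC 95% CI at least
#' `icc_lower_min`), there is no systematic bias (paired-t p at least
#' `p_min`), and within-individual error is low (the chosen bound of the CV
#' 95% CI at most `cv_limit_percent`). The screening literature applies the
#' CV criterion to the interval's lower bound; `cv_bound = "upper"` gives
#' the conservative variant.
#'
#' @param icc_lower_min Minimum lower 95% CI bound of the single ICC (0.75).
#' @param p_min Minimum paired-t p-value (0.05).
#' @param cv_limit_percent Maximum CV bound, percent (10).
#' @param cv_bound Which CV CI bound the limit applies to (`"lower"`, the
#'   default, or `"upper"`).
#' @return List of class `screening_criteria`.
#' @export
screening_criteria <- function(icc_lower_min = 0.75, p_min = 0.05,
                               cv_limit_percent = 10,
                               cv_bound = c("lower", "upper")) {
  cv_bound <- match.arg(cv_bound)
  if (p_min < 0 || cv_limit_percent <= 0) {
    abort_isofv("criteria thresholds must be positive", "isofv_error_invalid_parameter")
  }
  structure(list(icc_lower_min = icc_lower_min, p_min = p_min,
                 cv_limit_percent = cv_limit_percent, cv_bound = cv_bound),
            class = "screening_criteria")
}

fv_parameters <- c("F0", "v0", "Sfv", "Pmax")

# Per-subject reference (multi-point linear) and per-combination two-point
# profiles for one task's points table.
subject_profiles <- function(points) {
  split(points, points$subject_id)
}

#' Screen all two-velocity combinations against the multi-point reference
#'
#' For every unordered pair of protocol velocities, fits the per-subject
#' two-point profile and compares each F-v parameter (F0, v0, Sfv, Pmax)
#' with the per-subject multi-point linear profile through the full
#' agreement battery, then applies the validity criteria. Subjects whose
#' two-point profile is non-physical for a combination (force not
#' decreasing at the noisy points) are dropped pairwise for that
#' combination; combinations retaining fewer than 5 subjects are flagged
#' not-evaluable (`valid = NA`), never silently valid.
#'
#' @param points F-v points data.frame with columns `subject_id`, `task`,
#'   `angular_velocity_dps`, `velocity_mps`, `force_n_per_kg23`; every
#'   subject must be measured at every protocol velocity.
#' @param criteria A [screening_criteria()] object.
#' @param velocities Protocol velocities (default: the distinct isokinetic
#'   velocities present in `points`).
#' @param icc_definition Passed to [agreement_report()].
#' @return data.frame with one row per (task, combination, parameter):
#'   agreement statistics, `valid` flag, `overall_valid` (all four
#'   parameters valid for that combination) and exclusion counts. The
#'   attribute `"exclusions"` tabulates dropped subjects per combination.
#' @export
screen_combinations <- function(points, criteria = screening_criteria(),
                                velocities = NULL,
                                icc_definition = c("consistency", "agreement")) {
  icc_definition <- match.arg(icc_definition)
  check_fv_points(points)
  if (is.null(points$subject_id)) {
    abort_isofv("points must carry subject_id", "isofv_error_malformed_input")
  }
  tasks <- unique(points$task)
  out <- list()
  exclusions <- list()
  for (task in tasks) {
    tp <- points[points$task == task, , drop = FALSE]
    vset <- velocities %||% sort(unique(tp$angular_velocity_dps[tp$angular_velocity_dps > 0]))
    combos <- enumerate_combinations(vset)
    subs <- subject_profiles(tp)
    complete <- vapply(subs, function(s) all(vset %in% s$angular_velocity_dps), logical(1))
    if (!all(complete)) {
      warn_isofv(sprintf("%d subject(s) lack some protocol velocity and were excluded",
                         sum(!complete)), "isofv_warning_incomplete_subjects")
      subs <- subs[complete]
    }
    if (length(subs) < 5L) {
      abort_isofv("need at least 5 subjects with complete velocity sets",
                  "isofv_error_insufficient_sample")
    }
    ref <- lapply(subs, function(s) {
      fit_linear(s[s$angular_velocity_dps %in% vset, , drop = FALSE])
    })
    ref_par <- t(vapply(ref, profile_params, c(F0 = 0, v0 = 0, Sfv = 0, Pmax = 0)))
    for (ci in seq_len(nrow(combos))) {
      lo <- combos$low[ci]; hi <- combos$high[ci]
      cand_par <- t(vapply(subs, function(s) {
        pl <- s[s$angular_velocity_dps == lo, , drop = FALSE][1, ]
        ph <- s[s$angular_velocity_dps == hi, , drop = FALSE][1, ]
        tryCatch(profile_params(two_point_profile(pl, ph)),
                 isofv_error = function(e) rep(NA_real_, 4))
      }, c(F0 = 0, v0 = 0, Sfv = 0, Pmax = 0)))
      n_dropped <- sum(!stats::complete.cases(cand_par))
      exclusions[[length(exclusions) + 1L]] <-
        data.frame(task = task, low = lo, high = hi, n_dropped = n_dropped)
      for (par in fv_parameters) {
        rvals <- ref_par[, par]
        cvals <- cand_par[, par]
        keep <- is.finite(rvals) & is.finite(cvals)
        row <- data.frame(task = task, parameter = par, low = lo, high = hi,
                          n = sum(keep), n_dropped = sum(!keep))
        if (sum(keep) < 5L) {
          stat_cols <- c("mean_9p", "sd_9p", "mean_2p", "sd_2p", "bias", "sd_bias",
                         "t", "p", "es", "icc_s", "icc_s_lo", "icc_s_hi",
                         "icc_a", "icc_a_lo", "icc_a_hi", "sem", "cv", "cv_lo",
                         "cv_hi", "mdc")
          row[stat_cols] <- NA_real_
          row$valid <- NA
        } else {
          rep_ <- suppressWarnings(
            agreement_report(rvals[keep], cvals[keep], parameter_label = par,
                             icc_definition = icc_definition)
          )
          row$mean_9p <- rep_$mean_ref; row$sd_9p <- rep_$sd_ref
          row$mean_2p <- rep_$mean_cand; row$sd_2p <- rep_$sd_cand
          row$bias <- rep_$bias; row$sd_bias <- rep_$sd_bias
          row$t <- rep_$t_statistic; row$p <- rep_$p_value; row$es <- rep_$effect_size
          row$icc_s <- rep_$icc_single
          row$icc_s_lo <- rep_$icc_single_ci[1]; row$icc_s_hi <- rep_$icc_single_ci[2]
          row$icc_a <- rep_$icc_average
          row$icc_a_lo <- rep_$icc_average_ci[1]; row$icc_a_hi <- rep_$icc_average_ci[2]
          row$sem <- rep_$sem; row$cv <- rep_$cv_percent
          row$cv_lo <- rep_$cv_ci[1]; row$cv_hi <- rep_$cv_ci[2]
          row$mdc <- rep_$mdc
          cv_b <- if (criteria$cv_bound == "lower") row$cv_lo else row$cv_hi
          row$valid <- (row$icc_s_lo >= criteria$icc_lower_min) &&
            (row$p >= criteria$p_min) &&
            (cv_b <= criteria$cv_limit_percent)
        }
        out[[length(out) + 1L]] <- row
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  # overall flag: conjunction of the four per-parameter flags of a combination
  key <- interaction(res$task, res$low, res$high, drop = TRUE)
  overall <- tapply(res$valid, key, function(v) if (anyNA(v)) NA else all(v))
  res$overall_valid <- as.logical(overall[as.character(key)])
  attr(res, "exclusions") <- do.call(rbind, exclusions)
  attr(res, "criteria") <- criteria
  class(res) <- c("screening_result", class(res))
  res
}

#' Rank screened combinations for one parameter
#'
#' Valid combinations first, then by descending single ICC, then ascending
#' CV%, with a deterministic `(low, high)` tie-break. Not-evaluable
#' combinations sort last.
#'
#' @param results Output of [screen_combinations()].
#' @param parameter One of `"F0"`, `"v0"`, `"Sfv"`, `"Pmax"`.
#' @param task Optional task filter.
#' @return The filtered, ordered data.frame.
#' @export
rank_results <- function(results, parameter, task = NULL) {
  if (is.null(results) || nrow(results) == 0L) {
    abort_isofv("no screening results to rank", "isofv_error_precondition")
  }
  stopifnot(parameter %in% fv_parameters)
  r <- results[results$parameter == parameter, , drop = FALSE]
  if (!is.null(task)) r <- r[r$task == task, , drop = FALSE]
  valid_key <- ifelse(is.na(r$valid), -1L, as.integer(r$valid))
  icc_key <- ifelse(is.na(r$icc_s), -Inf, r$icc_s)
  cv_key <- ifelse(is.na(r$cv), Inf, r$cv)
  r[order(-valid_key, -icc_key, cv_key, r$low, r$high), , drop = FALSE]
}
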
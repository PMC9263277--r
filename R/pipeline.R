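# Pipeline entry points tying the stages together, plus format-stable I/O.

#' Per-subject profiling run: linear vs polynomial fit, F0 vs isometric
#'
#' Fits the multi-point linear and quadratic polynomial profile for every
#' subject, compares the two methods' fit quality on the Fisher-z scale
#' with a paired t-test (skipped with a reason when any fit is exact, since
#' z' is then infinite), and, when isometric data are supplied, compares
#' extrapolated linear/polynomial F0 with measured isometric force.
#'
#' @param points F-v points data.frame (`subject_id`, `task`,
#'   `angular_velocity_dps`, `velocity_mps`, `force_n_per_kg23`).
#' @param isometric Optional data.frame `subject_id`, `task`,
#'   `iso_force_n_per_kg23` (see [cohort_isometric()]).
#' @return List of class `profile_run`: `profiles` (one row per subject x
#'   task x method), `fit_comparison` (per task: paired t on z' of linear
#'   minus polynomial, or a skip reason), `f0_vs_isometric` (per task and
#'   method: mean difference/ratio and paired t), `excluded` subjects.
#' @export
run_profile <- function(points, isometric = NULL) {
  check_fv_points(points)
  if (nrow(points) == 0L) {
    abort_isofv("empty input: no F-v points", "isofv_error_empty_input")
  }
  tasks <- unique(points$task)
  profiles <- list()
  excluded <- list()
  for (task in tasks) {
    tp <- points[points$task == task, , drop = FALSE]
    vset <- sort(unique(tp$angular_velocity_dps[tp$angular_velocity_dps > 0]))
    for (s in split(tp, tp$subject_id)) {
      sid <- s$subject_id[1]
      if (!all(vset %in% s$angular_velocity_dps)) {
        excluded[[length(excluded) + 1L]] <- data.frame(
          subject_id = sid, task = task,
          reason = "missing protocol velocity")
        next
      }
      lin <- fit_linear(s)
      pol <- fit_polynomial(s)
      profiles[[length(profiles) + 1L]] <- do.call(rbind, lapply(list(lin, pol), function(p) {
        data.frame(subject_id = sid, task = task, method = p$method,
                   velocities_used = paste(p$velocities_used, collapse = ";"),
                   F0 = p$F0, v0 = p$v0, Sfv = p$Sfv, Pmax = p$Pmax,
                   r = p$fit$r, r2 = p$fit$r_squared, z_prime = p$fit$z_prime)
      }))
    }
  }
  profiles <- do.call(rbind, profiles)
  if (is.null(profiles)) {
    abort_isofv("no subject had a complete velocity set", "isofv_error_empty_input")
  }
  rownames(profiles) <- NULL

  fit_comparison <- lapply(stats::setNames(nm = tasks), function(task) {
    lin <- profiles[profiles$task == task & grepl("^linear", profiles$method), ]
    pol <- profiles[profiles$task == task & profiles$method == "polynomial_9pt", ]
    z_lin <- lin$z_prime[order(lin$subject_id)]
    z_pol <- pol$z_prime[order(pol$subject_id)]
    if (any(!is.finite(z_lin)) || any(!is.finite(z_pol))) {
      return(list(skipped = TRUE,
                  reason = "exact fit(s) present: z' infinite, comparison undefined"))
    }
    pc <- paired_comparison(z_lin, z_pol, parameter_label = "z_prime")
    c(list(skipped = FALSE), pc)
  })

  f0_vs_isometric <- NULL
  if (!is.null(isometric)) {
    f0_vs_isometric <- do.call(rbind, lapply(tasks, function(task) {
      iso <- isometric[isometric$task == task, ]
      do.call(rbind, lapply(unique(profiles$method), function(m) {
        pr <- profiles[profiles$task == task & profiles$method == m, ]
        merged <- merge(pr[, c("subject_id", "F0")],
                        iso[, c("subject_id", "iso_force_n_per_kg23")],
                        by = "subject_id")
        cmp <- compare_f0_to_isometric(merged$F0, merged$iso_force_n_per_kg23)
        pc <- paired_comparison(merged$F0, merged$iso_force_n_per_kg23)
        data.frame(task = task, method = m, n = nrow(merged),
                   mean_difference = mean(cmp$difference),
                   mean_ratio = mean(cmp$ratio),
                   prop_underestimating = mean(cmp$ratio < 1),
                   t = pc$t, p = pc$p)
      }))
    }))
  }
  structure(
    list(profiles = profiles, fit_comparison = fit_comparison,
         f0_vs_isometric = f0_vs_isometric,
         excluded = if (length(excluded)) do.call(rbind, excluded) else NULL),
    class = "profile_run"
  )
}

#' Full two-point screening run
#'
#' Thin orchestration over [screen_combinations()] + [rank_results()] with
#' run metadata attached (package version, criteria, timestamp-free config
#' fingerprint) so a rerun on the same inputs is reproducible.
#'
#' @inheritParams screen_combinations
#' @return List of class `screen_run`: `table` (the screening data.frame),
#'   `ranked` (per task x parameter ranked tables), `metadata`.
#' @export
run_screen <- function(points, criteria = screening_criteria(),
                       velocities = NULL,
                       icc_definition = c("consistency", "agreement")) {
  icc_definition <- match.arg(icc_definition)
  tab <- screen_combinations(points, criteria, velocities, icc_definition)
  tasks <- unique(tab$task)
  ranked <- list()
  for (task in tasks) {
    for (par in fv_parameters) {
      ranked[[paste(task, par, sep = ".")]] <- rank_results(tab, par, task)
    }
  }
  meta <- list(
    package_version = as.character(utils::packageVersion("isofv")),
    criteria = unclass(criteria),
    icc_definition = icc_definition,
    n_points = nrow(points),
    config_hash = sum(as.integer(charToRaw(paste(
      format(criteria$icc_lower_min), format(criteria$p_min),
      format(criteria$cv_limit_percent), criteria$cv_bound, icc_definition
    )))))
  structure(list(table = tab, ranked = ranked, metadata = meta),
            class = "screen_run")
}

# ---- I/O --------------------------------------------------------------

#' Read / write the F-v points table
#'
#' CSV with header `subject_id,task,angular_velocity_dps,velocity_mps,
#' force_n_per_kg23`, decimal point, comma separator, UTF-8.
#'
#' @param path File path.
#' @param points Points data.frame (for the writer).
#' @return The points data.frame (reader) or `path` invisibly (writer).
#' @export
read_points_csv <- function(path) {
  pts <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_fv_points(pts)
  pts
}

#' @rdname read_points_csv
#' @export
write_points_csv <- function(points, path) {
  check_fv_points(points)
  utils::write.csv(format_num_df(points), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the screening table as CSV
#'
#' Columns mirror the published validity-table layout (means, bias, t, p,
#' ES, both ICC forms with CIs, SEM, CV with CI, MDC, validity flag).
#'
#' @param results Output of [screen_combinations()].
#' @param path File path.
#' @export
write_screening_csv <- function(results, path) {
  utils::write.csv(format_num_df(as.data.frame(results)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write one or more agreement reports as JSON
#'
#' @param reports A single [agreement_report()] or a named list of them.
#' @param path File path.
#' @export
write_agreement_json <- function(reports, path) {
  if (inherits(reports, "agreement_report")) reports <- list(reports)
  payload <- lapply(reports, function(r) {
    r$bland_altman_pairs <- NULL
    unclass(r)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 6, pretty = TRUE)
  invisible(path)
}

# 6 significant digits for serialized floating-point columns.
format_num_df <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- signif(df[[nm]], 6)
  }
  df
}
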
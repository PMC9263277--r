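#' Detect isokinetic plateaus in a trace
#'
#' Finds the maximal runs of samples where the achieved angular velocity is
#' within `tolerance_fraction` of the protocol velocity and the run lasts at
#' least `min_duration` seconds -- one window per repetition, in temporal
#' order. If no velocity channel is present, velocity is derived from the
#' angle channel by central differences followed by the same low-pass filter
#' applied to torque.
#'
#' Window indices are 1-based and inclusive on both ends.
#'
#' @param trace A [torque_trace()] with `protocol_velocity > 0` and at least
#'   one of the velocity / angle channels.
#' @param tolerance_fraction Allowed relative deviation from the protocol
#'   velocity (default 0.05, i.e. a 5 percent band).
#' @param min_duration Minimum plateau duration in seconds (default 0.05).
#' @param cutoff,order Low-pass settings for the derived-velocity path.
#' @return A data.frame with one row per repetition window: `start_index`,
#'   `end_index`, `achieved_velocity`.
#' @export
detect_isokinetic_window <- function(trace, tolerance_fraction = 0.05,
                                     min_duration = 0.05,
                                     cutoff = 5, order = 2) {
  stopifnot(inherits(trace, "torque_trace"))
  vp <- trace$protocol_velocity
  if (vp <= 0) {
    abort_isofv("isokinetic window detection requires protocol_velocity > 0",
                "isofv_error_precondition")
  }
  if (!is.null(trace$velocity)) {
    v <- trace$velocity
  } else if (!is.null(trace$angle)) {
    v <- derive_velocity(trace$angle, trace$sampling_rate, cutoff, order)
  } else {
    abort_isofv("trace has neither a velocity nor an angle channel",
                "isofv_error_precondition")
  }
  v <- abs(v)
  ok <- abs(v - vp) <= tolerance_fraction * vp
  min_len <- max(1L, as.integer(round(min_duration * trace$sampling_rate)))
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_len
  if (!any(keep)) {
    abort_isofv(
      sprintf("no isokinetic plateau found at %g deg/s (tolerance %g%%, min %g ms)",
              vp, 100 * tolerance_fraction, 1000 * min_duration),
      "isofv_error_no_plateau"
    )
  }
  s <- starts[keep]
  e <- ends[keep]
  data.frame(
    start_index = s,
    end_index = e,
    achieved_velocity = vapply(seq_along(s), function(i) mean(v[s[i]:e[i]]), numeric(1))
  )
}

# Angular velocity (deg/s) from an angle channel (deg): central differences,
# one-sided at the ends, then the same zero-phase Butterworth as the torque.
derive_velocity <- function(angle, sampling_rate, cutoff = 5, order = 2) {
  n <- length(angle)
  v <- numeric(n)
  v[1] <- (angle[2] - angle[1]) * sampling_rate
  v[n] <- (angle[n] - angle[n - 1]) * sampling_rate
  if (n > 2) {
    v[2:(n - 1)] <- (angle[3:n] - angle[1:(n - 2)]) * sampling_rate / 2
  }
  ba <- butter_lowpass(order, cutoff, sampling_rate)
  filtfilt_bw(ba$b, ba$a, v, as.integer(ceiling(3 * sampling_rate / cutoff)))
}

#' Extract the peak torque of each repetition window
#'
#' @param trace A (typically filtered) [torque_trace()].
#' @param windows Window table from [detect_isokinetic_window()]; must be
#'   non-empty and pairwise disjoint.
#' @return A data.frame: `repetition` (1-based, temporal order),
#'   `peak_torque`, `peak_index`.
#' @export
extract_repetition_peaks <- function(trace, windows) {
  stopifnot(inherits(trace, "torque_trace"))
  if (is.null(windows) || nrow(windows) == 0L) {
    abort_isofv("window list is empty", "isofv_error_precondition")
  }
  o <- order(windows$start_index)
  windows <- windows[o, , drop = FALSE]
  if (any(windows$end_index < windows$start_index) ||
      any(windows$end_index > length(trace$torque))) {
    abort_isofv("window indices out of range", "isofv_error_precondition")
  }
  if (nrow(windows) > 1L &&
      any(windows$start_index[-1L] <= windows$end_index[-nrow(windows)])) {
    abort_isofv("windows must be disjoint", "isofv_error_precondition")
  }
  peaks <- lapply(seq_len(nrow(windows)), function(i) {
    idx <- windows$start_index[i]:windows$end_index[i]
    j <- which.max(trace$torque[idx])
    data.frame(repetition = i, peak_torque = trace$torque[idx[j]], peak_index = idx[j])
  })
  do.call(rbind, peaks)
}

#' Select the best repetition peak from the analysed repetitions
#'
#' Only the final `consider_last` repetitions of a set enter the analysis
#' (the opening repetitions serve as ramp-up); the maximum peak among them is
#' returned, ties broken toward the earlier repetition.
#'
#' @param peaks Peak table from [extract_repetition_peaks()].
#' @param consider_last How many final repetitions to consider (default 4).
#' @return The selected single-row peak table.
#' @export
select_best_peak <- function(peaks, consider_last = 4) {
  if (is.null(peaks) || nrow(peaks) < consider_last) {
    abort_isofv(
      sprintf("need at least %d repetitions, got %d", consider_last,
              if (is.null(peaks)) 0L else nrow(peaks)),
      "isofv_error_insufficient_repetitions"
    )
  }
  tail_peaks <- peaks[(nrow(peaks) - consider_last + 1L):nrow(peaks), , drop = FALSE]
  best <- which.max(tail_peaks$peak_torque)  # which.max: earliest on ties
  tail_peaks[best, , drop = FALSE]
}

#' Peak torque of an isometric trial
#'
#' Filters the trace (unless `apply_filter = FALSE`) and returns the maximum
#' torque over the whole record. Trials shorter than 3 s are still evaluated
#' but flagged (attribute `short_duration`) with a warning, since the
#' protocol asks for at least 3 s of maximal exertion.
#'
#' @param trace A [torque_trace()] with `protocol_velocity == 0`.
#' @param cutoff,order Low-pass settings (defaults 5 Hz, order 2).
#' @param apply_filter Set `FALSE` if the trace is already filtered.
#' @return Peak torque (N m) with logical attribute `short_duration`.
#' @export
isometric_peak <- function(trace, cutoff = 5, order = 2, apply_filter = !isTRUE(trace$filtered)) {
  stopifnot(inherits(trace, "torque_trace"))
  if (trace$protocol_velocity != 0) {
    abort_isofv("isometric_peak requires protocol_velocity == 0",
                "isofv_error_precondition")
  }
  short <- trace_duration(trace) < 3
  if (short) {
    warn_isofv(sprintf("isometric trial lasts %.2f s (< 3 s); value flagged",
                       trace_duration(trace)),
               "isofv_warning_short_duration")
  }
  if (apply_filter) trace <- lowpass_filter(trace, cutoff, order)
  structure(max(trace$torque), short_duration = short)
}
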
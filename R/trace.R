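#' Construct a torque-time trace
#'
#' A `torque_trace` is a uniformly sampled dynamometer record: torque in
#' newton-meters against time in seconds, with optional angular-velocity
#' (deg/s) and joint-angle (deg) channels. `protocol_velocity` is the
#' dynamometer's set angular velocity for the trial (0 for isometric trials).
#'
#' @param torque Numeric vector, newton-meters. Must be finite throughout.
#' @param sampling_rate Sampling frequency in Hz (nominally 500).
#' @param protocol_velocity Set angular velocity in deg/s; 0 for isometric.
#' @param task `"KE"` (knee extension) or `"KF"` (knee flexion).
#' @param time Optional explicit time vector (seconds). Must be a strictly
#'   increasing uniform grid consistent with `sampling_rate` to within one
#'   part in 1e6; built from `sampling_rate` when omitted.
#' @param velocity Optional angular-velocity channel, deg/s, same length.
#' @param angle Optional joint-angle channel, degrees, same length.
#' @param subject_id Optional subject identifier carried as metadata.
#' @return An object of class `torque_trace`.
#' @export
torque_trace <- function(torque, sampling_rate, protocol_velocity,
                         task = c("KE", "KF"), time = NULL,
                         velocity = NULL, angle = NULL, subject_id = NULL) {
  task <- match.arg(task)
  torque <- as.numeric(torque)
  n <- length(torque)
  if (n < 2L) {
    abort_isofv("a torque trace needs at least 2 samples", "isofv_error_malformed_input")
  }
  if (!all(is.finite(torque))) {
    abort_isofv("torque must be finite everywhere", "isofv_error_malformed_input")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0) {
    abort_isofv("sampling_rate must be a positive scalar", "isofv_error_invalid_parameter")
  }
  if (is.null(time)) {
    time <- (seq_len(n) - 1L) / sampling_rate
  } else {
    if (length(time) != n) {
      abort_isofv("time and torque must have equal length", "isofv_error_malformed_input")
    }
    dt <- diff(time)
    if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * mean(dt)) {
      abort_isofv("time grid must be strictly increasing and uniform to 1e-6",
                  "isofv_error_malformed_input")
    }
    if (abs(mean(dt) - 1 / sampling_rate) > 1e-6 / sampling_rate) {
      abort_isofv("time grid spacing inconsistent with sampling_rate",
                  "isofv_error_malformed_input")
    }
  }
  if (!is.null(velocity) && length(velocity) != n) {
    abort_isofv("velocity channel length mismatch", "isofv_error_malformed_input")
  }
  if (!is.null(angle) && length(angle) != n) {
    abort_isofv("angle channel length mismatch", "isofv_error_malformed_input")
  }
  if (protocol_velocity < 0) {
    abort_isofv("protocol_velocity must be >= 0", "isofv_error_invalid_parameter")
  }
  structure(
    list(time = time, torque = torque, velocity = velocity, angle = angle,
         sampling_rate = sampling_rate, protocol_velocity = protocol_velocity,
         task = task, subject_id = subject_id, filtered = FALSE),
    class = "torque_trace"
  )
}

#' @export
print.torque_trace <- function(x, ...) {
  dur <- length(x$torque) / x$sampling_rate
  cat(sprintf(
    "<torque_trace> %s @ %g deg/s | %d samples, %.2f s @ %g Hz | peak %.1f N m%s\n",
    x$task, x$protocol_velocity, length(x$torque), dur, x$sampling_rate,
    max(x$torque), if (isTRUE(x$filtered)) " | filtered" else ""
  ))
  invisible(x)
}

trace_duration <- function(trace) length(trace$torque) / trace$sampling_rate
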
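# Butterworth low-pass filtering.
#
# No signal-processing package is assumed: the digital Butterworth design
# (bilinear transform of the analog prototype) and the zero-phase
# forward-backward pass (odd-reflection padding + steady-state initial
# conditions, so a constant input is reproduced exactly) are implemented here
# and verified in the tests against the analytic magnitude response.

# Polynomial coefficients (descending powers, leading 1) from complex roots.
poly_from_roots <- function(roots) {
  coef <- 1 + 0i
  for (r in roots) {
    coef <- c(coef, 0 + 0i) - c(0 + 0i, coef * r)
  }
  coef
}

# Digital Butterworth low-pass (b, a) for a given order, cutoff and sampling
# rate. Poles of the analog prototype are prewarped and mapped with the
# bilinear transform; all zeros sit at z = -1; gain normalized to unity at DC.
butter_lowpass <- function(order, cutoff, sampling_rate) {
  if (order < 1 || order != round(order)) {
    abort_isofv("filter order must be a positive integer", "isofv_error_invalid_parameter")
  }
  if (cutoff <= 0 || cutoff >= sampling_rate / 2) {
    abort_isofv(
      sprintf("cutoff (%g Hz) must lie in (0, Nyquist = %g Hz)", cutoff, sampling_rate / 2),
      "isofv_error_invalid_parameter"
    )
  }
  warped <- tan(pi * cutoff / sampling_rate)
  k <- seq_len(order)
  theta <- pi * (2 * k + order - 1) / (2 * order)
  p_analog <- warped * exp(1i * theta)
  p_digital <- (1 + p_analog) / (1 - p_analog)
  a <- Re(poly_from_roots(p_digital))
  b_raw <- choose(order, 0:order)  # zeros at z = -1: (1 + z^-1)^order
  gain <- sum(a) / sum(b_raw)
  list(b = b_raw * gain, a = a)
}

# Direct-form II transposed IIR filter with optional initial state.
iir_filter <- function(b, a, x, zi = NULL) {
  nfilt <- max(length(a), length(b))
  b <- c(b, numeric(nfilt - length(b)))
  a <- c(a, numeric(nfilt - length(a)))
  b <- b / a[1]
  a <- a / a[1]
  z <- if (is.null(zi)) numeric(nfilt - 1L) else zi
  y <- numeric(length(x))
  ns <- nfilt - 1L
  for (m in seq_along(x)) {
    xm <- x[m]
    ym <- b[1] * xm + z[1]
    if (ns > 1L) {
      for (i in seq_len(ns - 1L)) {
        z[i] <- b[i + 1L] * xm + z[i + 1L] - a[i + 1L] * ym
      }
    }
    z[ns] <- b[nfilt] * xm - a[nfilt] * ym
    y[m] <- ym
  }
  list(y = y, z = z)
}

# Steady-state initial filter state for a unit step (so filtering a constant
# c with state c * zi yields c from the first sample).
iir_steady_state <- function(b, a) {
  nfilt <- max(length(a), length(b))
  b <- c(b, numeric(nfilt - length(b)))
  a <- c(a, numeric(nfilt - length(a)))
  b <- b / a[1]
  a <- a / a[1]
  ns <- nfilt - 1L
  comp <- matrix(0, ns, ns)
  comp[1, ] <- -a[2:nfilt]
  if (ns > 1L) comp[cbind(2:ns, 1:(ns - 1L))] <- 1
  rhs <- b[2:nfilt] - a[2:nfilt] * b[1]
  solve(diag(ns) - t(comp), rhs)
}

# Zero-phase forward-backward filtering with odd-reflection edge padding.
# padlen should cover the filter's settling time so edge transients decay
# inside the pads; callers that know the cutoff pass ~3 periods of it.
filtfilt_bw <- function(b, a, x, padlen = 3L * max(length(a), length(b))) {
  n <- length(x)
  padlen <- min(padlen, n - 1L)
  if (padlen > 0L) {
    front <- 2 * x[1] - x[(padlen + 1L):2L]
    back <- 2 * x[n] - x[(n - 1L):(n - padlen)]
    ext <- c(front, x, back)
  } else {
    ext <- x
  }
  zi <- iir_steady_state(b, a)
  fwd <- iir_filter(b, a, ext, zi * ext[1])$y
  rev_in <- rev(fwd)
  bwd <- iir_filter(b, a, rev_in, zi * rev_in[1])$y
  out <- rev(bwd)
  out[(padlen + 1L):(padlen + n)]
}

#' Zero-phase Butterworth low-pass filter for a torque trace
#'
#' Applies an order-`order` digital Butterworth low-pass (default 2nd order,
#' 5 Hz) forward and backward, so the effective response is zero-phase with
#' squared magnitude; peak timing is preserved and the DC component passes
#' unchanged. Only the torque channel is filtered.
#'
#' @param trace A [torque_trace()].
#' @param cutoff Cutoff frequency in Hz (default 5). Must be below Nyquist.
#' @param order Filter order per pass (default 2).
#' @return The trace with filtered torque; `$filtered` is set to `TRUE`.
#' @export
lowpass_filter <- function(trace, cutoff = 5, order = 2) {
  stopifnot(inherits(trace, "torque_trace"))
  if (cutoff >= trace$sampling_rate / 2) {
    abort_isofv(
      sprintf("cutoff %g Hz is at or above Nyquist (%g Hz)", cutoff, trace$sampling_rate / 2),
      "isofv_error_invalid_parameter"
    )
  }
  if (length(trace$torque) < 3 * (order + 1)) {
    abort_isofv("trace too short to filter at this order", "isofv_error_malformed_input")
  }
  ba <- butter_lowpass(order, cutoff, trace$sampling_rate)
  padlen <- as.integer(ceiling(3 * trace$sampling_rate / cutoff))
  trace$torque <- filtfilt_bw(ba$b, ba$a, trace$torque, padlen)
  trace$filtered <- TRUE
  trace
}
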
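#' Subject anthropometrics
#'
#' @param subject_id Identifier (coerced to character).
#' @param body_mass Body mass in kg (> 0).
#' @param lever_length Dynamometer lever arm in meters (0.1 to 0.6; the pad
#'   sits at the distal tibia, so adult values cluster around 0.3-0.4 m).
#' @return A list of class `anthropometrics`.
#' @export
anthropometrics <- function(subject_id, body_mass, lever_length) {
  if (!is.numeric(body_mass) || body_mass <= 0) {
    abort_isofv("body_mass must be > 0 kg", "isofv_error_invalid_parameter")
  }
  if (!is.numeric(lever_length) || lever_length <= 0.1 || lever_length >= 0.6) {
    abort_isofv("lever_length must lie in (0.1, 0.6) m", "isofv_error_invalid_parameter")
  }
  structure(
    list(subject_id = as.character(subject_id), body_mass = body_mass,
         lever_length = lever_length),
    class = "anthropometrics"
  )
}

#' Convert peak torque at an angular velocity to a normalized F-v point
#'
#' Force is torque divided by the lever length, then allometrically
#' normalized by body mass to the 2/3 power (N kg^-2/3); linear velocity is
#' the angular velocity converted to radians per second times the lever
#' length (m/s). Vectorized over `peak_torque` / `angular_velocity`.
#'
#' @param peak_torque Peak torque(s), N m, all > 0.
#' @param angular_velocity Angular velocity(ies), deg/s, >= 0 (0 = isometric).
#' @param anthro An [anthropometrics()] object.
#' @param task Optional task label carried into the output.
#' @return A data.frame of F-v points with columns `subject_id`, `task`,
#'   `angular_velocity_dps`, `velocity_mps`, `force_n_per_kg23`.
#' @export
to_fv_point <- function(peak_torque, angular_velocity, anthro, task = NA_character_) {
  stopifnot(inherits(anthro, "anthropometrics"))
  if (any(!is.finite(peak_torque)) || any(peak_torque <= 0)) {
    abort_isofv("peak_torque must be finite and > 0", "isofv_error_invalid_measurement")
  }
  if (any(angular_velocity < 0)) {
    abort_isofv("angular_velocity must be >= 0", "isofv_error_invalid_parameter")
  }
  if (length(peak_torque) != length(angular_velocity)) {
    peak_torque <- rep_len(peak_torque, length(angular_velocity))
  }
  data.frame(
    subject_id = anthro$subject_id,
    task = task,
    angular_velocity_dps = angular_velocity,
    velocity_mps = angular_velocity * pi / 180 * anthro$lever_length,
    force_n_per_kg23 = (peak_torque / anthro$lever_length) / anthro$body_mass^(2 / 3)
  )
}

# Validate an F-v points data.frame (the package's tabular lingua franca).
check_fv_points <- function(points) {
  need <- c("velocity_mps", "force_n_per_kg23")
  if (!is.data.frame(points) || !all(need %in% names(points))) {
    abort_isofv(
      "points must be a data.frame with columns velocity_mps and force_n_per_kg23",
      "isofv_error_malformed_input"
    )
  }
  invisible(points)
}
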
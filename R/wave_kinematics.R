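#' Wave kinematics parameterization
#'
#' Inward actomyosin contraction waves are summarized by two affine laws in
#' droplet diameter `D` (um): the wave period `T(D) = a_T * D + b_T` (s) and
#' the initial contraction velocity `v(D) = a_v * D + b_v` (um/s). The fitted
#' velocity line crosses zero near D ~ 80 um while waves are still observed
#' in smaller droplets, so evaluated velocities are clamped below at `v_min`.
#'
#' @param a_T Period slope (s/um).
#' @param b_T Period intercept (s).
#' @param a_v Velocity slope (um/s per um).
#' @param b_v Velocity intercept (um/s).
#' @param condition Label for the condition the fit describes.
#' @param v_min Velocity floor (um/s), default 0.05.
#'
#' @return An object of class `wave_kinematics`.
#' @examples
#' w <- wave_kinematics(2.5e-2, 39, 1.6e-2, -1.3, condition = "control")
#' wave_period(100, w)
#' @export
wave_kinematics <- function(a_T, b_T, a_v, b_v, condition = "custom",
                            v_min = 0.05) {
  check_number(a_T, "a_T")
  check_number(b_T, "b_T")
  check_number(a_v, "a_v")
  check_number(b_v, "b_v")
  check_positive(v_min, "v_min")
  obj <- structure(
    list(a_T = a_T, b_T = b_T, a_v = a_v, b_v = b_v,
         condition = condition, v_min = v_min),
    class = "wave_kinematics"
  )
  # period must stay positive across the droplet sizes the model covers
  if (any(c(a_T * 16 + b_T, a_T * 330 + b_T) <= 0)) {
    abort("Wave period is non-positive somewhere on D in [16, 330] um.",
          class = "actotug_invalid_parameter")
  }
  obj
}

#' @export
print.wave_kinematics <- function(x, ...) {
  cat(sprintf("<wave_kinematics: %s>\n", x$condition))
  cat(sprintf("  T(D) = %g * D + %g s\n  v(D) = %g * D + %g um/s (floor %g)\n",
              x$a_T, x$b_T, x$a_v, x$b_v, x$v_min))
  invisible(x)
}

#' Wave period at a droplet diameter
#'
#' @param D Droplet diameter (um), > 0; vectorized.
#' @param waves A [wave_kinematics()] object.
#' @return Period in seconds.
#' @examples
#' wave_period(100, condition_waves("control")) # 41.5 s
#' @export
wave_period <- function(D, waves) {
  stopifnot(inherits(waves, "wave_kinematics"))
  if (any(D < 0)) {
    abort("`D` must be non-negative.", class = "actotug_invalid_parameter")
  }
  period <- waves$a_T * D + waves$b_T
  if (any(period <= 0)) {
    abort("Predicted wave period is non-positive.",
          class = "actotug_invalid_parameter")
  }
  period
}

#' Initial wave contraction velocity at a droplet diameter
#'
#' Affine fit clamped below at the configured `v_min` floor.
#'
#' @inheritParams wave_period
#' @return Velocity in um/s.
#' @examples
#' wave_velocity(200, condition_waves("control")) # 1.9 um/s
#' @export
wave_velocity <- function(D, waves) {
  stopifnot(inherits(waves, "wave_kinematics"))
  if (any(D < 0)) {
    abort("`D` must be non-negative.", class = "actotug_invalid_parameter")
  }
  pmax(waves$v_min, waves$a_v * D + waves$b_v)
}

#' Radial position of an inward wave front
#'
#' A front is born at the droplet boundary and travels inward at the constant
#' initial velocity `v(D)` until it reaches the centre; position is clamped
#' at 0.
#'
#' @param t_since_birth Time since the front was born (s), >= 0; vectorized.
#' @inheritParams wave_period
#' @return Radial distance from the droplet centre (um).
#' @export
front_position <- function(t_since_birth, D, waves) {
  if (any(t_since_birth < 0)) {
    abort("`t_since_birth` must be >= 0.", class = "actotug_invalid_parameter")
  }
  pmax(0, D / 2 - wave_velocity(D, waves) * t_since_birth)
}
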
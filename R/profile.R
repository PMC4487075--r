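#' Stimulus velocity/acceleration profile
#'
#' Builds the motion profile of one trial: a Gaussian-bell velocity,
#' peak-normalized, together with its (peak-normalized) time derivative.
#' The bell is centred at half the stimulus duration with standard
#' deviation `width_frac * duration_s`; the edge value is subtracted and
#' clamped at zero so the profile starts and ends exactly at rest.
#'
#' The velocity profile drives the visual (optic-flow) evidence stream;
#' the acceleration profile drives the vestibular (inertial) stream.
#'
#' @param duration_s stimulus duration in seconds (default 2).
#' @param dt_s time grid step in seconds; must be at most `duration_s/100`.
#' @param width_frac bell standard deviation as a fraction of duration,
#'   in (0, 0.5).
#' @return An object of class `stimulus_profile`: list with `t` (time
#'   grid, seconds), `v` (velocity, peak 1), `a` (signed acceleration,
#'   peak magnitude 1), `dt_s`, `duration_s`.
#' @examples
#' pr <- make_stimulus_profile(2, 0.001, 1/6)
#' max(pr$v) # 1
#' @export
make_stimulus_profile <- function(duration_s = 2, dt_s = 0.001,
                                  width_frac = 1 / 6) {
  if (!is.finite(duration_s) || duration_s <= 0)
    stop("`duration_s` must be a positive finite number", call. = FALSE)
  if (!is.finite(dt_s) || dt_s <= 0 || dt_s > duration_s / 100)
    stop("`dt_s` must be in (0, duration_s/100]", call. = FALSE)
  if (!is.finite(width_frac) || width_frac <= 0 || width_frac >= 0.5)
    stop("`width_frac` must be in (0, 0.5)", call. = FALSE)
  t <- seq(0, duration_s, by = dt_s)
  sig <- width_frac * duration_s
  v_raw <- exp(-(t - duration_s / 2)^2 / (2 * sig^2))
  v_raw <- pmax(v_raw - v_raw[1], 0)   # exact rest at the endpoints
  # central-difference derivative of the unnormalized velocity
  # (antisymmetric about the peak for this symmetric bell)
  n <- length(v_raw)
  a_raw <- numeric(n)
  a_raw[2:(n - 1)] <- (v_raw[3:n] - v_raw[1:(n - 2)]) / (2 * dt_s)
  a_raw[1] <- (v_raw[2] - v_raw[1]) / dt_s
  a_raw[n] <- (v_raw[n] - v_raw[n - 1]) / dt_s
  structure(
    list(t = t, v = v_raw / max(v_raw), a = a_raw / max(abs(a_raw)),
         dt_s = dt_s, duration_s = duration_s),
    class = "stimulus_profile"
  )
}

#' @export
print.stimulus_profile <- function(x, ...) {
  cat("<stimulus_profile> duration", x$duration_s, "s, dt", x$dt_s,
      "s,", length(x$t), "samples\n")
  invisible(x)
}
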
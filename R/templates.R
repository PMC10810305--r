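# Within-cycle mechanical templates. All are smooth periodic functions of
# gait-cycle phase (0-100%, heel contact at 0). Angle conventions:
# dorsiflexion positive for the ankle, flexion positive for knee/hip.
# Moments are plantarflexion-positive (ankle) / extension-positive
# (knee, hip), in Nm/kg.

periodic_template <- function(phase_pts, values) {
  stopifnot(phase_pts[1] == 0, phase_pts[length(phase_pts)] == 100,
            values[1] == values[length(values)])
  splinefun(phase_pts, values, method = "periodic")
}

# Sagittal ankle angle (deg, dorsiflexion +): slight plantarflexion at
# loading, progressive dorsiflexion through midstance peaking ~5 deg, rapid
# plantarflexion at push-off to -20 deg just after toe-off, return through
# swing. Range of motion 25 deg (5 DF to 20 PF).
ankle_angle_template <- function() {
  periodic_template(
    c(0, 8, 20, 35, 48, 55, 62, 72, 86, 100),
    c(0, -4, 1, 4, 5, -3, -20, -9, -2, 0)
  )
}

# Total sagittal ankle moment (Nm/kg, plantarflexion +): small dorsiflexor
# moment at loading, plantarflexor moment building to ~0.9 Nm/kg in late
# stance, collapsing through push-off, zero in swing.
ankle_moment_template <- function() {
  periodic_template(
    c(0, 5, 12, 25, 40, 46, 52, 58, 64, 72, 100),
    c(0, -0.05, 0.10, 0.42, 0.60, 0.65, 0.47, 0.24, 0.06, 0, 0)
  )
}

knee_angle_template <- function() {
  periodic_template(
    c(0, 8, 15, 40, 62, 73, 85, 100),
    c(5, 18, 15, 5, 35, 62, 25, 5)
  )
}

knee_moment_template <- function() {
  periodic_template(
    c(0, 10, 18, 40, 55, 70, 100),
    c(0, 0.45, 0.25, -0.05, 0.15, 0, 0)
  )
}

hip_angle_template <- function() {
  periodic_template(
    c(0, 30, 52, 68, 88, 100),
    c(28, 5, -12, 5, 26, 28)
  )
}

hip_moment_template <- function() {
  periodic_template(
    c(0, 12, 30, 50, 62, 75, 100),
    c(0.3, 0.5, 0.05, -0.5, -0.2, 0, 0.3)
  )
}

# Vertical GRF template on stance-normalized time s in [0,1], in units of
# body weight; classic double hump, zero at heel contact and toe-off,
# strictly positive inside stance. Linear interpolation keeps it positive
# between positive knots.
grf_stance_template <- function(s) {
  knots_s <- c(0, 0.08, 0.25, 0.45, 0.60, 0.75, 0.92, 1)
  knots_f <- c(0, 0.75, 1.10, 0.85, 0.90, 1.08, 0.50, 0)
  approx(knots_s, knots_f, xout = pmin(pmax(s, 0), 1))$y
}

#' Evaluate a Gaussian-burst EMG envelope template
#'
#' Sums Gaussian bursts (periodic in cycle phase) on a 0--100% phase grid.
#' With no bursts the envelope is identically zero.
#'
#' @param muscle_params Data frame with columns `center`, `width` (Gaussian
#'   SD), `amp` -- one row per burst; `center`/`width` in %cycle, `amp` in mV.
#' @param phase_grid Numeric vector of cycle phases in \[0, 100\].
#' @return Non-negative envelope values (mV) on `phase_grid`.
#' @examples
#' emg_envelope_template(data.frame(center = 45, width = 10, amp = 1),
#'                       phase_grid = 0:100)
#' @export
emg_envelope_template <- function(muscle_params, phase_grid) {
  if (any(phase_grid < 0 | phase_grid > 100)) {
    stop("`phase_grid` must lie within [0, 100]", call. = FALSE)
  }
  out <- numeric(length(phase_grid))
  if (is.null(muscle_params) || nrow(muscle_params) == 0L) return(out)
  if (any(muscle_params$amp < 0)) {
    stop("burst amplitudes must be >= 0", call. = FALSE)
  }
  if (any(muscle_params$width <= 0)) {
    stop("burst widths must be > 0", call. = FALSE)
  }
  for (i in seq_len(nrow(muscle_params))) {
    c0 <- muscle_params$center[i]
    w <- muscle_params$width[i]
    a <- muscle_params$amp[i]
    # wrap bursts across the cycle boundary
    for (shift in c(-100, 0, 100)) {
      out <- out + a * exp(-((phase_grid - c0 - shift)^2) / (2 * w^2))
    }
  }
  out
}
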
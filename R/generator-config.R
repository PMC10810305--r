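#' Default EMG burst parameters
#'
#' Gaussian-burst envelope templates for the four recorded muscles, expressed
#' on the 0--100% gait-cycle axis (heel contact at 0%). Each row of a muscle's
#' data frame is one burst: `center` and `width` (the Gaussian SD) in %cycle,
#' `amp` in mV. The plantar flexors (soleus, medial/lateral gastrocnemius) are
#' active through stance with activity peaking in late stance and decaying
#' before push-off completes; the tibialis anterior is active at loading and
#' through swing.
#'
#' @return Named list (`sol`, `mg`, `lg`, `ta`) of data frames with columns
#'   `center`, `width`, `amp`.
#' @export
default_burst_params <- function() {
  list(
    sol = data.frame(center = c(34, 52), width = c(10, 8), amp = c(0.13, 0.30)),
    mg  = data.frame(center = c(32, 50), width = c(10, 8), amp = c(0.13, 0.26)),
    lg  = data.frame(center = c(30, 48), width = c(10, 8), amp = c(0.10, 0.20)),
    ta  = data.frame(center = c(3, 68, 97), width = c(4, 9, 4),
                     amp = c(0.20, 0.16, 0.12))
  )
}

#' Default adaptation parameters
#'
#' Per-muscle steady-state fractional change of the EMG envelope with powered
#' practice and the exponential time constant (minutes). The triceps surae
#' muscles decrease (soleus -12%, medial gastrocnemius -5%, lateral
#' gastrocnemius -17%); the tibialis anterior increases (+9%). The time
#' constant of 6 minutes puts most of the change in the first quarter hour and
#' >99% of it within a 30-minute powered session.
#'
#' @return Named list per muscle of `list(change, tau_min)`.
#' @export
default_adaptation <- function() {
  list(
    sol = list(change = -0.12, tau_min = 6),
    mg  = list(change = -0.05, tau_min = 6),
    lg  = list(change = -0.17, tau_min = 6),
    ta  = list(change = +0.09, tau_min = 6)
  )
}

#' Default condition timeline
#'
#' The single-session protocol: 5 minutes walking in the boots alone, 5
#' minutes with the exoskeletons attached but unpowered (the controller is
#' calibrated in this window), 30 minutes powered, and 10 minutes of
#' deadaptation with the exoskeletons switched off -- 50 minutes of walking in
#' total.
#'
#' @return Data frame with columns `condition`, `minutes`.
#' @export
default_timeline <- function() {
  data.frame(
    condition = c("BootsOnly", "Unpowered", "Powered", "Deadaptation"),
    minutes = c(5, 5, 30, 10)
  )
}

default_noise <- function() {
  list(
    emg_floor_mv = 0.005,     # baseline EMG noise floor (mV RMS, ~5 uV)
    stride_amp_cv = 0.05,     # per-stride envelope amplitude CV
    subject_amp_sdlog = 0.20, # between-subject EMG gain spread (lognormal)
    subject_adapt_sd = 0.02,  # between-subject SD of steady-state change
    subject_cadence_sdlog = 0.04,
    subject_mech_sdlog = 0.04, # between-subject moment/ROM amplitude spread
    angle_noise_deg = 0.25,
    moment_noise_nmkg = 0.015,
    grf_stride_cv = 0.03
  )
}

#' Synthetic study generator configuration
#'
#' Assembles and validates the full parameter set of the synthetic gait/EMG
#' generator. The defaults are the study conditions: 12 subjects, EMG sampled
#' at 1000 Hz and mechanics at 100 Hz, cadence 0.9 strides/s, stance occupying
#' 60% of the cycle, the 5/5/30/10-minute condition timeline, per-muscle
#' adaptation of -12%/-5%/-17%/+9% (soleus, medial gastrocnemius, lateral
#' gastrocnemius, tibialis anterior), an affine exoskeleton-encoder angle
#' discrepancy (scale 0.44, offset 4.8 deg) reproducing the reduced
#' exoskeleton range of motion, body mass 69.3 kg and walking speed 1.15 m/s.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed; the same configuration (including seed) always
#'   yields an identical dataset.
#' @param sample_rate_emg,sample_rate_mech Sampling rates (Hz) of the EMG and
#'   mechanics channel groups.
#' @param cadence_mean Mean cadence, strides/s.
#' @param cadence_cv Stride-to-stride CV of stride duration.
#' @param stance_fraction Fraction of the gait cycle in stance.
#' @param burst_params Per-muscle burst list, see [default_burst_params()].
#' @param adaptation Per-muscle adaptation list, see [default_adaptation()].
#' @param discrepancy List `angle_scale`, `angle_offset` (deg) mapping the
#'   biological ankle angle to the exoskeleton-reported angle.
#' @param timeline Condition timeline data frame (`condition`, `minutes`).
#' @param body_mass Body mass, kg.
#' @param walking_speed Treadmill speed, m/s (carried as metadata).
#' @param noise Noise/variability parameters; see source for fields.
#' @param target_shares Calibration targets of the generator defaults for the
#'   exoskeleton contribution shares (fractions of peak total ankle power,
#'   peak total moment, positive work) used as simulation ground truth.
#' @param adaptation_enabled Logical; disable to generate a stationary
#'   (null-adaptation) study.
#'
#' @return A validated list of class `gen_config`.
#' @export
gen_config <- function(n_subjects = 12,
                       seed = 1,
                       sample_rate_emg = 1000,
                       sample_rate_mech = 100,
                       cadence_mean = 0.9,
                       cadence_cv = 0.03,
                       stance_fraction = 0.60,
                       burst_params = default_burst_params(),
                       adaptation = default_adaptation(),
                       discrepancy = list(angle_scale = 0.44, angle_offset = 4.8),
                       timeline = default_timeline(),
                       body_mass = 69.3,
                       walking_speed = 1.15,
                       noise = default_noise(),
                       target_shares = list(power = 0.29, moment = 0.18,
                                            pos_work = 0.33),
                       adaptation_enabled = TRUE) {
  stopifnot_scalar(n_subjects, "n_subjects", positive = TRUE)
  stopifnot_scalar(seed, "seed")
  stopifnot_scalar(sample_rate_emg, "sample_rate_emg", positive = TRUE)
  stopifnot_scalar(sample_rate_mech, "sample_rate_mech", positive = TRUE)
  stopifnot_scalar(cadence_mean, "cadence_mean", positive = TRUE)
  stopifnot_scalar(body_mass, "body_mass", positive = TRUE)
  if (stance_fraction <= 0 || stance_fraction >= 1) {
    stop("`stance_fraction` must lie in (0, 1)", call. = FALSE)
  }
  for (m in names(burst_params)) {
    bp <- burst_params[[m]]
    if (nrow(bp) > 0 && any(bp$width <= 0)) {
      stop("burst widths must be > 0", call. = FALSE)
    }
    if (nrow(bp) > 0 && any(bp$amp < 0)) {
      stop("burst amplitudes must be >= 0", call. = FALSE)
    }
  }
  for (m in names(adaptation)) {
    if (adaptation[[m]]$tau_min <= 0) {
      stop("adaptation time constants must be > 0", call. = FALSE)
    }
  }
  if (any(timeline$minutes <= 0)) {
    stop("timeline durations must be > 0", call. = FALSE)
  }
  if (discrepancy$angle_scale < 0) {
    stop("`angle_scale` must be >= 0", call. = FALSE)
  }
  cfg <- list(
    n_subjects = as.integer(n_subjects), seed = as.integer(seed),
    sample_rate_emg = sample_rate_emg, sample_rate_mech = sample_rate_mech,
    cadence_mean = cadence_mean, cadence_cv = cadence_cv,
    stance_fraction = stance_fraction, burst_params = burst_params,
    adaptation = adaptation, discrepancy = discrepancy, timeline = timeline,
    body_mass = body_mass, walking_speed = walking_speed, noise = noise,
    target_shares = target_shares,
    adaptation_enabled = isTRUE(adaptation_enabled)
  )
  class(cfg) <- "gen_config"
  cfg
}

#' @export
print.gen_config <- function(x, ...) {
  cat("Synthetic gait/EMG generator configuration\n")
  cat(sprintf("  subjects: %d, seed: %d\n", x$n_subjects, x$seed))
  cat(sprintf("  rates: EMG %g Hz, mechanics %g Hz\n",
              x$sample_rate_emg, x$sample_rate_mech))
  cat(sprintf("  cadence: %.2f strides/s (cv %.2f), stance %.0f%%\n",
              x$cadence_mean, x$cadence_cv, 100 * x$stance_fraction))
  cat("  timeline:",
      paste(sprintf("%s %gmin", x$timeline$condition, x$timeline$minutes),
            collapse = ", "), "\n")
  ad <- vapply(x$adaptation, function(a) a$change, numeric(1))
  cat("  adaptation (steady state):",
      paste(sprintf("%s %+.0f%%", names(ad), 100 * ad), collapse = ", "),
      if (x$adaptation_enabled) "\n" else "(disabled)\n")
  invisible(x)
}
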
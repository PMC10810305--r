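# Synthetic multi-subject gait + surface-EMG generator emulating the
# single-session adaptation protocol (BootsOnly -> Unpowered -> Powered ->
# Deadaptation). All ground truth (events, adaptation factors, subject
# factors, calibration) is embedded in each trial.

sampled_signal <- function(values, rate, units) {
  structure(list(values = as.numeric(values), rate = rate, units = units),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %d samples @ %g Hz (%s), %.1f s\n",
              length(x$values), x$rate, x$units, length(x$values) / x$rate))
  invisible(x)
}

#' Practice-time adaptation multiplier
#'
#' Exponential approach of a muscle's envelope amplitude toward its
#' steady-state change with powered practice time:
#' `1 + change * (1 - exp(-t / tau))`. Equals 1 at `t = 0` and
#' `1 + change` as `t` grows.
#'
#' @param elapsed_powered_minutes Minutes of powered walking so far (>= 0).
#' @param muscle_adaptation List with `change` (signed fraction at steady
#'   state) and `tau_min` (time constant, minutes, > 0).
#' @return Multiplier (vectorized over `elapsed_powered_minutes`).
#' @examples
#' adaptation_factor(0, list(change = -0.12, tau_min = 6))   # 1
#' adaptation_factor(Inf, list(change = -0.12, tau_min = 6)) # 0.88
#' @export
adaptation_factor <- function(elapsed_powered_minutes, muscle_adaptation) {
  if (any(elapsed_powered_minutes < 0)) {
    stop("`elapsed_powered_minutes` must be >= 0", call. = FALSE)
  }
  tau <- muscle_adaptation$tau_min
  if (!is.numeric(tau) || tau <= 0) {
    stop("adaptation time constant must be > 0", call. = FALSE)
  }
  1 + muscle_adaptation$change * (1 - exp(-elapsed_powered_minutes / tau))
}

#' Synthesize raw surface EMG from an envelope
#'
#' Amplitude-modulates a band-limited (default 20--450 Hz) zero-mean Gaussian
#' noise carrier of unit RMS by `envelope + noise_floor`, the standard
#' surrogate for raw EMG that preserves envelope statistics. Deterministic
#' under a fixed seed.
#'
#' @param envelope Non-negative envelope values (mV).
#' @param sample_rate Sampling rate, Hz; must exceed twice the carrier band
#'   top to avoid aliasing.
#' @param seed Integer seed for the carrier noise.
#' @param noise_floor Baseline noise floor (mV RMS) present with zero
#'   envelope.
#' @param band Carrier passband (Hz), length 2.
#' @return Raw EMG vector (mV), same length as `envelope`.
#' @export
synthesize_raw_emg <- function(envelope, sample_rate, seed,
                               noise_floor = 0.01, band = c(20, 450)) {
  if (any(envelope < 0)) stop("`envelope` must be >= 0", call. = FALSE)
  if (sample_rate < 2 * band[2]) {
    stop(sprintf(
      "sample rate %g Hz is below twice the carrier band top (%g Hz)",
      sample_rate, band[2]), call. = FALSE)
  }
  n <- length(envelope)
  bf <- signal::butter(2, band / (sample_rate / 2), type = "pass")
  carrier <- with_seed(seed, rnorm(n))
  carrier <- as.numeric(signal::filter(bf, carrier))
  carrier <- carrier / sqrt(mean(carrier^2))
  (envelope + noise_floor) * carrier
}

#' Exoskeleton-reported ankle angle from the biological angle
#'
#' Affine compression of the biological ankle angle emulating the
#' exoskeleton encoder's reduced range of motion (soft-tissue and cuff
#' compliance, joint-center mismatch): `exo = scale * bio + offset`, with
#' optional low-pass smoothing.
#'
#' @param bio_angle Biological ankle angle (deg, dorsiflexion positive).
#' @param discrepancy List `angle_scale` (>= 0) and `angle_offset` (deg).
#' @param sample_rate Sampling rate (Hz), needed only when `lp_cutoff` is set.
#' @param lp_cutoff Optional low-pass cutoff (Hz) for zero-phase smoothing.
#' @return Exoskeleton angle (deg), same length as input.
#' @export
exo_angle_from_bio <- function(bio_angle, discrepancy,
                               sample_rate = NULL, lp_cutoff = NULL) {
  if (discrepancy$angle_scale < 0) {
    stop("`angle_scale` must be >= 0", call. = FALSE)
  }
  out <- discrepancy$angle_scale * bio_angle + discrepancy$angle_offset
  if (!is.null(lp_cutoff)) {
    bf <- signal::butter(2, lp_cutoff / (sample_rate / 2), type = "low")
    out <- as.numeric(signal::filtfilt(bf, out))
  }
  out
}

# Draw a stride plan covering `dur_s` seconds: lognormal stride durations
# around 1/cadence with CV `cv`. Returns heel-strike times (the last one
# may exceed dur_s so every sample belongs to a stride).
stride_plan <- function(dur_s, cadence, cv) {
  mean_dur <- 1 / cadence
  n_guess <- ceiling(dur_s / mean_dur * 1.2) + 10L
  durs <- mean_dur * exp(rnorm(n_guess, -cv^2 / 2, cv))
  hs <- cumsum(c(0, durs))
  n_keep <- which(hs >= dur_s)[1L]
  list(hs_times = hs[seq_len(n_keep + 1L)][seq_len(n_keep)],
       durations = durs[seq_len(n_keep)])
}

# Phase (%cycle) and stride index for each sample time.
phase_of <- function(t, plan) {
  idx <- findInterval(t, plan$hs_times)
  idx[idx < 1L] <- 1L
  ph <- (t - plan$hs_times[idx]) / plan$durations[idx] * 100
  list(phase = pmin(ph, 100), stride = idx)
}

fast_envelope <- function(burst_df, phase) {
  grid <- seq(0, 100, by = 0.1)
  tmpl <- emg_envelope_template(burst_df, grid)
  approx(grid, tmpl, xout = phase)$y
}

# Generate one trial (one subject x condition). `subj` carries the
# subject-level factors; `calib` the controller calibration (Powered only).
# RNG: caller must have seeded the subject stream.
generate_trial <- function(config, subject_id, condition, minutes, subj,
                           calib = NULL, powered_offset_min = 0,
                           deadapt_start_factor = NULL) {
  dur_s <- minutes * 60
  fs_m <- config$sample_rate_mech
  fs_e <- config$sample_rate_emg
  nz <- config$noise

  plan <- stride_plan(dur_s, config$cadence_mean * subj$cadence_factor,
                      config$cadence_cv)
  n_str <- length(plan$durations)
  t_m <- seq(0, by = 1 / fs_m, length.out = round(dur_s * fs_m))
  t_e <- seq(0, by = 1 / fs_e, length.out = round(dur_s * fs_e))
  pm <- phase_of(t_m, plan)
  pe <- phase_of(t_e, plan)

  # mechanics channels
  aa <- ankle_angle_template()(pm$phase) * subj$rom_factor +
    rnorm(length(t_m), 0, nz$angle_noise_deg)
  ka <- knee_angle_template()(pm$phase) * subj$rom_factor +
    rnorm(length(t_m), 0, nz$angle_noise_deg)
  ha <- hip_angle_template()(pm$phase) * subj$rom_factor +
    rnorm(length(t_m), 0, nz$angle_noise_deg)
  am_bio <- ankle_moment_template()(pm$phase) * subj$moment_factor +
    rnorm(length(t_m), 0, nz$moment_noise_nmkg)
  km <- knee_moment_template()(pm$phase) * subj$moment_factor +
    rnorm(length(t_m), 0, nz$moment_noise_nmkg)
  hm <- hip_moment_template()(pm$phase) * subj$moment_factor +
    rnorm(length(t_m), 0, nz$moment_noise_nmkg)

  grf_jit <- exp(rnorm(n_str, 0, nz$grf_stride_cv))
  stance_end <- config$stance_fraction * 100
  in_stance <- pm$phase < stance_end
  grf <- numeric(length(t_m))
  s_norm <- pm$phase[in_stance] / stance_end
  grf[in_stance] <- grf_stance_template(s_norm) *
    config$body_mass * 9.81 * grf_jit[pm$stride[in_stance]]

  exo_angle <- exo_angle_from_bio(
    ankle_angle_template()(pm$phase) * subj$rom_factor, config$discrepancy)

  # adaptation multiplier per muscle as a function of elapsed time
  elapsed_min <- t_e / 60
  adapt_mult <- function(muscle) {
    ad <- config$adaptation[[muscle]]
    ad$change <- ad$change + subj$adapt_offset[[muscle]]
    if (!config$adaptation_enabled) return(rep(1, length(t_e)))
    if (condition == "Powered") {
      adaptation_factor(powered_offset_min + elapsed_min, ad)
    } else if (condition == "Deadaptation" && !is.null(deadapt_start_factor)) {
      f0 <- deadapt_start_factor[[muscle]]
      1 + (f0 - 1) * exp(-elapsed_min / ad$tau_min)
    } else {
      rep(1, length(t_e))
    }
  }

  emg <- list()
  env_scale_window <- list()
  for (m in MUSCLES) {
    stride_jit <- exp(rnorm(n_str, 0, nz$stride_amp_cv))
    env <- fast_envelope(config$burst_params[[m]], pe$phase) *
      subj$amp_factor[[m]] * stride_jit[pe$stride] * adapt_mult(m)
    emg_seed <- floor(runif(1, 0, 2^30))
    emg[[paste0("emg_", m)]] <- sampled_signal(
      synthesize_raw_emg(env, fs_e, emg_seed, noise_floor = nz$emg_floor_mv),
      fs_e, "mV")
  }

  # exoskeleton contribution to the measured total ankle moment
  exo_applied <- FALSE
  if (condition == "Powered" && !is.null(calib)) {
    ctrl <- run_controller(emg$emg_sol$values, fs_e, calib,
                           exo_angle = NULL, config = calib$config)
    tq_mech <- approx(t_e, ctrl$torque, xout = t_m, rule = 2)$y
    am <- am_bio + tq_mech / config$body_mass
    exo_applied <- TRUE
  } else {
    am <- am_bio
  }

  hs_ok <- plan$hs_times <= dur_s - 1 / fs_m
  hs_idx <- ceiling(plan$hs_times[hs_ok] * fs_m + 1 - 1e-9)
  to_times <- plan$hs_times + config$stance_fraction * plan$durations
  to_ok <- to_times <= dur_s - 1 / fs_m
  to_idx <- ceiling(to_times[to_ok] * fs_m + 1 - 1e-9)

  end_min <- if (condition == "Powered") powered_offset_min + minutes else 0
  gt <- list(
    hs_times = plan$hs_times[hs_ok], stride_durations = plan$durations,
    hs_idx_mech = hs_idx, to_idx_mech = to_idx,
    subject_factors = subj,
    adaptation_factor_end = if (condition == "Powered") {
      lapply(MUSCLES, function(m) {
        ad <- config$adaptation[[m]]
        ad$change <- ad$change + subj$adapt_offset[[m]]
        if (config$adaptation_enabled) adaptation_factor(end_min, ad) else 1
      }) |> setNames(MUSCLES)
    } else NULL,
    exo_applied = exo_applied,
    target_shares = config$target_shares
  )

  channels <- list(
    ankle_angle = sampled_signal(aa, fs_m, "deg"),
    knee_angle = sampled_signal(ka, fs_m, "deg"),
    hip_angle = sampled_signal(ha, fs_m, "deg"),
    ankle_moment = sampled_signal(am, fs_m, "Nm/kg"),
    knee_moment = sampled_signal(km, fs_m, "Nm/kg"),
    hip_moment = sampled_signal(hm, fs_m, "Nm/kg"),
    exo_angle = sampled_signal(exo_angle, fs_m, "deg"),
    grf_v = sampled_signal(grf, fs_m, "N")
  )
  channels <- c(channels, emg)

  structure(list(subject_id = subject_id, condition = condition,
                 channels = channels, ground_truth = gt,
                 body_mass = config$body_mass),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> subject %s, condition %s\n",
              x$subject_id, x$condition))
  cat(sprintf("  %d channels, %.1f min, %d ground-truth strides\n",
              length(x$channels),
              length(x$channels$grf_v$values) / x$channels$grf_v$rate / 60,
              length(x$ground_truth$hs_times) - 1L))
  invisible(x)
}

#' Generate all trials for one subject
#'
#' Runs the full single-session protocol for subject `subject_index`:
#' the four conditions of the configured timeline, with the controller
#' calibrated on the subject's own Unpowered walking and its commanded
#' torque folded into the measured total ankle moment during the Powered
#' condition. Triceps surae (and tibialis anterior) envelopes follow the
#' configured adaptation dynamics during Powered walking and wash out during
#' Deadaptation. Deterministic given `config` (including its seed).
#'
#' @param config A [gen_config()].
#' @param subject_index Integer in `1:config$n_subjects`.
#' @param controller A [controller_config()] used for the embedded
#'   calibration and torque synthesis.
#' @return Named list of `trial_recording`s, one per condition.
#' @export
generate_subject <- function(config, subject_index,
                             controller = controller_config()) {
  stopifnot(inherits(config, "gen_config"))
  subject_id <- sprintf("S%02d", subject_index)
  with_seed(config$seed * 1000L + subject_index * 7L, {
    nz <- config$noise
    subj <- list(
      cadence_factor = exp(rnorm(1, 0, nz$subject_cadence_sdlog)),
      rom_factor = exp(rnorm(1, 0, nz$subject_mech_sdlog)),
      moment_factor = exp(rnorm(1, 0, nz$subject_mech_sdlog)),
      amp_factor = lapply(setNames(MUSCLES, MUSCLES),
                          function(m) exp(rnorm(1, 0, nz$subject_amp_sdlog))),
      adapt_offset = lapply(setNames(MUSCLES, MUSCLES),
                            function(m) rnorm(1, 0, nz$subject_adapt_sd))
    )
    trials <- list()
    calib <- NULL
    deadapt_f0 <- NULL
    for (k in seq_len(nrow(config$timeline))) {
      cond <- config$timeline$condition[k]
      mins <- config$timeline$minutes[k]
      trials[[cond]] <- generate_trial(
        config, subject_id, cond, mins, subj,
        calib = if (cond == "Powered") calib else NULL,
        deadapt_start_factor = if (cond == "Deadaptation") deadapt_f0 else NULL
      )
      if (cond == "Unpowered") {
        env <- preprocess_emg(trials[[cond]]$channels$emg_sol$values,
                              config$sample_rate_emg, controller)
        calib <- calibrate(env, config$sample_rate_emg, controller)
      }
      if (cond == "Powered") {
        deadapt_f0 <- trials[[cond]]$ground_truth$adaptation_factor_end
      }
    }
    trials
  })
}

#' Generate the full synthetic dataset
#'
#' All subjects crossed with all timeline conditions. At the default
#' 50-minute timeline each subject holds roughly 3 million EMG samples per
#' muscle; for large `n_subjects` prefer streaming subjects through
#' [generate_subject()] as [run_pipeline()] does.
#'
#' @inheritParams generate_subject
#' @return List of `trial_recording`s, named `<subject>_<condition>`.
#' @export
generate_dataset <- function(config, controller = controller_config()) {
  out <- list()
  for (i in seq_len(config$n_subjects)) {
    trials <- generate_subject(config, i, controller)
    names(trials) <- paste0(sprintf("S%02d", i), "_", names(trials))
    out <- c(out, trials)
  }
  out
}
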
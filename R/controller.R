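# Proportional myoelectric controller chain: causal Butterworth high-pass
# (50 Hz), full-wave rectification, causal Butterworth low-pass (8 Hz),
# subject-specific gain/threshold calibration, saturation at the q-axis
# current cap, and current-to-torque transmission.

#' Controller configuration
#'
#' Constants of the proportional myoelectric control chain. Defaults follow
#' the deployed controller: 2nd-order Butterworth high-pass at 50 Hz and
#' low-pass at 8 Hz, q-axis current capped at 7.6 A (equivalent to 20 A
#' line-to-line, stored for reference only), deadband threshold at 5% of the
#' calibration maximum, and a constant 2 Nm/A transmission (7.6 A then maps
#' to 15.2 Nm, inside the 7--17 Nm torque range observed across users); a
#' tabulated transmission-ratio-vs-exoskeleton-angle hook is provided for
#' variable transmissions.
#'
#' @param hp_cutoff,lp_cutoff High-/low-pass cutoffs, Hz.
#' @param filter_order Butterworth order (both filters).
#' @param i_max_qaxis Q-axis current cap, A.
#' @param i_line_to_line_equiv Line-to-line equivalent of the cap, A
#'   (informational; the conversion is vendor-stated, never computed here).
#' @param threshold_fraction Deadband threshold as a fraction of the
#'   calibration maximum envelope, in `[0, 1)`.
#' @param transmission Either a single constant gain (Nm/A) or a data frame
#'   with columns `angle` (deg) and `ratio` (Nm/A) for a tabulated
#'   angle-dependent ratio. Ratios must be non-negative.
#' @param torque_sign_plantar Logical; if `TRUE` (default) the device only
#'   assists plantarflexion and torque is clipped at zero.
#' @param settle_s Seconds discarded from the start of any calibration
#'   window (causal-filter start-up transient).
#' @return List of class `controller_config`.
#' @export
controller_config <- function(hp_cutoff = 50, lp_cutoff = 8,
                              filter_order = 2, i_max_qaxis = 7.6,
                              i_line_to_line_equiv = 20,
                              threshold_fraction = 0.05,
                              transmission = 2.0,
                              torque_sign_plantar = TRUE,
                              settle_s = 2) {
  stopifnot_scalar(hp_cutoff, "hp_cutoff", positive = TRUE)
  stopifnot_scalar(lp_cutoff, "lp_cutoff", positive = TRUE)
  stopifnot_scalar(i_max_qaxis, "i_max_qaxis", positive = TRUE)
  if (lp_cutoff >= hp_cutoff) {
    stop("`lp_cutoff` must be below `hp_cutoff`", call. = FALSE)
  }
  if (threshold_fraction < 0 || threshold_fraction >= 1) {
    stop("`threshold_fraction` must lie in [0, 1)", call. = FALSE)
  }
  if (is.data.frame(transmission)) {
    if (!all(c("angle", "ratio") %in% names(transmission))) {
      stop("tabulated transmission needs `angle` and `ratio` columns",
           call. = FALSE)
    }
    if (any(transmission$ratio < 0)) {
      stop("transmission ratios must be >= 0", call. = FALSE)
    }
  } else {
    stopifnot_scalar(transmission, "transmission")
    if (transmission < 0) stop("transmission gain must be >= 0", call. = FALSE)
  }
  structure(list(hp_cutoff = hp_cutoff, lp_cutoff = lp_cutoff,
                 filter_order = filter_order, i_max_qaxis = i_max_qaxis,
                 i_line_to_line_equiv = i_line_to_line_equiv,
                 threshold_fraction = threshold_fraction,
                 transmission = transmission,
                 torque_sign_plantar = isTRUE(torque_sign_plantar),
                 settle_s = settle_s),
            class = "controller_config")
}

#' @export
print.controller_config <- function(x, ...) {
  cat("Proportional myoelectric controller configuration\n")
  cat(sprintf("  HP %g Hz / rectify / LP %g Hz (order-%d Butterworth, causal)\n",
              x$hp_cutoff, x$lp_cutoff, x$filter_order))
  cat(sprintf("  current cap %g A q-axis (%g A line-to-line equiv.)\n",
              x$i_max_qaxis, x$i_line_to_line_equiv))
  tr <- if (is.data.frame(x$transmission)) {
    sprintf("tabulated over %d angles", nrow(x$transmission))
  } else sprintf("constant %g Nm/A", x$transmission)
  cat(sprintf("  deadband %g%% of calibration max; transmission %s\n",
              100 * x$threshold_fraction, tr))
  invisible(x)
}

#' Causal EMG envelope extraction
#'
#' The real-time control envelope: forward-only (causal) 2nd-order
#' Butterworth high-pass, full-wave rectification, then causal 2nd-order
#' Butterworth low-pass, clipped at zero. Output sample `t` depends only on
#' input samples `<= t`; filters start from rest (zero initial conditions).
#'
#' @param raw Raw EMG (mV).
#' @param sample_rate Sampling rate, Hz; must exceed `2 * hp_cutoff`.
#' @param config A [controller_config()].
#' @return Envelope (mV), same length as `raw`.
#' @export
preprocess_emg <- function(raw, sample_rate, config = controller_config()) {
  if (anyNA(raw)) stop("`raw` contains NA/NaN", call. = FALSE)
  if (sample_rate <= 2 * config$hp_cutoff) {
    stop(sprintf("sample rate must exceed 2 x hp_cutoff = %g Hz",
                 2 * config$hp_cutoff), call. = FALSE)
  }
  nyq <- sample_rate / 2
  hp <- signal::butter(config$filter_order, config$hp_cutoff / nyq,
                       type = "high")
  lp <- signal::butter(config$filter_order, config$lp_cutoff / nyq,
                       type = "low")
  x <- as.numeric(signal::filter(hp, raw))
  x <- abs(x)
  x <- as.numeric(signal::filter(lp, x))
  pmax(x, 0)
}

#' Calibrate the subject-specific gain and threshold
#'
#' From an envelope recorded during unpowered walking: the gain maps the
#' window's maximum envelope to the q-axis current cap
#' (`gain = i_max / max(envelope)`), so applying the controller to the
#' calibration window itself reaches exactly the cap; the deadband threshold
#' is `threshold_fraction * max(envelope)`. The first `settle_s` seconds are
#' discarded (filter start-up).
#'
#' @param envelope Envelope (mV) from [preprocess_emg()] on unpowered
#'   walking; at least 10 s.
#' @param sample_rate Sampling rate, Hz.
#' @param config A [controller_config()].
#' @return List of class `calibration_result`: `gain` (A/mV), `threshold`
#'   (mV), `max_envelope` (mV), plus the config used.
#' @export
calibrate <- function(envelope, sample_rate, config = controller_config()) {
  if (length(envelope) / sample_rate < 10) {
    stop("calibration window must be at least 10 s of walking", call. = FALSE)
  }
  drop_n <- min(length(envelope), round(config$settle_s * sample_rate))
  win <- envelope[(drop_n + 1L):length(envelope)]
  mx <- max(win)
  if (mx <= 0) {
    stop("cannot calibrate on an all-zero envelope", call. = FALSE)
  }
  structure(list(gain = config$i_max_qaxis / mx,
                 threshold = config$threshold_fraction * mx,
                 max_envelope = mx, config = config),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> gain %.3g A/mV, threshold %.3g mV (max env %.3g mV)\n",
    x$gain, x$threshold, x$max_envelope))
  invisible(x)
}

#' Commanded q-axis current from the envelope
#'
#' `current = clip(gain * envelope, 0, i_max_qaxis)`, forced to zero wherever
#' the envelope is below the deadband threshold -- the device is transparent
#' when the muscle is quiet (swing).
#'
#' @param envelope Envelope (mV).
#' @param calibration A `calibration_result`.
#' @param config A [controller_config()].
#' @return Current series (A) in `[0, i_max_qaxis]`.
#' @export
command_current <- function(envelope, calibration,
                            config = controller_config()) {
  cur <- pmin(pmax(calibration$gain * envelope, 0), config$i_max_qaxis)
  cur[envelope < calibration$threshold] <- 0
  cur
}

transmission_ratio <- function(exo_angle, config) {
  tr <- config$transmission
  if (is.data.frame(tr)) {
    if (is.null(exo_angle)) {
      stop("tabulated transmission needs the exoskeleton angle", call. = FALSE)
    }
    # clamp outside the table hull
    a <- pmin(pmax(exo_angle, min(tr$angle)), max(tr$angle))
    approx(tr$angle, tr$ratio, xout = a)$y
  } else {
    tr
  }
}

#' Current-to-torque transmission
#'
#' `torque = ratio(exo_angle) * current`. The ratio is either a constant gain
#' (Nm/A) or interpolated from the tabulated ratio-vs-angle profile, with the
#' angle clamped to the table hull. Plantarflexion-only devices clip torque
#' at zero.
#'
#' @param current Q-axis current (A).
#' @param exo_angle Exoskeleton ankle angle (deg) on the same clock, or
#'   `NULL` with a constant transmission.
#' @param config A [controller_config()].
#' @return Torque series (Nm).
#' @export
current_to_torque <- function(current, exo_angle = NULL,
                              config = controller_config()) {
  tq <- transmission_ratio(exo_angle, config) * current
  if (config$torque_sign_plantar) tq <- pmax(tq, 0)
  tq
}

#' Run the full controller chain
#'
#' Raw EMG to envelope to current to torque, all on the EMG clock.
#'
#' @param raw Raw EMG (mV).
#' @param sample_rate Sampling rate, Hz.
#' @param calibration A `calibration_result`.
#' @param exo_angle Optional exoskeleton angle on the EMG clock (only needed
#'   for tabulated transmissions).
#' @param config A [controller_config()].
#' @return List of class `controller_output`: `envelope` (mV), `current`
#'   (A), `torque` (Nm).
#' @export
run_controller <- function(raw, sample_rate, calibration, exo_angle = NULL,
                           config = controller_config()) {
  env <- preprocess_emg(raw, sample_rate, config)
  cur <- command_current(env, calibration, config)
  tq <- current_to_torque(cur, exo_angle, config)
  structure(list(envelope = env, current = cur, torque = tq,
                 sample_rate = sample_rate),
            class = "controller_output")
}

#' @export
print.controller_output <- function(x, ...) {
  cat(sprintf(
    "<controller_output> %d samples @ %g Hz; peak current %.2f A, peak torque %.2f Nm\n",
    length(x$current), x$sample_rate, max(x$current), max(x$torque)))
  invisible(x)
}

#' Zero-phase analysis envelope
#'
#' Offline variant of the control envelope for analysis figures and metrics:
#' zero-phase (forward-backward) Butterworth high-pass, rectification,
#' zero-phase low-pass. Unlike the causal control chain this introduces no
#' phase lag, so cycle-normalized envelopes line up with the mechanics.
#'
#' @inheritParams preprocess_emg
#' @return Envelope (mV).
#' @export
analysis_envelope <- function(raw, sample_rate, config = controller_config()) {
  if (anyNA(raw)) stop("`raw` contains NA/NaN", call. = FALSE)
  nyq <- sample_rate / 2
  hp <- signal::butter(config$filter_order, config$hp_cutoff / nyq,
                       type = "high")
  lp <- signal::butter(config$filter_order, config$lp_cutoff / nyq,
                       type = "low")
  x <- abs(as.numeric(signal::filtfilt(hp, raw)))
  pmax(as.numeric(signal::filtfilt(lp, x)), 0)
}
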
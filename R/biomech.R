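# Stride segmentation, gait-cycle time normalization (101-point curves,
# heel contact at 0%), joint power and work, and the exoskeleton/biological
# ankle decomposition.

#' Detect stride events from the vertical ground reaction force
#'
#' Heel strikes are upward crossings of `threshold_N`, toe-offs downward
#' crossings, debounced by a minimum-interval rule so force-plate chatter
#' near the threshold cannot double-count events.
#'
#' @param grf_v Vertical GRF (N), uniformly sampled.
#' @param sample_rate Sampling rate, Hz.
#' @param threshold_N Event threshold, N.
#' @param min_interval_s Minimum time between two heel strikes (and between
#'   a heel strike and its toe-off), s.
#' @return List of class `stride_events`: `heel_strikes` and `toe_offs`
#'   (1-based sample indices), `rate`.
#' @export
detect_events <- function(grf_v, sample_rate, threshold_N = 20,
                          min_interval_s = 0.3) {
  above <- grf_v >= threshold_N
  up <- which(!above[-length(above)] & above[-1L]) + 1L
  down <- which(above[-length(above)] & !above[-1L]) + 1L
  min_gap <- round(min_interval_s * sample_rate)
  debounce <- function(idx) {
    if (length(idx) < 2L) return(idx)
    keep <- idx[1L]
    for (i in idx[-1L]) if (i - keep[length(keep)] >= min_gap) keep <- c(keep, i)
    keep
  }
  up <- debounce(up)
  down <- debounce(down)
  if (length(up) == 0L) {
    warning("no threshold crossings found; returning empty events")
    return(structure(list(heel_strikes = integer(0), toe_offs = integer(0),
                          rate = sample_rate), class = "stride_events"))
  }
  # exactly one toe-off between consecutive heel strikes
  down <- down[down > up[1L]]
  to <- integer(0)
  for (k in seq_along(up)) {
    hi <- if (k < length(up)) up[k + 1L] else Inf
    cand <- down[down > up[k] & down < hi]
    if (length(cand)) to <- c(to, cand[1L])
  }
  structure(list(heel_strikes = as.integer(up), toe_offs = as.integer(to),
                 rate = sample_rate), class = "stride_events")
}

#' @export
print.stride_events <- function(x, ...) {
  cat(sprintf("<stride_events> %d heel strikes, %d toe-offs @ %g Hz (%d strides)\n",
              length(x$heel_strikes), length(x$toe_offs), x$rate,
              max(0L, length(x$heel_strikes) - 1L)))
  invisible(x)
}

n_strides <- function(events) max(0L, length(events$heel_strikes) - 1L)

#' Select an analysis window of strides
#'
#' Returns the `n` contiguous complete strides at the requested end of the
#' recording -- the protocol analyzes the first or last 30 strides of each
#' condition.
#'
#' @param events A `stride_events`.
#' @param end `"last"` or `"first"`.
#' @param n Number of strides.
#' @return A `stride_events` covering exactly `n` strides (`n + 1` heel
#'   strikes).
#' @export
select_window <- function(events, end = c("last", "first"), n = 30) {
  end <- match.arg(end)
  avail <- n_strides(events)
  if (avail < n) {
    stop(sprintf("only %d complete strides available, need %d (short by %d)",
                 avail, n, n - avail), call. = FALSE)
  }
  idx <- if (end == "first") 1:(n + 1L) else (avail - n + 1L):(avail + 1L)
  hs <- events$heel_strikes[idx]
  to <- events$toe_offs[events$toe_offs >= hs[1L] &
                          events$toe_offs < hs[length(hs)]]
  structure(list(heel_strikes = hs, toe_offs = to, rate = events$rate),
            class = "stride_events")
}

#' Time-normalize a signal to gait cycles
#'
#' Resamples each stride (heel strike to next heel strike) onto 101 evenly
#' spaced points of the 0--100% gait cycle by linear interpolation; heel
#' contact is point 0. The signal may live on a different clock than the
#' events (e.g. EMG at 1000 Hz vs mechanics events at 100 Hz) -- strides are
#' mapped through time in seconds. Strides covering fewer than 3 signal
#' samples are skipped with a warning.
#'
#' @param x Signal values (or a `sampled_signal`).
#' @param sample_rate Sampling rate of `x` (ignored when `x` is a
#'   `sampled_signal`).
#' @param events A `stride_events` (any clock).
#' @param units Unit string carried into the ensemble.
#' @param t_start Time (s) of the first sample of `x`, for signals that are
#'   segments cut out of a longer recording.
#' @return A `cycle_ensemble`: `curves` (n_strides x 101), `mean`, `sd`,
#'   `stance_end` (%cycle per stride), `durations` (s), `grid`, `units`.
#' @export
time_normalize <- function(x, sample_rate = NULL, events, units = "",
                           t_start = 0) {
  if (inherits(x, "sampled_signal")) {
    sample_rate <- x$rate
    if (nzchar(x$units)) units <- x$units
    x <- x$values
  }
  hs_t <- (events$heel_strikes - 1) / events$rate
  to_t <- (events$toe_offs - 1) / events$rate
  t_end <- t_start + (length(x) - 1L) / sample_rate
  if (length(hs_t) < 2L) stop("need at least one complete stride", call. = FALSE)
  if (hs_t[length(hs_t)] > t_end + 1 / events$rate || hs_t[1L] < t_start) {
    stop("events extend beyond the signal span", call. = FALSE)
  }
  grid <- seq(0, 100, length.out = 101L)
  ns <- length(hs_t) - 1L
  curves <- matrix(NA_real_, ns, 101L)
  stance_end <- rep(NA_real_, ns)
  durations <- diff(hs_t)
  keep <- rep(TRUE, ns)
  for (i in seq_len(ns)) {
    t0 <- hs_t[i]; t1 <- hs_t[i + 1L]
    # slice out the stride's samples (uniform clock) instead of handing the
    # whole recording to approx()
    i0 <- max(1L, floor((t0 - t_start) * sample_rate) + 1L)
    i1 <- min(length(x), ceiling((t1 - t_start) * sample_rate) + 2L)
    if (i1 - i0 + 1L < 3L) {
      keep[i] <- FALSE
      next
    }
    tt <- seq(t0, t1, length.out = 101L)
    ts <- t_start + (seq.int(i0, i1) - 1L) / sample_rate
    curves[i, ] <- approx(ts, x[i0:i1], xout = tt, rule = 2)$y
    to_i <- to_t[to_t > t0 & to_t <= t1]
    if (length(to_i)) stance_end[i] <- (to_i[1L] - t0) / (t1 - t0) * 100
  }
  if (!all(keep)) {
    warning(sprintf("%d stride(s) shorter than 3 samples skipped",
                    sum(!keep)))
    curves <- curves[keep, , drop = FALSE]
    stance_end <- stance_end[keep]
    durations <- durations[keep]
  }
  cycle_ensemble(curves, stance_end, durations, units)
}

cycle_ensemble <- function(curves, stance_end, durations, units = "") {
  structure(list(curves = curves,
                 mean = colMeans(curves),
                 sd = apply(curves, 2L, sd),
                 stance_end = stance_end,
                 durations = durations,
                 grid = seq(0, 100, length.out = 101L),
                 units = units),
            class = "cycle_ensemble")
}

#' @export
print.cycle_ensemble <- function(x, ...) {
  cat(sprintf(
    "<cycle_ensemble> %d strides x 101 points (%s); mean stance end %.1f%%\n",
    nrow(x$curves), if (nzchar(x$units)) x$units else "unitless",
    mean(x$stance_end, na.rm = TRUE)))
  invisible(x)
}

#' @export
mean.cycle_ensemble <- function(x, ...) x$mean

# centered finite differences along the 101-point grid, per stride, with
# per-stride time step durations/100; one-sided at the ends.
grid_derivative <- function(curves, durations) {
  ns <- nrow(curves)
  d <- matrix(NA_real_, ns, ncol(curves))
  for (i in seq_len(ns)) {
    dt <- durations[i] / 100
    y <- curves[i, ]
    n <- length(y)
    d[i, ] <- c(y[2L] - y[1L],
                (y[3:n] - y[1:(n - 2L)]) / 2,
                y[n] - y[n - 1L]) / dt
  }
  d
}

#' Joint power from moment and angle cycle curves
#'
#' Angular velocity by centered finite differences of the angle curves
#' (deg converted to rad using each stride's duration); power is
#' `moment * velocity`. Moment and angle must share the sign convention so
#' that, at the ankle, plantarflexion moment times plantarflexion velocity
#' is positive.
#'
#' @param moment Cycle curves (matrix n x 101 or `cycle_ensemble`), Nm/kg.
#' @param angle Cycle curves on the same grid, deg.
#' @param durations Stride durations (s), one per curve.
#' @return Matrix of power curves (W/kg), n x 101.
#' @export
joint_power <- function(moment, angle, durations = NULL) {
  if (inherits(moment, "cycle_ensemble")) {
    if (is.null(durations)) durations <- moment$durations
    moment <- moment$curves
  }
  if (inherits(angle, "cycle_ensemble")) angle <- angle$curves
  if (is.null(durations)) stop("stride `durations` are required", call. = FALSE)
  if (!all(dim(moment) == dim(angle))) {
    stop("moment and angle curves must share the same grid", call. = FALSE)
  }
  omega <- grid_derivative(angle, durations) * pi / 180
  moment * omega
}

#' Positive and negative work from power cycle curves
#'
#' Trapezoid integration of `max(P, 0)` and `min(P, 0)` over stride time.
#'
#' @param power Power curves (matrix n x 101), W/kg.
#' @param durations Stride durations (s).
#' @return Data frame with per-stride `positive` and `negative` work (J/kg).
#' @export
work_decomposition <- function(power, durations) {
  if (is.null(dim(power))) power <- matrix(power, nrow = 1L)
  pos <- neg <- numeric(nrow(power))
  for (i in seq_len(nrow(power))) {
    dx <- durations[i] / 100
    pos[i] <- trapz_uniform(pmax(power[i, ], 0), dx)
    neg[i] <- trapz_uniform(pmin(power[i, ], 0), dx)
  }
  data.frame(positive = pos, negative = neg)
}

#' Decompose the total ankle moment into exoskeleton and biological parts
#'
#' The exoskeleton torque (Nm) is converted to Nm/kg with the body mass; the
#' biological moment is `total - exo` pointwise. Powers use angular velocity
#' from the biological ankle angle for the total and biological components;
#' for the exoskeleton component the velocity source is selectable
#' (biological angle by default, exoskeleton-reported angle via
#' `velocity_source = "exo"` -- the encoder's compressed range of motion
#' proportionally compresses its velocities). Contribution shares are
#' computed from the ensemble-mean curves: peak(exo)/peak(total) for moment
#' and power, and positive-work share from the mean power curves.
#'
#' @param total_moment `cycle_ensemble` (Nm/kg) of the measured total ankle
#'   moment (plantarflexion positive).
#' @param exo_torque `cycle_ensemble` (Nm) of the exoskeleton torque.
#' @param body_mass Body mass, kg (> 0).
#' @param bio_angle `cycle_ensemble` (deg, dorsiflexion positive) of the
#'   biological ankle angle.
#' @param exo_angle Optional `cycle_ensemble` of the exoskeleton angle,
#'   required when `velocity_source = "exo"`.
#' @param velocity_source `"bio"` or `"exo"`: angle source for the
#'   exoskeleton power.
#' @return List of class `ankle_decomposition`: mean curves for the three
#'   moment and power components, per-component positive/negative work, and
#'   `shares` (`peak_power`, `peak_moment`, `pos_work`).
#' @export
decompose_ankle <- function(total_moment, exo_torque, body_mass,
                            bio_angle, exo_angle = NULL,
                            velocity_source = c("bio", "exo")) {
  velocity_source <- match.arg(velocity_source)
  if (body_mass <= 0) stop("`body_mass` must be > 0", call. = FALSE)
  if (velocity_source == "exo" && is.null(exo_angle)) {
    stop("`exo_angle` is required with velocity_source = \"exo\"",
         call. = FALSE)
  }
  durations <- total_moment$durations
  exo_m <- exo_torque$curves / body_mass
  tot_m <- total_moment$curves
  bio_m <- tot_m - exo_m
  # plantarflexion-positive angle for the power sign convention
  ang_pf <- -bio_angle$curves
  p_tot <- joint_power(tot_m, ang_pf, durations)
  p_bio <- joint_power(bio_m, ang_pf, durations)
  exo_ang_pf <- if (velocity_source == "exo") -exo_angle$curves else ang_pf
  p_exo <- joint_power(exo_m, exo_ang_pf, durations)

  mean_dur <- mean(durations)
  works <- lapply(list(total = p_tot, bio = p_bio, exo = p_exo), function(p) {
    w <- work_decomposition(matrix(colMeans(p), 1L), mean_dur)
    c(positive = w$positive, negative = w$negative)
  })
  peak <- function(m) max(colMeans(m))
  shares <- list(
    peak_moment = peak(exo_m) / peak(tot_m),
    peak_power = peak(p_exo) / peak(p_tot),
    pos_work = works$exo[["positive"]] / works$total[["positive"]]
  )
  structure(list(
    moment = list(total = colMeans(tot_m), bio = colMeans(bio_m),
                  exo = colMeans(exo_m)),
    power = list(total = colMeans(p_tot), bio = colMeans(p_bio),
                 exo = colMeans(p_exo)),
    works = works, shares = shares, durations = durations,
    velocity_source = velocity_source, grid = total_moment$grid
  ), class = "ankle_decomposition")
}

#' @export
print.ankle_decomposition <- function(x, ...) {
  cat("<ankle_decomposition>\n")
  cat(sprintf("  peak moment: total %.2f, exo %.2f Nm/kg (share %.0f%%)\n",
              max(x$moment$total), max(x$moment$exo),
              100 * x$shares$peak_moment))
  cat(sprintf("  peak power:  total %.2f, exo %.2f W/kg (share %.0f%%)\n",
              max(x$power$total), max(x$power$exo),
              100 * x$shares$peak_power))
  cat(sprintf("  positive work: total %.3f, exo %.3f J/kg (share %.0f%%)\n",
              x$works$total[["positive"]], x$works$exo[["positive"]],
              100 * x$shares$pos_work))
  invisible(x)
}

#' Range-of-motion comparison between angle sources
#'
#' Per condition, the range of motion of each source is the sum of the
#' maximal dorsiflexion and plantarflexion magnitudes; the difference is
#' `ROM_bio - ROM_exo`, averaged across conditions. This quantifies how much
#' smaller the exoskeleton-encoder range of motion is than the motion-capture
#' one.
#'
#' @param bio,exo Data frames (or matrices) with columns `df`, `pf`: maximal
#'   dorsiflexion and plantarflexion magnitudes (deg, both positive), one row
#'   per condition.
#' @return List: `per_condition` data frame (`rom_bio`, `rom_exo`, `diff`)
#'   and `average` (deg).
#' @export
rom_comparison <- function(bio, exo) {
  bio <- as.data.frame(bio); exo <- as.data.frame(exo)
  if (any(bio < 0) || any(exo < 0)) {
    stop("dorsiflexion/plantarflexion magnitudes must be >= 0", call. = FALSE)
  }
  rom_bio <- bio$df + bio$pf
  rom_exo <- exo$df + exo$pf
  per <- data.frame(rom_bio = rom_bio, rom_exo = rom_exo,
                    diff = rom_bio - rom_exo)
  list(per_condition = per, average = mean(per$diff))
}
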
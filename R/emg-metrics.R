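# EMG normalization, phase-restricted RMS, percent change, and the
# standardized mean difference.

#' Normalize EMG cycle ensembles to the BootsOnly reference
#'
#' Divides every curve of every condition by the subject-and-muscle-specific
#' maximum of the reference condition's mean curve (the boots-only maximum),
#' making amplitudes comparable across subjects and invariant to
#' subject-level gain. The mean-curve maximum (rather than the single
#' largest sample) is used for robustness to spikes.
#'
#' @param ensembles Named list of `cycle_ensemble`s, one per condition, for
#'   one subject and muscle.
#' @param reference Name of the reference condition (default `"BootsOnly"`).
#' @return List of normalized `cycle_ensemble`s with attribute
#'   `reference_max` (the divisor, mV).
#' @export
normalize_emg <- function(ensembles, reference = "BootsOnly") {
  if (!reference %in% names(ensembles)) {
    stop(sprintf("reference condition `%s` is missing", reference),
         call. = FALSE)
  }
  ref_max <- max(ensembles[[reference]]$mean)
  if (ref_max <= 0) {
    stop("reference condition has a zero maximum; cannot normalize",
         call. = FALSE)
  }
  out <- lapply(ensembles, function(e) {
    cycle_ensemble(e$curves / ref_max, e$stance_end, e$durations,
                   units = "normalized")
  })
  attr(out, "reference_max") <- ref_max
  out
}

#' Phase-restricted RMS of a cycle ensemble
#'
#' Root mean square of each stride's curve over its stance (heel contact to
#' toe-off) or swing (toe-off to next heel contact) window, then averaged
#' across the ensemble's strides. Plantar flexors are scored during stance,
#' the tibialis anterior during swing.
#'
#' @param ensemble A `cycle_ensemble` with known per-stride `stance_end`.
#' @param phase `"stance"` or `"swing"`.
#' @param pooled If `TRUE`, pool all phase samples across strides into one
#'   RMS instead of averaging per-stride RMS values.
#' @return RMS scalar (units of the ensemble).
#' @export
phase_rms <- function(ensemble, phase = c("stance", "swing"),
                      pooled = FALSE) {
  phase <- match.arg(phase)
  grid <- ensemble$grid
  vals_per_stride <- lapply(seq_len(nrow(ensemble$curves)), function(i) {
    se <- ensemble$stance_end[i]
    if (is.na(se)) return(NULL)
    sel <- if (phase == "stance") grid <= se else grid > se
    ensemble$curves[i, sel]
  })
  vals_per_stride <- Filter(Negate(is.null), vals_per_stride)
  if (length(vals_per_stride) == 0L ||
      any(vapply(vals_per_stride, length, 1L) == 0L)) {
    stop("empty phase window", call. = FALSE)
  }
  if (pooled) {
    rms(unlist(vals_per_stride))
  } else {
    mean(vapply(vals_per_stride, rms, numeric(1)))
  }
}

#' Signed percent change
#'
#' `100 * (b - a) / a`: negative when the second condition is lower.
#'
#' @param rms_a Reference value (> 0).
#' @param rms_b Comparison value.
#' @return Percent change.
#' @export
percent_change <- function(rms_a, rms_b) {
  if (any(rms_a <= 0)) stop("reference value must be > 0", call. = FALSE)
  100 * (rms_b - rms_a) / rms_a
}

#' Standardized mean difference
#'
#' Absolute difference in means divided by the mean of the two standard
#' deviations: `|mean_a - mean_b| / ((sd_a + sd_b) / 2)`. Values below 0.3
#' are conventionally considered small.
#'
#' @param mean_a,mean_b Group means.
#' @param sd_a,sd_b Group standard deviations (>= 0, not both zero).
#' @return List: `smd` and `magnitude` (`"small"` if below `small_cutoff`,
#'   else `"non-small"`).
#' @param small_cutoff Cutoff below which the effect is flagged small.
#' @export
smd <- function(mean_a, mean_b, sd_a, sd_b, small_cutoff = 0.3) {
  if (sd_a < 0 || sd_b < 0) stop("SDs must be >= 0", call. = FALSE)
  if (sd_a + sd_b == 0) stop("both SDs are zero", call. = FALSE)
  val <- abs(mean_a - mean_b) / ((sd_a + sd_b) / 2)
  list(smd = val,
       magnitude = if (val < small_cutoff) "small" else "non-small")
}
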
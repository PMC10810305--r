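# Trial CSV interchange: one CSV per trial with a `time_s` column followed by
# channel columns on the union time grid (mechanics channels are blank off
# their own grid), plus a JSON sidecar carrying units and ground truth.

KNOWN_CHANNELS <- c(EMG_CHANNELS, MECH_CHANNELS)

#' Write a trial recording to CSV (+ JSON sidecar)
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces the doubles exactly. The sidecar (`<path>.json`) stores
#' subject, condition, body mass, per-channel units/rates and the embedded
#' ground truth.
#'
#' @param trial A `trial_recording`.
#' @param path Output CSV path; the sidecar goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  rates <- vapply(trial$channels, function(ch) ch$rate, numeric(1))
  fs <- max(rates)
  n <- max(vapply(trial$channels, function(ch) length(ch$values), 1L) *
             fs / rates)
  tim <- (seq_len(n) - 1) / fs
  cols <- c(list(time_s = sprintf("%.17g", tim)),
            lapply(trial$channels, function(ch) {
              step <- fs / ch$rate
              out <- rep("", n)
              idx <- seq(1L, by = step, length.out = length(ch$values))
              out[idx] <- sprintf("%.17g", ch$values)
              out
            }))
  lines <- c(paste(names(cols), collapse = ","),
             do.call(paste, c(unname(cols), sep = ",")))
  writeLines(lines, path)
  sidecar <- list(
    subject_id = trial$subject_id, condition = trial$condition,
    body_mass = trial$body_mass,
    channels = lapply(trial$channels, function(ch)
      list(rate = ch$rate, units = ch$units)),
    ground_truth = trial$ground_truth
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a trial recording from CSV
#'
#' Expects a header row with `time_s` followed by channel names, strictly
#' increasing time, and groups channels by sampling rate (inferred from the
#' spacing of each channel's non-blank rows, or taken from the JSON sidecar
#' when present). Unknown channels are an error under `strict = TRUE`
#' (default), otherwise skipped with a warning.
#'
#' @param path CSV path written by [write_trial_csv()] (or matching schema).
#' @param strict Error (rather than warn) on unknown channels.
#' @return A `trial_recording`.
#' @export
read_trial_csv <- function(path, strict = TRUE) {
  d <- read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(d)) {
    stop("missing required `time_s` column", call. = FALSE)
  }
  tim <- d$time_s
  if (anyNA(tim) || any(diff(tim) <= 0)) {
    stop("`time_s` must be strictly increasing without duplicates",
         call. = FALSE)
  }
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path) else NULL
  chan_names <- setdiff(names(d), "time_s")
  unknown <- setdiff(chan_names, KNOWN_CHANNELS)
  if (length(unknown)) {
    msg <- sprintf("unknown channel column(s): %s",
                   paste(unknown, collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(paste(msg, "- skipped"))
    chan_names <- setdiff(chan_names, unknown)
  }
  channels <- lapply(chan_names, function(nm) {
    v <- d[[nm]]
    ok <- !is.na(v)
    units <- if (!is.null(side)) side$channels[[nm]]$units else ""
    rate <- if (!is.null(side)) side$channels[[nm]]$rate
            else 1 / stats::median(diff(tim[ok]))
    sampled_signal(v[ok], rate, units)
  })
  names(channels) <- chan_names
  gt <- if (!is.null(side)) side$ground_truth else NULL
  structure(list(
    subject_id = if (!is.null(side)) side$subject_id else NA_character_,
    condition = if (!is.null(side)) side$condition else NA_character_,
    channels = channels, ground_truth = gt,
    body_mass = if (!is.null(side)) side$body_mass else NA_real_
  ), class = "trial_recording")
}
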
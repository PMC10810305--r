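# End-to-end pipeline: simulate -> control -> biomechanics -> EMG metrics ->
# statistics, with per-subject condition summaries and group-level tests.

ANALYSIS_WINDOWS <- list(
  BootsOnly    = list(condition = "BootsOnly",    end = "last"),
  Unpowered    = list(condition = "Unpowered",    end = "last"),
  PoweredStart = list(condition = "Powered",      end = "first"),
  PoweredEnd   = list(condition = "Powered",      end = "last"),
  D1           = list(condition = "Deadaptation", end = "first"),
  D2           = list(condition = "Deadaptation", end = "last")
)

MUSCLE_PHASE <- c(sol = "stance", mg = "stance", lg = "stance", ta = "swing")

#' Analyze one subject's trials
#'
#' Runs the analysis side of the protocol on a subject's four condition
#' recordings: stride events from the vertical GRF, controller calibration on
#' the unpowered walking, zero-phase EMG envelopes, 30-stride analysis
#' windows (last of BootsOnly/Unpowered/PoweredEnd/D2, first of
#' PoweredStart/D1), boots-only EMG normalization, phase-restricted RMS per
#' muscle, and the exoskeleton/biological ankle decomposition in the
#' PoweredEnd window.
#'
#' @param trials Named list of `trial_recording`s (the four conditions).
#' @param controller A [controller_config()].
#' @param n_strides Strides per analysis window.
#' @param grf_threshold_N Event-detection threshold, N.
#' @param velocity_source Angle source for exoskeleton power, see
#'   [decompose_ankle()].
#' @return List of class `subject_summary`: `rms` (data frame with one row
#'   per muscle x window), `pct_change` (BootsOnly to PoweredEnd, per
#'   muscle), `decomposition` (`ankle_decomposition`), `calibration`,
#'   `emg_curves` (normalized mean envelope per muscle x window, for
#'   curve-level group tests), `mech_curves` (mean total ankle
#'   moment/angle/power in PoweredEnd).
#' @export
analyze_subject <- function(trials, controller = controller_config(),
                            n_strides = 30, grf_threshold_N = 20,
                            velocity_source = c("bio", "exo")) {
  velocity_source <- match.arg(velocity_source)
  stopifnot(all(CONDITIONS %in% names(trials)))
  fs_e <- trials$Unpowered$channels$emg_sol$rate

  events <- lapply(trials, function(tr)
    detect_events(tr$channels$grf_v$values, tr$channels$grf_v$rate,
                  grf_threshold_N))

  cal_env <- preprocess_emg(trials$Unpowered$channels$emg_sol$values,
                            fs_e, controller)
  calib <- calibrate(cal_env, fs_e, controller)

  win_events <- lapply(ANALYSIS_WINDOWS, function(w)
    select_window(events[[w$condition]], end = w$end, n = n_strides))

  # Filtering is restricted to a padded segment around each analysis window;
  # the 5 s pad dwarfs the filters' settling times, so segment envelopes are
  # numerically identical to full-recording ones inside the window.
  pad_s <- 5
  segment <- function(values, fs, wev) {
    t0 <- (wev$heel_strikes[1L] - 1) / wev$rate - pad_s
    t1 <- (wev$heel_strikes[length(wev$heel_strikes)] - 1) / wev$rate + pad_s
    i0 <- max(1L, floor(t0 * fs) + 1L)
    i1 <- min(length(values), ceiling(t1 * fs) + 1L)
    list(values = values[i0:i1], t_start = (i0 - 1L) / fs)
  }

  # normalized EMG ensembles and phase RMS per muscle
  rms_rows <- list()
  pct <- emg_curves <- list()
  for (m in MUSCLES) {
    ch <- paste0("emg_", m)
    ens <- lapply(names(ANALYSIS_WINDOWS), function(wn) {
      w <- ANALYSIS_WINDOWS[[wn]]
      seg <- segment(trials[[w$condition]]$channels[[ch]]$values, fs_e,
                     win_events[[wn]])
      env <- analysis_envelope(seg$values, fs_e, controller)
      time_normalize(env, fs_e, win_events[[wn]], units = "mV",
                     t_start = seg$t_start)
    })
    names(ens) <- names(ANALYSIS_WINDOWS)
    ens <- normalize_emg(ens, reference = "BootsOnly")
    vals <- vapply(ens, phase_rms, numeric(1), phase = MUSCLE_PHASE[[m]])
    rms_rows[[m]] <- data.frame(
      subject = trials[[1L]]$subject_id, muscle = toupper(m),
      condition = names(vals), phase = MUSCLE_PHASE[[m]],
      rms = unname(vals), row.names = NULL)
    pct[[m]] <- percent_change(vals[["BootsOnly"]], vals[["PoweredEnd"]])
    emg_curves[[m]] <- t(vapply(ens, function(e) e$mean, numeric(101)))
  }

  # ankle decomposition in the PoweredEnd window; the controller torque is
  # recomputed on a padded segment (transients from the segment cut decay
  # orders of magnitude below numerical tolerance within the pad)
  tr_p <- trials$Powered
  wev <- win_events$PoweredEnd
  seg_e <- segment(tr_p$channels$emg_sol$values, fs_e, wev)
  ctrl <- run_controller(seg_e$values, fs_e, calib, config = controller)
  fs_m <- tr_p$channels$ankle_moment$rate
  t_e <- seg_e$t_start + (seq_along(ctrl$torque) - 1) / fs_e
  seg_m <- segment(tr_p$channels$ankle_moment$values, fs_m, wev)
  t_m <- seg_m$t_start + (seq_along(seg_m$values) - 1) / fs_m
  tq_m <- approx(t_e, ctrl$torque, xout = t_m, rule = 2)$y
  ens_tot <- time_normalize(seg_m$values, fs_m, wev, units = "Nm/kg",
                            t_start = seg_m$t_start)
  ens_exo_tq <- time_normalize(tq_m, fs_m, wev, units = "Nm",
                               t_start = seg_m$t_start)
  seg_ba <- segment(tr_p$channels$ankle_angle$values, fs_m, wev)
  ens_bio_ang <- time_normalize(seg_ba$values, fs_m, wev, units = "deg",
                                t_start = seg_ba$t_start)
  seg_xa <- segment(tr_p$channels$exo_angle$values, fs_m, wev)
  ens_exo_ang <- time_normalize(seg_xa$values, fs_m, wev, units = "deg",
                                t_start = seg_xa$t_start)
  decomp <- decompose_ankle(ens_tot, ens_exo_tq, tr_p$body_mass,
                            ens_bio_ang, ens_exo_ang,
                            velocity_source = velocity_source)

  structure(list(
    rms = do.call(rbind, rms_rows),
    pct_change = unlist(pct),
    decomposition = decomp,
    calibration = calib,
    emg_curves = emg_curves,
    mech_curves = list(total_moment = ens_tot$mean,
                       bio_angle = ens_bio_ang$mean,
                       exo_angle = ens_exo_ang$mean)
  ), class = "subject_summary")
}

#' Run the full simulation + analysis pipeline
#'
#' Streams subjects through simulate -> control -> analyze, then runs the
#' group statistics: per-muscle percent change (BootsOnly to PoweredEnd),
#' repeated-measures one-way ANOVA across the six analysis windows with
#' Tukey HSD when significant, standardized mean differences, mean
#' exoskeleton contribution shares, and (optionally) curve-level permutation
#' SPM on the normalized envelopes. Deterministic for a fixed `config`
#' (including its seed).
#'
#' @param config A [gen_config()].
#' @param controller A [controller_config()].
#' @param n_strides Strides per analysis window.
#' @param spm Run the curve-level permutation SPM per muscle (costlier).
#' @param spm_n_perm Permutations for the SPM stage.
#' @param velocity_source Angle source for exoskeleton power.
#' @param out Optional path; when given, the report is written there as JSON.
#' @return List of class `exomyo_report`; see fields in the source.
#' @export
run_pipeline <- function(config = gen_config(),
                         controller = controller_config(),
                         n_strides = 30, spm = FALSE, spm_n_perm = 499,
                         velocity_source = c("bio", "exo"), out = NULL) {
  velocity_source <- match.arg(velocity_source)
  summaries <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    trials <- generate_subject(config, i, controller)
    summaries[[i]] <- analyze_subject(trials, controller, n_strides,
                                      velocity_source = velocity_source)
  }
  rms_table <- do.call(rbind, lapply(summaries, function(s) s$rms))
  pct <- t(vapply(summaries, function(s) s$pct_change,
                  numeric(length(MUSCLES))))
  colnames(pct) <- MUSCLES
  shares <- t(vapply(summaries, function(s)
    unlist(s$decomposition$shares), numeric(3)))
  exo_peak_power <- vapply(summaries, function(s)
    max(s$decomposition$power$exo), numeric(1))

  # scalar stats per muscle across the six windows (subjects cross windows)
  anova_by_muscle <- smd_by_muscle <- list()
  for (m in MUSCLES) {
    sub <- rms_table[rms_table$muscle == toupper(m), ]
    groups <- split(sub$rms[order(sub$condition, sub$subject)],
                    sub$condition[order(sub$condition, sub$subject)])
    groups <- groups[names(ANALYSIS_WINDOWS)]
    anova_by_muscle[[m]] <- oneway_anova(groups, repeated = TRUE)
    a <- groups$BootsOnly; b <- groups$PoweredEnd
    smd_by_muscle[[m]] <- smd(mean(a), mean(b), sd(a), sd(b))
  }

  spm_by_muscle <- NULL
  if (isTRUE(spm)) {
    spm_by_muscle <- lapply(setNames(MUSCLES, MUSCLES), function(m) {
      ens <- lapply(setNames(names(ANALYSIS_WINDOWS), names(ANALYSIS_WINDOWS)),
                    function(wn) t(vapply(summaries, function(s)
                      s$emg_curves[[m]][wn, ], numeric(101))))
      spm_anova_permutation(ens, n_perm = spm_n_perm,
                            seed = config$seed + 101L)
    })
  }

  cfg_file <- tempfile()
  saveRDS(config, cfg_file)
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_file)),
                   seed = config$seed,
                   n_subjects = config$n_subjects,
                   n_strides = n_strides,
                   package_version = as.character(utils::packageVersion("exomyo")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  unlink(cfg_file)

  report <- structure(list(
    manifest = manifest,
    rms_table = rms_table,
    pct_change = list(per_subject = pct,
                      mean = colMeans(pct),
                      sd = apply(pct, 2L, sd)),
    shares = list(per_subject = shares, mean = colMeans(shares)),
    exo_peak_power_wkg = list(per_subject = exo_peak_power,
                              mean = mean(exo_peak_power)),
    anova = anova_by_muscle,
    smd = smd_by_muscle,
    spm = spm_by_muscle,
    subject_summaries = summaries
  ), class = "exomyo_report")
  if (!is.null(out)) write_report(report, out)
  report
}

#' Serialize a pipeline report to JSON
#'
#' Writes the numeric content of an `exomyo_report` (manifest, RMS table,
#' percent changes, shares, test results) to a JSON file; the heavyweight
#' per-subject curve objects are omitted.
#'
#' @param report An `exomyo_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  slim <- list(
    manifest = report$manifest,
    rms_table = report$rms_table,
    pct_change = report$pct_change,
    shares = report$shares,
    exo_peak_power_wkg = report$exo_peak_power_wkg,
    anova = lapply(report$anova, function(a)
      list(F = a$F, df = as.list(a$df), p = a$p, method = a$method,
           posthoc = a$posthoc)),
    smd = report$smd,
    spm = if (!is.null(report$spm)) lapply(report$spm, function(s)
      list(threshold = s$threshold, p_max = s$p_max,
           significant = s$significant, clusters = s$clusters))
  )
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  invisible(path)
}

#' @export
print.exomyo_report <- function(x, ...) {
  cat("Proportional myoelectric exoskeleton adaptation report\n")
  cat(sprintf("  %d subjects, %d-stride windows, seed %d\n",
              x$manifest$n_subjects, x$manifest$n_strides, x$manifest$seed))
  cat("  EMG percent change, BootsOnly -> PoweredEnd (group mean):\n")
  for (m in names(x$pct_change$mean)) {
    cat(sprintf("    %-3s %+6.1f%%  (ANOVA p = %.3f, SMD = %.2f %s)\n",
                toupper(m), x$pct_change$mean[[m]], x$anova[[m]]$p,
                x$smd[[m]]$smd, x$smd[[m]]$magnitude))
  }
  cat(sprintf(
    "  exoskeleton shares (PoweredEnd): power %.2f, moment %.2f, +work %.2f\n",
    x$shares$mean[["peak_power"]], x$shares$mean[["peak_moment"]],
    x$shares$mean[["pos_work"]]))
  cat(sprintf("  exoskeleton peak power: %.2f W/kg\n",
              x$exo_peak_power_wkg$mean))
  invisible(x)
}
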
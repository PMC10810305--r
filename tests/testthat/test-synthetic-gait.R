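# Synthetic gait/EMG generator: envelope templates, adaptation dynamics,
# raw-EMG synthesis, encoder discrepancy, and whole-dataset structure.

test_that("burst envelope template sums Gaussians and validates input", {
  grid <- 0:100
  expect_equal(emg_envelope_template(data.frame(center = numeric(0),
                                                width = numeric(0),
                                                amp = numeric(0)), grid),
               rep(0, 101))
  one <- emg_envelope_template(data.frame(center = 45, width = 10, amp = 1),
                               grid)
  expect_equal(grid[which.max(one)], 45)
  expect_true(all(one >= 0))
  expect_error(
    emg_envelope_template(data.frame(center = 45, width = 10, amp = -1), grid),
    "amplitudes")
  expect_error(
    emg_envelope_template(data.frame(center = 45, width = 10, amp = 1),
                          c(-5, 50)), "phase_grid")
})

test_that("default plantar-flexor envelopes concentrate activity in stance", {
  grid <- seq(0, 100, by = 0.5)
  for (m in c("sol", "mg", "lg")) {
    env <- emg_envelope_template(default_burst_params()[[m]], grid)
    stance_mass <- sum(env[grid <= 60]) / sum(env)
    expect_gt(stance_mass, 0.75)
  }
})

test_that("adaptation factor follows the exponential approach", {
  ad <- list(change = -0.12, tau_min = 6)
  expect_equal(adaptation_factor(0, ad), 1)
  expect_equal(adaptation_factor(1e9, ad), 0.88)
  expect_equal(adaptation_factor(6, ad), 1 - 0.12 * (1 - exp(-1)))
  expect_error(adaptation_factor(5, list(change = -0.1, tau_min = 0)),
               "time constant")
  expect_error(adaptation_factor(-1, ad), ">= 0")
})

test_that("raw EMG synthesis is deterministic and respects the noise floor", {
  env <- rep(0, 4000)
  a <- synthesize_raw_emg(env, 1000, seed = 9, noise_floor = 0.02)
  b <- synthesize_raw_emg(env, 1000, seed = 9, noise_floor = 0.02)
  expect_identical(a, b)
  # all-zero envelope: output RMS equals the configured floor (unit-RMS carrier)
  expect_equal(sqrt(mean(a^2)), 0.02, tolerance = 1e-12)
  c2 <- synthesize_raw_emg(env, 1000, seed = 10, noise_floor = 0.02)
  expect_false(identical(a, c2))
  expect_error(synthesize_raw_emg(env, 800, seed = 1), "aliasing|band")
  expect_error(synthesize_raw_emg(rep(-1, 100), 1000, seed = 1), ">= 0")
})

test_that("controller envelope of constant-envelope EMG scales linearly", {
  # the causal chain recovers c * e for a constant envelope e; estimate the
  # chain scale c once at e = 1, then check stability across amplitudes
  fs <- 1000
  n <- 30 * fs
  extract <- function(e) {
    raw <- synthesize_raw_emg(rep(e, n), fs, seed = 4, noise_floor = 0)
    env <- preprocess_emg(raw, fs)
    mean(env[(5 * fs):n])
  }
  c1 <- extract(1)
  expect_gt(c1, 0.3)   # rectified-Gaussian mean scale, after HP losses
  expect_lt(c1, 1)
  for (e in c(0.5, 2)) {
    expect_equal(extract(e) / e, c1, tolerance = 0.02)
  }
})

test_that("exoskeleton angle is an affine compression of the biological angle", {
  bio <- c(-20, -5, 0, 5)
  expect_equal(exo_angle_from_bio(bio, list(angle_scale = 1, angle_offset = 0)),
               bio)
  expect_equal(exo_angle_from_bio(rep(3, 10),
                                  list(angle_scale = 0.44, angle_offset = 4.8)),
               rep(0.44 * 3 + 4.8, 10))
  # biological ROM 25 deg compresses to 11 deg at scale 0.44
  exo <- exo_angle_from_bio(bio, list(angle_scale = 0.44, angle_offset = 4.8))
  expect_equal(diff(range(exo)), 0.44 * 25)
  expect_error(exo_angle_from_bio(bio, list(angle_scale = -1,
                                            angle_offset = 0)), ">= 0")
})

test_that("generated dataset follows the protocol structure", {
  cfg <- small_config()
  trials <- small_subject()
  expect_named(trials, c("BootsOnly", "Unpowered", "Powered", "Deadaptation"))
  for (k in seq_len(nrow(cfg$timeline))) {
    tr <- trials[[cfg$timeline$condition[k]]]
    dur_s <- length(tr$channels$grf_v$values) / tr$channels$grf_v$rate
    expect_equal(dur_s, cfg$timeline$minutes[k] * 60, tolerance = 1e-6)
    # EMG and mechanics clocks cover the same span
    expect_equal(length(tr$channels$emg_sol$values) / tr$channels$emg_sol$rate,
                 dur_s, tolerance = 1e-6)
  }
  ds <- generate_dataset(small_config(n_subjects = 2))
  expect_length(ds, 8)  # 2 subjects x 4 conditions
})

test_that("identical configuration yields a byte-identical dataset", {
  t1 <- generate_subject(small_config(), 1)
  t2 <- generate_subject(small_config(), 1)
  expect_identical(t1, t2)
})

test_that("GRF is zero through swing and positive inside stance", {
  tr <- small_subject()$Powered
  grf <- tr$channels$grf_v$values
  fs <- tr$channels$grf_v$rate
  gt <- tr$ground_truth
  hs_t <- gt$hs_times
  for (i in seq_len(min(20, length(hs_t) - 1))) {
    dur <- hs_t[i + 1] - hs_t[i]
    t_sw0 <- hs_t[i] + 0.60 * dur
    sw <- grf[ceiling(t_sw0 * fs + 2):floor((hs_t[i + 1]) * fs - 1)]
    expect_true(all(sw == 0))
    st <- grf[(floor(hs_t[i] * fs) + 3):(floor(t_sw0 * fs) - 2)]
    expect_true(all(st > 0))
  }
})

test_that("ground-truth events are recovered within one mechanics sample", {
  tr <- small_subject()$Unpowered
  ev <- detect_events(tr$channels$grf_v$values, tr$channels$grf_v$rate)
  gt <- tr$ground_truth
  n_hs <- min(length(ev$heel_strikes), length(gt$hs_idx_mech))
  expect_gt(n_hs, 30)
  expect_true(all(abs(ev$heel_strikes[seq_len(n_hs)] -
                        gt$hs_idx_mech[seq_len(n_hs)]) <= 1))
  n_to <- min(length(ev$toe_offs), length(gt$to_idx_mech))
  expect_true(all(abs(ev$toe_offs[seq_len(n_to)] -
                        gt$to_idx_mech[seq_len(n_to)]) <= 1))
})

test_that("with adaptation disabled the powered envelopes are stationary", {
  cfg <- small_config(seed = 11, adaptation_enabled = FALSE)
  tr <- generate_subject(cfg, 1)$Powered
  ev <- detect_events(tr$channels$grf_v$values, tr$channels$grf_v$rate)
  env <- analysis_envelope(tr$channels$emg_sol$values,
                           tr$channels$emg_sol$rate)
  first <- time_normalize(env, tr$channels$emg_sol$rate,
                          select_window(ev, "first", 30))
  last <- time_normalize(env, tr$channels$emg_sol$rate,
                         select_window(ev, "last", 30))
  expect_equal(phase_rms(first, "stance"), phase_rms(last, "stance"),
               tolerance = 0.03)
})
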
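# Stride events, cycle normalization, joint power/work closed forms, the
# exoskeleton/biological decomposition, and the ROM comparison.

test_that("event detection handles degenerate force signals", {
  expect_warning(ev <- detect_events(rep(0, 1000), 100), "no threshold")
  expect_length(ev$heel_strikes, 0)
  expect_warning(ev2 <- detect_events(rep(10, 1000), 100, threshold_N = 20),
                 "no threshold")
  expect_length(ev2$heel_strikes, 0)
})

test_that("event detection recovers known square-wave events exactly", {
  fs <- 100
  grf <- rep(0, 1000)
  starts <- c(101, 211, 321, 431)
  for (s in starts) grf[s:(s + 59)] <- 700
  ev <- detect_events(grf, fs, threshold_N = 20)
  expect_equal(ev$heel_strikes, starts)
  expect_equal(ev$toe_offs, starts + 60L)
})

test_that("window selection takes contiguous strides from the requested end", {
  hs <- seq(1, by = 100, length.out = 36)   # 35 strides
  to <- hs[-length(hs)] + 60L
  ev <- structure(list(heel_strikes = hs, toe_offs = to, rate = 100),
                  class = "stride_events")
  w <- select_window(ev, "last", 30)
  expect_equal(w$heel_strikes, hs[6:36])    # strides 6..35
  expect_length(w$toe_offs, 30)
  w2 <- select_window(ev, "first", 30)
  expect_equal(w2$heel_strikes, hs[1:31])
  ev10 <- structure(list(heel_strikes = hs[1:11], toe_offs = to[1:10],
                         rate = 100), class = "stride_events")
  expect_error(select_window(ev10, "last", 30), "short by 20")
})

test_that("time normalization is exact on constant and affine signals", {
  fs <- 100
  hs <- c(1L, 101L, 201L)
  to <- c(61L, 161L)
  ev <- structure(list(heel_strikes = hs, toe_offs = to, rate = fs),
                  class = "stride_events")
  const <- time_normalize(rep(5, 250), fs, ev)
  expect_equal(dim(const$curves), c(2L, 101L))
  expect_true(all(abs(const$curves - 5) < 1e-12))
  expect_equal(const$stance_end, c(60, 60))
  ramp <- time_normalize(seq(0, 249) * 0.1, fs, ev)
  # a linear ramp stays linear: each cycle is an affine 101-point sequence
  for (i in 1:2) {
    expect_lt(max(abs(diff(ramp$curves[i, ]) - 0.1)), 1e-9)
  }
  # 30 selected strides give an ensemble of 30 curves
  hs30 <- seq(1L, by = 100L, length.out = 31L)
  ev30 <- structure(list(heel_strikes = hs30, toe_offs = hs30[-31] + 60L,
                         rate = fs), class = "stride_events")
  e30 <- time_normalize(rnorm(3100), fs, ev30)
  expect_equal(nrow(e30$curves), 30L)
})

test_that("joint power matches the sinusoid closed form", {
  s <- seq(0, 1, length.out = 101)
  angle <- matrix(sin(2 * pi * s), 1)     # deg
  moment <- matrix(cos(2 * pi * s), 1)    # Nm/kg
  p <- joint_power(moment, angle, durations = 1)
  expected <- 2 * pi * cos(2 * pi * s)^2 * pi / 180
  interior <- 5:97
  expect_equal(p[1, interior], expected[interior], tolerance = 0.005)
  expect_true(all(joint_power(moment, matrix(3, 1, 101), 1) == 0))
  expect_true(all(joint_power(matrix(0, 1, 101), angle, 1) == 0))
  expect_error(joint_power(moment, angle), "durations")
})

test_that("work decomposition matches analytic integrals", {
  expect_equal(work_decomposition(matrix(1, 1, 101), 1),
               data.frame(positive = 1, negative = 0))
  s <- seq(0, 1, length.out = 101)
  w <- work_decomposition(matrix(sin(2 * pi * s), 1), 1)
  expect_equal(w$positive, 1 / pi, tolerance = 0.005)
  expect_equal(w$negative, -1 / pi, tolerance = 0.005)
  wneg <- work_decomposition(matrix(pmin(sin(2 * pi * s), 0), 1), 1)
  expect_equal(wneg$positive, 0)
})

test_that("ankle decomposition conserves moments and computes shares", {
  s <- seq(0, 1, length.out = 101)
  tri <- function(peak, at, width) {
    pmax(0, peak * (1 - abs(s - at) / width))
  }
  n <- 5
  tot <- make_ensemble(matrix(rep(tri(2.0, 0.5, 0.2), n), n, byrow = TRUE),
                       durations = rep(1, n))
  exo <- make_ensemble(matrix(rep(tri(0.5 * 70, 0.5, 0.2), n), n,
                              byrow = TRUE), durations = rep(1, n))
  ang <- make_ensemble(matrix(rep(5 * sin(2 * pi * s), n), n, byrow = TRUE),
                       durations = rep(1, n))
  d <- decompose_ankle(tot, exo, body_mass = 70, bio_angle = ang)
  # co-timed triangles: bio 1.5 + exo 0.5 -> moment share 0.25
  expect_equal(d$shares$peak_moment, 0.25, tolerance = 1e-12)
  expect_equal(d$moment$total, d$moment$bio + d$moment$exo, tolerance = 1e-12)
  # zero exoskeleton torque -> all shares zero
  exo0 <- make_ensemble(matrix(0, n, 101), durations = rep(1, n))
  d0 <- decompose_ankle(tot, exo0, 70, ang)
  expect_equal(unname(unlist(d0$shares)), c(0, 0, 0))
  expect_error(decompose_ankle(tot, exo, 0, ang), "body_mass")
  expect_error(decompose_ankle(tot, exo, 70, ang, velocity_source = "exo"),
               "exo_angle")
})

test_that("total positive work dominates component works on co-signed fixtures", {
  s <- seq(0, 1, length.out = 101)
  n <- 3
  tot <- make_ensemble(matrix(rep(1 + 0.5 * sin(2 * pi * s), n), n,
                              byrow = TRUE))
  exo <- make_ensemble(matrix(rep(20 * (1 + 0.5 * sin(2 * pi * s)), n), n,
                              byrow = TRUE))
  ang <- make_ensemble(matrix(rep(-10 * s, n), n, byrow = TRUE))  # steady PF
  d <- decompose_ankle(tot, exo, 70, ang)
  expect_gte(d$works$total[["positive"]] + 1e-12,
             max(d$works$bio[["positive"]], d$works$exo[["positive"]]))
})

test_that("cycle-mean curves are insensitive to the mechanics sampling rate", {
  tmpl <- exomyo:::ankle_angle_template()
  mk <- function(fs) {
    dur <- 1.1
    n_str <- 12
    t <- seq(0, n_str * dur, by = 1 / fs)
    x <- tmpl((t %% dur) / dur * 100)
    hs <- round(seq(0, n_str) * dur * fs) + 1L
    ev <- structure(list(heel_strikes = hs, toe_offs = hs[-length(hs)] +
                           round(0.6 * dur * fs), rate = fs),
                    class = "stride_events")
    time_normalize(x, fs, ev)$mean
  }
  m100 <- mk(100)
  m200 <- mk(200)
  expect_lt(max(abs(m100 - m200)) / diff(range(m100)), 0.01)
})

test_that("ROM comparison reproduces the printed per-condition differences", {
  same <- data.frame(df = c(5, 8), pf = c(20, 14))
  expect_equal(rom_comparison(same, same)$average, 0)
  # unpowered endpoints: 5 DF / 20 PF by motion capture vs 7 DF / 4 PF
  one <- rom_comparison(data.frame(df = 5, pf = 20),
                        data.frame(df = 7, pf = 4))
  expect_equal(one$per_condition$diff, 25 - 11)
  expect_error(rom_comparison(data.frame(df = -1, pf = 5),
                              data.frame(df = 1, pf = 1)), ">= 0")
})
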
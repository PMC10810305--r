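# Independent oracles and small fixtures shared across the test files.

# --- independently coded Butterworth biquad (bilinear transform) ----------
# Standard 2nd-order Butterworth via analog prototype + bilinear transform
# with frequency prewarping; deliberately not using the signal package so it
# can serve as an independent oracle for the controller's filter chain.
biquad_butter2 <- function(cutoff, fs, type = c("low", "high")) {
  type <- match.arg(type)
  K <- tan(pi * cutoff / fs)
  norm <- 1 / (1 + sqrt(2) * K + K^2)
  if (type == "low") {
    b <- c(K^2, 2 * K^2, K^2) * norm
  } else {
    b <- c(1, -2, 1) * norm
  }
  a <- c(1, 2 * (K^2 - 1) * norm, (1 - sqrt(2) * K + K^2) * norm)
  list(b = b, a = a)
}

# direct-form difference equation, zero initial conditions
df1_filter <- function(coef, x) {
  b <- coef$b; a <- coef$a
  n <- length(x)
  y <- numeric(n)
  for (t in seq_len(n)) {
    y[t] <- b[1] * x[t] +
      (if (t > 1) b[2] * x[t - 1] - a[2] * y[t - 1] else 0) +
      (if (t > 2) b[3] * x[t - 2] - a[3] * y[t - 2] else 0)
  }
  y
}

# full envelope chain via the oracle filters: causal HP -> |.| -> causal LP
oracle_envelope <- function(raw, fs, hp_cutoff = 50, lp_cutoff = 8) {
  hp <- biquad_butter2(hp_cutoff, fs, "high")
  lp <- biquad_butter2(lp_cutoff, fs, "low")
  pmax(df1_filter(lp, abs(df1_filter(hp, raw))), 0)
}

# --- brute-force ANOVA sums of squares ------------------------------------
brute_anova <- function(groups) {
  y <- unlist(groups)
  k <- length(groups)
  N <- length(y)
  gm <- mean(y)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 1) - gm)^2)
  ssw <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
  Fv <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fv, df = c(k - 1, N - k),
       p = pf(Fv, k - 1, N - k, lower.tail = FALSE))
}

# repeated-measures: subjects cross conditions (two-way, no interaction)
brute_rm_anova <- function(groups) {
  k <- length(groups)
  n <- length(groups[[1]])
  y <- do.call(cbind, groups)           # n subjects x k conditions
  gm <- mean(y)
  ss_cond <- n * sum((colMeans(y) - gm)^2)
  ss_subj <- k * sum((rowMeans(y) - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  Fv <- (ss_cond / df1) / (ss_err / df2)
  list(F = Fv, df = c(df1, df2),
       p = pf(Fv, df1, df2, lower.tail = FALSE))
}

# --- fixtures --------------------------------------------------------------

# short-timeline configuration: full protocol shape, minutes shrunk so a
# subject generates in ~2 s while leaving >30 strides per condition
small_config <- function(seed = 42, n_subjects = 2, ...) {
  gen_config(
    n_subjects = n_subjects, seed = seed,
    timeline = data.frame(
      condition = c("BootsOnly", "Unpowered", "Powered", "Deadaptation"),
      minutes = c(1, 1, 2, 1)),
    ...
  )
}

# cache one generated subject for reuse across test files
small_subject <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_subject(small_config(), 1)
    cache
  }
})

# build a cycle_ensemble directly from a curve matrix
make_ensemble <- function(curves, stance_end = rep(60, nrow(curves)),
                          durations = rep(1, nrow(curves)), units = "") {
  exomyo:::cycle_ensemble(curves, stance_end, durations, units)
}
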
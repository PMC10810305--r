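# Scalar ANOVA/Tukey, permutation SPM, and the paired-t sample-size scan.

test_that("one-way ANOVA matches hand-computed sums of squares", {
  r <- oneway_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
  expect_equal(r$F, 3)
  expect_equal(unname(r$df), c(2, 6))
  o <- brute_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
  expect_equal(r$p, o$p, tolerance = 1e-12)
  same <- oneway_anova(list(a = c(1, 2), b = c(1, 2), c = c(1, 2)))
  expect_equal(same$F, 0)
  # two groups: F equals the squared pooled-variance t statistic
  set.seed(2)
  x <- rnorm(8); y <- rnorm(9, 0.5)
  expect_equal(oneway_anova(list(x = x, y = y))$F,
               unname(t.test(x, y, var.equal = TRUE)$statistic^2),
               tolerance = 1e-10)
  expect_error(oneway_anova(list(a = 1, b = c(1, 2))), "at least 2 values")
  expect_error(oneway_anova(list(a = c(1, 2))), "at least 2 groups")
})

test_that("ANOVA agrees with the brute-force oracle on random instances", {
  set.seed(7)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(3:8, 1), mean = j / 4))
    names(groups) <- paste0("g", seq_len(k))
    r <- oneway_anova(groups)
    o <- brute_anova(groups)
    expect_equal(r$F, o$F, tolerance = 1e-10)
    expect_equal(r$p, o$p, tolerance = 1e-10)
  }
})

test_that("repeated-measures ANOVA uses the within-subject error term", {
  set.seed(8)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    groups <- lapply(1:4, function(j) rnorm(n, mean = j / 5))
    names(groups) <- paste0("c", 1:4)
    r <- oneway_anova(groups, repeated = TRUE)
    o <- brute_rm_anova(groups)
    expect_equal(r$F, o$F, tolerance = 1e-10)
    expect_equal(unname(r$df), o$df)
    expect_equal(r$p, o$p, tolerance = 1e-10)
  }
})

test_that("post-hoc comparisons attach only under a significant omnibus test", {
  set.seed(9)
  null_groups <- lapply(1:3, function(j) rnorm(6))
  names(null_groups) <- letters[1:3]
  shifted <- null_groups
  shifted$c <- shifted$c + 10
  expect_null(oneway_anova(null_groups)$posthoc)
  r <- oneway_anova(shifted)
  expect_s3_class(r$posthoc, "data.frame")
})

test_that("Tukey HSD adjusts pairwise comparisons as expected", {
  set.seed(10)
  a <- rnorm(8); b <- rnorm(8)
  two <- tukey_hsd(list(a = a, b = b))
  # a single comparison carries no multiplicity penalty
  expect_equal(two$p_adj, t.test(a, b, var.equal = TRUE)$p.value,
               tolerance = 1e-10)
  ident <- tukey_hsd(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_gt(ident$p_adj, 0.99)
  three <- tukey_hsd(list(a = rnorm(8), b = rnorm(8), c = rnorm(8) + 10))
  pc <- three$p_adj[grepl("c", three$pair)]
  expect_true(all(pc < 0.001))
  expect_gt(three$p_adj[!grepl("c", three$pair)], 0.05)
})

test_that("SPM permutation ANOVA finds no effect in identical ensembles", {
  set.seed(11)
  base <- matrix(rnorm(10 * 101), 10)
  r <- spm_anova_permutation(list(a = base, b = base, c = base),
                             n_perm = 199, seed = 2)
  expect_false(r$significant)
  expect_null(r$clusters)
  expect_true(all(r$F_curve < 1e-20))
})

test_that("SPM localizes a difference injected at 40-60% of the cycle", {
  set.seed(12)
  grid <- seq(0, 100, length.out = 101)
  bump <- exp(-((grid - 50)^2) / (2 * 4^2))
  mk <- function(shift) t(replicate(10, rnorm(101, sd = 0.5) + shift * bump))
  r <- spm_anova_permutation(list(a = mk(0), b = mk(0), c = mk(2)),
                             n_perm = 199, seed = 3)
  expect_true(r$significant)
  expect_false(is.null(r$clusters))
  # the detected cluster overlaps the injected 40-60% window
  expect_true(any(r$clusters$start_pct <= 60 & r$clusters$end_pct >= 40))
})

test_that("SPM p-values are invariant to relabeling and constant shifts", {
  set.seed(13)
  ens <- list(a = matrix(rnorm(8 * 101), 8),
              b = matrix(rnorm(8 * 101, 0.2), 8),
              c = matrix(rnorm(8 * 101), 8))
  r1 <- spm_anova_permutation(ens, n_perm = 199, seed = 4)
  relab <- ens
  names(relab) <- c("x", "y", "z")
  r2 <- spm_anova_permutation(relab, n_perm = 199, seed = 4)
  shifted <- lapply(ens, function(m) m + 5)
  r3 <- spm_anova_permutation(shifted, n_perm = 199, seed = 4)
  expect_equal(r2$p_max, r1$p_max)
  expect_equal(r3$p_max, r1$p_max)
  expect_equal(r3$F_curve, r1$F_curve, tolerance = 1e-9)
  expect_gte(r1$p_max, 1 / 200)   # (b + 1)/(n_perm + 1) convention
  expect_error(spm_anova_permutation(list(a = matrix(0, 2, 101),
                                          b = matrix(0, 2, 50))), "grids")
})

test_that("paired-t sample size reproduces the noncentral-t solutions", {
  expect_equal(paired_t_sample_size(0.5, 0.05, 0.8, tails = 2), 34)
  # independent oracle: power.t.test's fractional n, rounded up
  expect_equal(ceiling(power.t.test(delta = 0.5, sd = 1, power = 0.8,
                                    type = "paired")$n), 34)
  n1 <- paired_t_sample_size(0.97, tails = 1)
  n2 <- paired_t_sample_size(0.97, tails = 2)
  expect_equal(n1, 9)
  expect_equal(n2, 11)
  # one-tailed power at n = 8 sits just under the 0.8 target, which is why
  # fractional-n software reports 8 for this effect size
  p8 <- 1 - pt(qt(0.95, 7), 7, ncp = 0.97 * sqrt(8))
  expect_equal(p8, 0.8, tolerance = 0.01)
  expect_lt(p8, 0.8)
  # monotone: larger effects never need more pairs
  ns <- vapply(c(0.3, 0.5, 0.8, 1.2), paired_t_sample_size, numeric(1))
  expect_true(all(diff(ns) <= 0))
  expect_error(paired_t_sample_size(0), "> 0")
  expect_error(paired_t_sample_size(0.5, alpha = 0.05, power = 0.04),
               "power")
})
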
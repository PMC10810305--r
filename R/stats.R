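# Scalar and curve-level inference: one-way (optionally repeated-measures)
# ANOVA with Tukey HSD post-hoc, permutation-based one-dimensional
# statistical parametric mapping, and paired-t sample-size calculation.

as_long <- function(groups) {
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  data.frame(
    y = unlist(groups, use.names = FALSE),
    condition = factor(rep(names(groups), lengths(groups)),
                       levels = names(groups)),
    subject = factor(unlist(lapply(groups, seq_along)))
  )
}

#' One-way ANOVA across conditions
#'
#' Classical one-way ANOVA, or the repeated-measures variant (subjects cross
#' conditions; values within each group must be ordered by subject) when
#' `repeated = TRUE`. Post-hoc comparisons are attached only when the
#' omnibus test is significant at `alpha`.
#'
#' @param groups Named list of numeric vectors, one per condition; each with
#'   at least 2 values (equal lengths required for `repeated = TRUE`).
#' @param repeated Use the repeated-measures error term.
#' @param alpha Significance level gating the post-hoc step.
#' @return List of class `scalar_test_result`: `F`, `df` (between, within),
#'   `p`, `method`, and `posthoc` (Tukey HSD data frame or `NULL`).
#' @export
oneway_anova <- function(groups, repeated = FALSE, alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2L)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  if (repeated && length(unique(lengths(groups))) != 1L) {
    stop("repeated-measures ANOVA needs equal group sizes", call. = FALSE)
  }
  d <- as_long(groups)
  fit <- if (repeated) aov(y ~ subject + condition, data = d)
         else aov(y ~ condition, data = d)
  tab <- summary(fit)[[1L]]
  row <- which(trimws(rownames(tab)) == "condition")
  Fv <- tab[row, "F value"]
  df <- c(between = tab[row, "Df"], within = tab[nrow(tab), "Df"])
  p <- tab[row, "Pr(>F)"]
  res <- list(F = Fv, df = df, p = p,
              method = if (repeated) "repeated-measures one-way ANOVA"
                       else "one-way ANOVA",
              posthoc = NULL)
  if (is.finite(p) && p < alpha) {
    res$posthoc <- tukey_hsd(groups, repeated = repeated)
  }
  class(res) <- "scalar_test_result"
  res
}

#' @export
print.scalar_test_result <- function(x, ...) {
  cat(sprintf("%s: F(%d, %d) = %.3f, p = %.4g\n", x$method,
              x$df[1L], x$df[2L], x$F, x$p))
  if (!is.null(x$posthoc)) {
    cat("Tukey HSD post-hoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise condition differences with studentized-range adjusted
#' p-values, using the same error term as the corresponding ANOVA.
#'
#' @inheritParams oneway_anova
#' @return Data frame: `pair`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(groups, repeated = FALSE) {
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2L)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  d <- as_long(groups)
  fit <- if (repeated) aov(y ~ subject + condition, data = d)
         else aov(y ~ condition, data = d)
  tk <- TukeyHSD(fit, which = "condition")$condition
  data.frame(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"], row.names = NULL)
}

# Pointwise one-way F statistic over curve columns. X: N x P matrix,
# g: factor of length N.
f_curve <- function(X, g) {
  N <- nrow(X); k <- nlevels(g)
  gm <- colMeans(X)
  sums <- rowsum(X, g)
  cnt <- as.vector(table(g))
  means <- sums / cnt
  ssb <- colSums(cnt * (means - matrix(gm, k, ncol(X), byrow = TRUE))^2)
  sst <- colSums((X - matrix(gm, N, ncol(X), byrow = TRUE))^2)
  ssw <- pmax(sst - ssb, 0)
  dfb <- k - 1L; dfw <- N - k
  (ssb / dfb) / (ssw / dfw)
}

#' Permutation-based one-dimensional SPM ANOVA
#'
#' Pointwise one-way F statistic along the 101-point gait-cycle grid, with
#' family-wise inference by the maximum-statistic permutation method:
#' condition labels of the subject-mean curves are permuted, the null
#' distribution of the curve-wide maximum F sets the critical threshold, and
#' suprathreshold clusters receive cluster-mass permutation p-values.
#' Permutation p-values use the `(b + 1) / (n_perm + 1)` convention.
#'
#' @param ensembles Named list (one per condition) of matrices
#'   `n_subjects x n_points` of subject-mean curves, all on the same grid.
#' @param n_perm Number of label permutations (>= 100).
#' @param alpha Family-wise significance level.
#' @param seed Integer seed for the permutation draws.
#' @return List of class `spm_anova`: `F_curve`, `threshold`, `p_max`
#'   (permutation p of the observed curve-wide max F), `clusters` (data
#'   frame: `start_pct`, `end_pct`, `mass`, `p`), `significant`.
#' @export
spm_anova_permutation <- function(ensembles, n_perm = 999, alpha = 0.05,
                                  seed = 1) {
  P <- unique(vapply(ensembles, ncol, 1L))
  if (length(P) != 1L) stop("curve grids do not match", call. = FALSE)
  if (n_perm < 100) stop("`n_perm` must be >= 100", call. = FALSE)
  X <- do.call(rbind, ensembles)
  g <- factor(rep(names(ensembles), vapply(ensembles, nrow, 1L)))
  obs <- f_curve(X, g)
  N <- nrow(X)
  perm_F <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(b) f_curve(X, g[sample.int(N)]),
           numeric(P))
  })                                            # P x n_perm
  null_max <- apply(perm_F, 2L, max)
  p_max <- (1 + sum(null_max >= max(obs))) / (n_perm + 1)
  m <- max(1L, floor(alpha * (n_perm + 1)))
  threshold <- sort(null_max, decreasing = TRUE)[m]

  grid <- seq(0, 100, length.out = P)
  cluster_runs <- function(f) {
    r <- rle(f > threshold)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    idx <- which(r$values)
    lapply(idx, function(j) starts[j]:ends[j])
  }
  obs_runs <- cluster_runs(obs)
  clusters <- NULL
  if (length(obs_runs)) {
    null_mass <- apply(perm_F, 2L, function(f) {
      runs <- cluster_runs(f)
      if (!length(runs)) 0
      else max(vapply(runs, function(r) sum(f[r] - threshold), numeric(1)))
    })
    clusters <- do.call(rbind, lapply(obs_runs, function(r) {
      mass <- sum(obs[r] - threshold)
      data.frame(start_pct = grid[r[1L]], end_pct = grid[r[length(r)]],
                 mass = mass,
                 p = (1 + sum(null_mass >= mass)) / (n_perm + 1))
    }))
  }
  structure(list(F_curve = obs, threshold = threshold, p_max = p_max,
                 clusters = clusters, alpha = alpha, n_perm = n_perm,
                 grid = grid, significant = p_max <= alpha),
            class = "spm_anova")
}

#' @export
print.spm_anova <- function(x, ...) {
  cat(sprintf(
    "<spm_anova> max F = %.2f, permutation threshold %.2f (alpha %.2f, %d perms)\n",
    max(x$F_curve), x$threshold, x$alpha, x$n_perm))
  cat(sprintf("  curve-wide p = %.4g (%s)\n", x$p_max,
              if (x$significant) "significant" else "not significant"))
  if (!is.null(x$clusters)) {
    for (i in seq_len(nrow(x$clusters))) {
      cat(sprintf("  cluster %d: %.0f-%.0f%% of cycle, p = %.4g\n", i,
                  x$clusters$start_pct[i], x$clusters$end_pct[i],
                  x$clusters$p[i]))
    }
  }
  invisible(x)
}

paired_t_power <- function(n, d, alpha, tails) {
  df <- n - 1
  ncp <- d * sqrt(n)
  if (tails == 2) {
    crit <- qt(1 - alpha / 2, df)
    1 - pt(crit, df, ncp = ncp) + pt(-crit, df, ncp = ncp)
  } else {
    crit <- qt(1 - alpha, df)
    1 - pt(crit, df, ncp = ncp)
  }
}

#' Required sample size for a paired t-test
#'
#' Smallest `n` whose exact noncentral-t power reaches the target for a
#' paired test at effect size `d` (mean difference over SD of differences).
#'
#' @param d Effect size (> 0).
#' @param alpha Type-I error level, in (0, 1).
#' @param power Target power, in (`alpha`, 1).
#' @param tails 1 or 2.
#' @return Required number of pairs (integer).
#' @export
paired_t_sample_size <- function(d, alpha = 0.05, power = 0.8, tails = 2) {
  if (d <= 0) stop("`d` must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0,1)", call. = FALSE)
  if (power <= alpha || power >= 1) {
    stop("`power` must be in (alpha, 1)", call. = FALSE)
  }
  if (!tails %in% c(1, 2)) stop("`tails` must be 1 or 2", call. = FALSE)
  for (n in 2:1000000) {
    if (paired_t_power(n, d, alpha, tails) >= power) return(n)
  }
  stop("no n below 1e6 reaches the requested power", call. = FALSE)
}
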
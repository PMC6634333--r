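#' Fisher confidence interval for a correlation
#'
#' Transforms r to Fisher's z, takes z +/- multiplier/sqrt(n - 3), and
#' back-transforms.  The default multiplier is 1.96 (the conventional
#' presentation value rather than `qnorm(0.975)`).
#'
#' @param r Pearson correlation.
#' @param n Sample size (>= 4).
#' @param multiplier Half-width multiplier on the z scale.
#' @return Numeric vector `c(low, high)`.
#' @export
#' @examples
#' fisher_ci(0.87, 2831)  # (.86, .88) at two decimals
fisher_ci <- function(r, n, multiplier = 1.96) {
  if (n < 4) stop("need n >= 4 for a Fisher confidence interval")
  if (abs(r) >= 1) return(c(r, r))  # degenerate: perfectly linear
  z <- atanh(r) + c(-1, 1) * multiplier / sqrt(n - 3)
  tanh(z)
}

#' Pearson correlation with a Fisher confidence interval
#'
#' @param x,y Numeric vectors of equal length (n >= 4), neither constant.
#' @param multiplier CI half-width multiplier on the Fisher-z scale
#'   (default 1.96).
#' @return Object of class `correlation_report`: list with `r`, `n`,
#'   `ci_low`, `ci_high` and `r_rounded` (two-decimal half-up presentation
#'   value; the raw `r` is retained).
#' @export
pearson_with_ci <- function(x, y, multiplier = 1.96) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  r <- stats::cor(x, y)
  ci <- fisher_ci(r, n, multiplier)
  structure(list(r = r, n = n, ci_low = ci[1], ci_high = ci[2],
                 r_rounded = round_half_up(r)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("r = %.2f (%.2f-%.2f), n = %d\n",
              x$r_rounded, round_half_up(x$ci_low), round_half_up(x$ci_high),
              x$n))
  invisible(x)
}

#' Spearman-Brown correction of a split-half correlation
#'
#' Projects the correlation between two half-length measurements to the
#' reliability of the full-length measurement: \eqn{2r/(1+r)}.
#'
#' @param r_half Split-half correlation in (-1, 1].
#' @return Corrected reliability.
#' @export
spearman_brown <- function(r_half) {
  if (any(r_half == -1)) stop("Spearman-Brown undefined at r = -1")
  2 * r_half / (1 + r_half)
}

#' Split-half reliability of mean ratings
#'
#' Repeatedly splits the raters at random into two halves (sizes differing
#' by at most one), correlates the two halves' per-word mean ratings
#' across words, applies the Spearman-Brown correction, and returns the
#' mean over randomizations.
#'
#' @param rater_matrix Raters x words matrix of ratings; missing ratings
#'   allowed (`NA`).  Words with no rating in one half of a given split
#'   are dropped for that randomization (logged once).
#' @param n_rand Number of random splits (default 10000).
#' @param seed Integer seed; the estimate is bit-reproducible given the
#'   seed.
#' @param keep_values Retain the per-randomization corrected correlations.
#' @return Object of class `reliability_report`: list with `reliability`
#'   (mean corrected split-half correlation), `n_randomizations`,
#'   `n_raters`, `n_words` and optionally `values`.
#' @export
split_half_reliability <- function(rater_matrix, n_rand = 10000, seed = 1,
                                   keep_values = FALSE) {
  R <- nrow(rater_matrix)
  W <- ncol(rater_matrix)
  if (R < 2) stop("need at least 2 raters")
  if (W < 4) stop("need at least 4 words")
  if (n_rand < 1) stop("need at least one randomization")
  vals <- numeric(n_rand)
  n_dropped <- 0L
  with_substream(seed, "split_half", {
    half <- R %/% 2
    for (b in seq_len(n_rand)) {
      idx <- sample.int(R, half)
      m1 <- colMeans(rater_matrix[idx, , drop = FALSE], na.rm = TRUE)
      m2 <- colMeans(rater_matrix[-idx, , drop = FALSE], na.rm = TRUE)
      ok <- is.finite(m1) & is.finite(m2)
      n_dropped <- n_dropped + sum(!ok)
      vals[b] <- spearman_brown(stats::cor(m1[ok], m2[ok]))
    }
  })
  if (n_dropped > 0)
    log_info("split_half_reliability: dropped %d word-halves with all ratings missing",
             n_dropped)
  structure(list(reliability = mean(vals), n_randomizations = n_rand,
                 n_raters = R, n_words = W,
                 values = if (keep_values) vals else NULL),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("split-half reliability = %.3f (%d raters, %d words, %d randomizations)\n",
              x$reliability, x$n_raters, x$n_words, x$n_randomizations))
  invisible(x)
}

#' Correction for attenuation
#'
#' Divides an observed correlation by the square root of the product of
#' the two measures' reliabilities to estimate the correlation between
#' their true scores.  When one measure is a model prediction its
#' reliability is conventionally set to one, so only the human norms'
#' reliability attenuates the correlation.
#'
#' @param r Observed correlation in \[-1, 1\].
#' @param rel_a,rel_b Reliabilities in (0, 1]; `rel_b` defaults to 1.
#' @return Disattenuated correlation, clipped to \[-1, 1\] with a warning
#'   if the raw quotient exceeds the bound.
#' @export
#' @examples
#' disattenuate(0.84, 0.97)  # 0.85 at two decimals
disattenuate <- function(r, rel_a, rel_b = 1) {
  if (rel_a <= 0 || rel_b <= 0) stop("reliabilities must be positive")
  if (rel_a > 1 || rel_b > 1) stop("reliabilities cannot exceed 1")
  out <- r / sqrt(rel_a * rel_b)
  if (abs(out) > 1) {
    warning("disattenuated correlation exceeds 1 in magnitude; clipped")
    out <- sign(out)
  }
  out
}

#' Incremental variance explained by a second predictor
#'
#' Regresses the human ratings on the primary predictions by ordinary
#' least squares, then regresses those residuals on the other source's
#' predictions.  The reported R-squared is the variance the second fit
#' explains as a share of the human ratings' total variance -- the
#' additional variance the other source accounts for beyond the primary
#' one -- so it adds with the first-stage R-squared to at most 1.
#'
#' @param human Human rating vector.
#' @param pred_primary Predictions whose residuals are analysed.
#' @param pred_other Predictions of the other data source.
#' @return List with `r_squared` (incremental, share of total variance),
#'   `p_value` (F test of the residual regression) and `n`.
#' @export
residual_incremental_r2 <- function(human, pred_primary, pred_other) {
  if (length(unique(c(length(human), length(pred_primary), length(pred_other)))) != 1)
    stop("inputs must have equal length")
  if (stats::sd(pred_primary) == 0 || stats::sd(pred_other) == 0)
    stop("constant predictor")
  res <- stats::resid(stats::lm(human ~ pred_primary))
  fit <- summary(stats::lm(res ~ pred_other))
  p <- stats::pf(fit$fstatistic[1], fit$fstatistic[2], fit$fstatistic[3],
                 lower.tail = FALSE)
  share_residual <- sum(res^2) / sum((human - mean(human))^2)
  list(r_squared = unname(fit$r.squared) * share_residual,
       p_value = unname(p), n = length(human))
}

#' Fisher z test for two independent correlations
#'
#' @param r1,r2 Correlations from two independent samples (|r| < 1).
#' @param n1,n2 Sample sizes (>= 4).
#' @return Object of class `comparison_report` with the z statistic, the
#'   two-tailed p value and the difference `r1 - r2`.
#' @export
compare_independent_correlations <- function(r1, n1, r2, n2) {
  if (n1 < 4 || n2 < 4) stop("need n >= 4 in both samples")
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| = 1: test undefined")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  structure(list(design = "independent", r1 = r1, r2 = r2, n1 = n1, n2 = n2,
                 difference = r1 - r2,
                 statistics = c(fisher1925 = z),
                 p_values = c(fisher1925 = p),
                 p = p),
            class = "comparison_report")
}

# Dependent overlapping correlations: r_hy1 = cor(h, y1), r_hy2 = cor(h, y2)
# share the variable h; r_y1y2 = cor(y1, y2).  Each method tests
# H0: rho_hy1 = rho_hy2 on one sample of size n.

steiger_z <- function(r1, r2, r12, n) {
  rb <- (r1 + r2) / 2
  c_ <- (r12 * (1 - 2 * rb^2) - 0.5 * rb^2 * (1 - 2 * rb^2 - r12^2)) /
    (1 - rb^2)^2
  (atanh(r1) - atanh(r2)) * sqrt((n - 3) / (2 - 2 * c_))
}

meng_z <- function(r1, r2, r12, n) {
  rb2 <- (r1^2 + r2^2) / 2
  f <- min((1 - r12) / (2 * (1 - rb2)), 1)
  h <- (1 - f * rb2) / (1 - rb2)
  (atanh(r1) - atanh(r2)) * sqrt((n - 3) / (2 * (1 - r12) * h))
}

hittner_z <- function(r1, r2, r12, n) {
  rm <- tanh((atanh(r1) + atanh(r2)) / 2)
  c_ <- (r12 * (1 - 2 * rm^2) - 0.5 * rm^2 * (1 - 2 * rm^2 - r12^2)) /
    (1 - rm^2)^2
  (atanh(r1) - atanh(r2)) * sqrt((n - 3) / (2 - 2 * c_))
}

#' Tests for two dependent overlapping correlations
#'
#' Compares `cor(h, y1)` against `cor(h, y2)` when both are computed on
#' the same sample and share the variable `h`.  Three published z tests
#' are evaluated -- Steiger's (1980) modified z with pooled correlation,
#' the Meng-Rosenthal-Rubin (1992) z, and the Hittner-May-Silver (2003)
#' z with back-transformed mean Fisher z -- and the largest (most
#' conservative) two-tailed p value is reported alongside each method's
#' own p.
#'
#' @param r_hy1,r_hy2 The two overlapping correlations.
#' @param r_y1y2 Correlation between the two non-shared variables.
#' @param n Sample size (>= 10).
#' @return Object of class `comparison_report`: per-method `statistics`
#'   and `p_values`, the conservative `p` (their maximum), and the
#'   difference `r_hy1 - r_hy2`.
#' @export
compare_dependent_correlations <- function(r_hy1, r_hy2, r_y1y2, n) {
  if (n < 10) stop("need n >= 10")
  if (abs(r_hy1) >= 1 || abs(r_hy2) >= 1) stop("|r| = 1: test undefined")
  cm <- matrix(c(1, r_hy1, r_hy2,
                 r_hy1, 1, r_y1y2,
                 r_hy2, r_y1y2, 1), 3, 3)
  if (min(eigen(cm, symmetric = TRUE, only.values = TRUE)$values) < -1e-12)
    stop("the three correlations do not form a positive semidefinite matrix")
  z <- c(steiger1980 = steiger_z(r_hy1, r_hy2, r_y1y2, n),
         meng1992 = meng_z(r_hy1, r_hy2, r_y1y2, n),
         hittner2003 = hittner_z(r_hy1, r_hy2, r_y1y2, n))
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  structure(list(design = "dependent-overlapping",
                 r1 = r_hy1, r2 = r_hy2, r_y1y2 = r_y1y2, n = n,
                 difference = r_hy1 - r_hy2,
                 statistics = z, p_values = p,
                 p = max(p)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("%s comparison: r1 = %.3f vs r2 = %.3f (diff %.3f), p = %.4g\n",
              x$design, x$r1, x$r2, x$difference, x$p))
  invisible(x)
}
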
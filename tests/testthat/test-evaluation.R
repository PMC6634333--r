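test_that("Pearson correlation with Fisher CI: worked examples and contract", {
  # hand computation: cov = 4/3, both variances 5/3 -> r = 0.8
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  rep <- pearson_with_ci(x, y)
  expect_equal(rep$r, 0.8)
  expect_equal(rep$n, 4L)
  ci <- tanh(atanh(0.8) + c(-1, 1) * 1.96)
  expect_equal(c(rep$ci_low, rep$ci_high), ci)

  # exactly linear input: r = 1 with a degenerate interval
  lin <- pearson_with_ci(x, 2 * x + 1)
  expect_equal(lin$r, 1)
  expect_equal(c(lin$ci_low, lin$ci_high), c(1, 1))

  expect_error(pearson_with_ci(c(1, 1, 1, 1), y), "constant")
  expect_error(pearson_with_ci(1:3, c(2, 1, 3)), "n >= 4")
})

test_that("pearson_with_ci is symmetric and affine invariant", {
  set.seed(1)
  x <- rnorm(30); y <- x + rnorm(30)
  a <- pearson_with_ci(x, y)
  b <- pearson_with_ci(y, x)
  expect_equal(a$r, b$r)
  d <- pearson_with_ci(3 * x + 2, 0.5 * y - 1)
  expect_equal(a$r, d$r)
  expect_equal(c(a$ci_low, a$ci_high), c(d$ci_low, d$ci_high))
  # cross-check the interval against cor.test (which uses qnorm(0.975))
  ct <- cor.test(x, y)
  e <- pearson_with_ci(x, y, multiplier = qnorm(0.975))
  expect_equal(c(e$ci_low, e$ci_high), as.numeric(ct$conf.int),
               tolerance = 1e-10)
})

test_that("Spearman-Brown correction", {
  expect_equal(spearman_brown(0.5), 2 / 3)
  expect_equal(spearman_brown(1), 1)
  expect_equal(spearman_brown(0), 0)
  expect_error(spearman_brown(-1), "undefined")
})

test_that("correction for attenuation: worked examples and monotonicity", {
  expect_equal(round_half_up(disattenuate(0.84, 0.97)), 0.85)
  expect_equal(round_half_up(disattenuate(0.59, 0.92)), 0.62)
  expect_equal(disattenuate(0.7, 1, 1), 0.7)  # identity at perfect reliability

  # monotone nondecreasing in r, nonincreasing in each reliability
  expect_true(disattenuate(0.6, 0.9) < disattenuate(0.7, 0.9))
  expect_true(disattenuate(0.6, 0.8) > disattenuate(0.6, 0.9))
  expect_true(disattenuate(0.6, 0.9, 0.8) > disattenuate(0.6, 0.9, 0.9))

  expect_warning(out <- disattenuate(0.95, 0.8), "clipped")
  expect_equal(out, 1)
  expect_error(disattenuate(0.5, 0), "positive")
  expect_error(disattenuate(0.5, 1.2), "exceed")
})

test_that("split-half reliability: exact, null, and closed-form recovery", {
  # identical raters: 1.0 exactly, any seed
  m <- matrix(rep(c(1, 3, 5, 2, 6, 4), 4), nrow = 4, byrow = TRUE)
  expect_equal(split_half_reliability(m, n_rand = 50, seed = 9)$reliability, 1)

  # two raters of pure independent noise: reliability near zero
  set.seed(2)
  noise <- matrix(rnorm(2 * 500), 2, 500)
  rel0 <- split_half_reliability(noise, n_rand = 1000, seed = 3)
  expect_lt(abs(rel0$reliability), 0.1)

  # parallel measurements: truth sd 1, error var 1.5, 12 raters
  set.seed(4)
  truth <- rnorm(500)
  P <- 12
  ratings <- matrix(rep(truth, each = P), P, 500) +
    matrix(rnorm(P * 500, sd = sqrt(1.5)), P, 500)
  rel <- split_half_reliability(ratings, n_rand = 1000, seed = 5)
  expected <- var(truth) / (var(truth) + 1.5 / P)
  expect_equal(rel$reliability, expected, tolerance = 0.03)

  # bit-reproducible under a fixed seed
  again <- split_half_reliability(ratings, n_rand = 100, seed = 5)
  again2 <- split_half_reliability(ratings, n_rand = 100, seed = 5)
  expect_identical(again$reliability, again2$reliability)

  expect_error(split_half_reliability(noise[, 1:3, drop = FALSE], 10, 1),
               "4 words")
  expect_error(split_half_reliability(noise[1, , drop = FALSE], 10, 1),
               "2 raters")
})

test_that("split-half drops words with an all-missing half, with a log note", {
  set.seed(6)
  m <- matrix(rnorm(4 * 20), 4, 20)
  m[1:3, 5] <- NA  # word 5 unrated in most halves containing rater 4's complement
  expect_message(rel <- split_half_reliability(m, n_rand = 50, seed = 7),
                 "missing")
  expect_true(is.finite(rel$reliability))
})

test_that("residual incremental R-squared: orthogonality and hand oracle", {
  set.seed(8)
  h <- rnorm(40); p1 <- h + rnorm(40)

  # the same predictor twice explains nothing beyond itself
  expect_lt(residual_incremental_r2(h, p1, p1)$r_squared, 1e-12)
  # an affine transform of the primary predictor adds nothing either
  expect_lt(residual_incremental_r2(h, p1, 2 * p1 + 3)$r_squared, 1e-12)

  # six-point dataset against explicit normal equations
  h6 <- c(2.0, 3.5, 1.0, 4.2, 5.1, 2.8)
  a6 <- c(1.8, 3.0, 1.5, 4.4, 4.6, 3.1)
  b6 <- c(2.5, 2.9, 1.2, 3.9, 5.5, 2.2)
  got <- residual_incremental_r2(h6, a6, b6)
  expect_equal(got$r_squared, oracle_incremental_r2(h6, a6, b6),
               tolerance = 1e-12)

  # additivity bound: R2(h ~ a) + incremental R2 of residuals <= 1
  r2a <- summary(lm(h6 ~ a6))$r.squared
  expect_lte(got$r_squared + r2a, 1 + 1e-9)

  expect_error(residual_incremental_r2(h6, rep(1, 6), b6), "constant")
  expect_error(residual_incremental_r2(h6, a6, b6[1:5]), "equal length")
})

test_that("Fisher z test for independent correlations", {
  eq <- compare_independent_correlations(0.5, 100, 0.5, 100)
  expect_equal(eq$statistics[["fisher1925"]], 0)
  expect_equal(eq$p, 1)

  # direct formula evaluation
  got <- compare_independent_correlations(0.5, 100, 0.3, 100)
  z <- (atanh(0.5) - atanh(0.3)) / sqrt(2 / 97)
  expect_equal(got$statistics[["fisher1925"]], z, tolerance = 1e-12)
  expect_equal(got$p, 2 * pnorm(-abs(z)), tolerance = 1e-12)
  expect_equal(round(z, 3), 1.670)
  expect_equal(round(got$p, 3), 0.095)

  # large-sample contrast is decisively significant
  big <- compare_independent_correlations(0.92, 946, 0.71, 951)
  expect_lt(big$p, 0.001)

  expect_error(compare_independent_correlations(1, 100, 0.5, 100), "undefined")
  expect_error(compare_independent_correlations(0.5, 3, 0.5, 100), "n >= 4")
})

test_that("dependent overlapping correlation tests match textbook formulas", {
  eq <- compare_dependent_correlations(0.6, 0.6, 0.4, 100)
  expect_equal(unname(eq$statistics), c(0, 0, 0))
  expect_equal(eq$p, 1)

  got <- compare_dependent_correlations(0.6, 0.4, 0.3, 50)
  oracle <- oracle_dependent_z(0.6, 0.4, 0.3, 50)
  expect_equal(got$statistics, oracle, tolerance = 1e-6)
  expect_equal(got$p_values, 2 * pnorm(-abs(oracle)), tolerance = 1e-6)
  expect_equal(got$p, max(got$p_values))
  expect_true(all(got$p >= got$p_values))
  expect_equal(got$difference, 0.2)

  # a large dependent contrast is significant for any admissible overlap
  for (r12 in c(0.5, 0.7, 0.9)) {
    cmp <- compare_dependent_correlations(0.91, 0.78, r12, 2831)
    expect_lt(cmp$p, 0.001)
  }

  expect_error(compare_dependent_correlations(0.9, 0.9, -0.9, 100),
               "positive semidefinite")
  expect_error(compare_dependent_correlations(0.5, 0.4, 0.3, 5), "n >= 10")
})
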
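# Independent brute-force oracles: deliberately naive (explicit loops and
# textbook formulas), kept free of the package's implementation paths.

oracle_ppmi <- function(m) {
  m <- as.matrix(m)
  N <- sum(m)
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (m[i, j] > 0) {
        pij <- m[i, j] / N
        pi_ <- sum(m[i, ]) / N
        p_j <- sum(m[, j]) / N
        out[i, j] <- max(0, log(pij / (pi_ * p_j)))
      }
    }
  }
  out
}

oracle_cosine <- function(w) {
  w <- as.matrix(w)
  n <- nrow(w)
  out <- matrix(0, n, n, dimnames = list(rownames(w), rownames(w)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ni <- sqrt(sum(w[i, ]^2))
      nj <- sqrt(sum(w[j, ]^2))
      if (ni > 0 && nj > 0) out[i, j] <- sum(w[i, ] * w[j, ]) / (ni * nj)
    }
  }
  out
}

# Exhaustive sort with the same declared tie rule: descending similarity,
# then token order.
oracle_top_k <- function(s, word, k, candidates = rownames(s)) {
  candidates <- setdiff(candidates, c(word, attr(s, "zero_norm")))
  df <- data.frame(word = candidates, sim = s[word, candidates])
  df <- df[order(-df$sim, df$word, method = "radix"), ]
  setNames(df$sim[seq_len(k)], df$word[seq_len(k)])
}

oracle_loo_knn <- function(s, norms, k) {
  sapply(names(norms), function(w) {
    nb <- oracle_top_k(s, w, k, candidates = setdiff(names(norms), w))
    mean(norms[names(nb)])
  })
}

oracle_holdout_knn <- function(s, train, test_words, k) {
  sapply(test_words, function(w) {
    nb <- oracle_top_k(s, w, k, candidates = names(train))
    mean(train[names(nb)])
  })
}

# OLS by explicit normal equations, then the residual regression's
# explained sum of squares as a share of the human ratings' total sum of
# squares.
oracle_incremental_r2 <- function(human, pred1, pred2) {
  b1 <- sum((pred1 - mean(pred1)) * (human - mean(human))) /
    sum((pred1 - mean(pred1))^2)
  a1 <- mean(human) - b1 * mean(pred1)
  res <- human - (a1 + b1 * pred1)
  b2 <- sum((pred2 - mean(pred2)) * (res - mean(res))) /
    sum((pred2 - mean(pred2))^2)
  a2 <- mean(res) - b2 * mean(pred2)
  fit <- a2 + b2 * pred2
  sum((fit - mean(res))^2) / sum((human - mean(human))^2)
}

# Published z statistics for two overlapping dependent correlations,
# transcribed directly from the original articles.
oracle_dependent_z <- function(r1, r2, r12, n) {
  z1 <- 0.5 * log((1 + r1) / (1 - r1))
  z2 <- 0.5 * log((1 + r2) / (1 - r2))
  cov_term <- function(r) {
    (r12 * (1 - 2 * r^2) - 0.5 * r^2 * (1 - 2 * r^2 - r12^2)) / (1 - r^2)^2
  }
  # Steiger (1980), eq. 14 with pooled r = arithmetic mean
  steiger <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cov_term((r1 + r2) / 2)))
  # Meng, Rosenthal & Rubin (1992), eqs. 1-3
  rb2 <- (r1^2 + r2^2) / 2
  f <- (1 - r12) / (2 * (1 - rb2))
  if (f > 1) f <- 1
  h <- (1 - f * rb2) / (1 - rb2)
  meng <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - r12) * h))
  # Hittner, May & Silver (2003): Dunn & Clark's z with the
  # backtransformed average Fisher z as the pooled correlation
  zm <- (z1 + z2) / 2
  rm <- (exp(2 * zm) - 1) / (exp(2 * zm) + 1)
  hittner <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cov_term(rm)))
  c(steiger1980 = steiger, meng1992 = meng, hittner2003 = hittner)
}

# Random small count matrix with word names, for oracle comparisons.
random_counts <- function(nr, nc, seed, density = 0.6, max_count = 9) {
  set.seed(seed)
  m <- matrix(rbinom(nr * nc, 1, density) * sample(max_count, nr * nc, TRUE),
              nr, nc)
  while (any(rowSums(m) == 0)) {
    i <- which(rowSums(m) == 0)[1]
    m[i, sample(nc, 1)] <- 1
  }
  rownames(m) <- sprintf("w%02d", seq_len(nr))
  colnames(m) <- sprintf("c%02d", seq_len(nc))
  m
}

# A small well-behaved similarity matrix over named words.
random_similarity <- function(n, seed) {
  m <- random_counts(n, n + 2, seed)
  suppressMessages(cosine_similarity(ppmi_transform(m)))
}
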
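#' Positive pointwise mutual information weighting
#'
#' Re-weights a word-by-context count matrix so that each cell holds
#' \eqn{\max(0, \log(p_{ij} / (p_{i\cdot} p_{\cdot j})))}, where
#' \eqn{p_{ij} = c_{ij}/N} and the marginals are row and column sums over
#' the grand total \eqn{N}.  Negative PMI values are clamped to zero
#' (positive PMI), which both downweights high-frequency edges and
#' preserves sparsity: a zero count always maps to a zero weight.
#'
#' The natural logarithm is used; the base is immaterial for any downstream
#' cosine similarity since a change of base rescales all weights by one
#' positive constant.  No smoothing (context-distribution exponent or
#' add-k) is applied.
#'
#' @param m Nonnegative count matrix (base matrix or [Matrix::Matrix]).
#' @return Weight matrix of the same class, dimensions and dimnames.
#' @export
#' @examples
#' ppmi_transform(matrix(c(4, 0, 0, 4), 2, 2))
ppmi_transform <- function(m) {
  N <- sum(m)
  if (N <= 0) stop("all-zero count matrix: PPMI undefined")
  rs <- Matrix::rowSums(m)
  cs <- Matrix::colSums(m)
  if (inherits(m, "sparseMatrix")) {
    m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
    ii <- m@i + 1L
    jj <- rep(seq_along(m@p[-1]), diff(m@p))
    w <- log(m@x * N / (rs[ii] * cs[jj]))
    m@x <- pmax(0, w)
    return(Matrix::drop0(m))
  }
  p_ratio <- (m * N) / outer(rs, cs)
  w <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  nz <- m > 0
  w[nz] <- pmax(0, log(p_ratio[nz]))
  w
}

#' Cosine similarity between the rows of a weighted matrix
#'
#' @param w Nonnegative weight matrix (e.g. from [ppmi_transform()]); rows
#'   are word vectors.
#' @return A dense square similarity matrix over the row words, values in
#'   \[0, 1\], symmetric, with unit diagonal for rows of nonzero norm.
#'   Rows whose vector has zero norm get similarity 0 everywhere
#'   (diagonal included) and are listed in the `"zero_norm"` attribute;
#'   such words are never eligible as nearest neighbors.
#' @export
cosine_similarity <- function(w) {
  norms <- sqrt(Matrix::rowSums(w^2))
  zero <- norms == 0
  inv <- ifelse(zero, 0, 1 / norms)
  x <- Matrix::Diagonal(x = inv) %*% w
  s <- as.matrix(Matrix::tcrossprod(x))
  dimnames(s) <- list(rownames(w), rownames(w))
  s[s > 1] <- 1
  s[s < 0] <- 0
  diag(s)[!zero] <- 1
  if (any(zero))
    log_info("cosine_similarity: %d zero-norm row(s) flagged", sum(zero))
  attr(s, "zero_norm") <- rownames(w)[zero]
  s
}

# Candidates eligible as neighbors of `word`: the given candidate set minus
# the word itself and minus zero-norm (flagged) words.
eligible_neighbors <- function(s, word, candidates) {
  candidates <- setdiff(candidates, word)
  flagged <- attr(s, "zero_norm")
  if (length(flagged)) candidates <- setdiff(candidates, flagged)
  candidates
}

#' Top-k nearest neighbors of a word
#'
#' Returns the `k` candidate words most similar to `word`, self excluded,
#' ties broken by descending similarity then lexicographic token order
#' (deterministic).  Zero-norm words are never returned as neighbors.
#'
#' @param s Similarity matrix from [cosine_similarity()].
#' @param word Target word (must be a row of `s`).
#' @param k Number of neighbors.
#' @param candidates Words the neighbors may be drawn from (default: all
#'   words in `s`).
#' @return Named numeric vector of length `k`: similarities, named by
#'   neighbor word, in neighbor order.
#' @export
top_k_neighbors <- function(s, word, k, candidates = rownames(s)) {
  if (!word %in% rownames(s)) stop("word not in similarity matrix: ", word)
  cands <- eligible_neighbors(s, word, candidates)
  if (k < 1 || k > length(cands))
    stop(sprintf("k = %d neighbors requested for '%s' but only %d candidates available",
                 k, word, length(cands)))
  sims <- s[word, cands]
  names(sims) <- cands
  ord <- order(-sims, cands, method = "radix")[seq_len(k)]
  sims[ord]
}

#' Write top-n neighbor lists to a TSV file (debug/inspection)
#'
#' @param s Similarity matrix.
#' @param path Output path.
#' @param n Neighbors per word.
#' @return Invisibly, the data frame written (word, neighbor, similarity).
#' @export
write_neighbor_lists <- function(s, path, n = 10) {
  words <- setdiff(rownames(s), attr(s, "zero_norm"))
  rows <- lapply(words, function(w) {
    nb <- top_k_neighbors(s, w, min(n, length(eligible_neighbors(s, w, rownames(s)))))
    data.frame(word = w, neighbor = names(nb), similarity = unname(nb))
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
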
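#' Default grid of neighborhood sizes
#'
#' Every integer from 1 to 50 together with 60, 70, 80, 90 and 100
#' (55 values), the grid used throughout the cross-validation sweeps.
#'
#' @return Integer vector of length 55.
#' @export
default_k_grid <- function() c(1:50, seq(60L, 100L, 10L))

# All of a target's eligible training candidates in neighbor order
# (descending similarity, lexicographic tie-break), as an ordered vector of
# training values named by neighbor.
ranked_train_values <- function(s, word, train) {
  cands <- eligible_neighbors(s, word, names(train))
  if (length(cands) == 0)
    stop("no eligible neighbors for '", word, "'")
  sims <- s[word, cands]
  ord <- order(-sims, cands, method = "radix")
  structure(unname(train[cands[ord]]), names = cands[ord], sims = sims[ord])
}

#' Predict one word's norm as the mean of its k nearest rated neighbors
#'
#' @param s Similarity matrix from [cosine_similarity()].
#' @param train Named numeric vector: training words -> norm values.  The
#'   target must not be in the training set.
#' @param target Word to predict (a row of `s`).
#' @param k Number of neighbors; must not exceed the number of eligible
#'   training candidates (no silent shrinking).
#' @param weighted If `TRUE`, use a similarity-weighted mean instead of the
#'   default unweighted mean of the k neighbors.
#' @return Predicted norm value (always within the range of the training
#'   values).
#' @export
knn_predict <- function(s, train, target, k, weighted = FALSE) {
  if (target %in% names(train)) stop("target '", target, "' is in the training set")
  if (!target %in% rownames(s)) stop("word not in similarity matrix: ", target)
  vals <- ranked_train_values(s, target, train)
  if (k < 1 || k > length(vals))
    stop(sprintf("k = %d neighbors requested for '%s' but only %d candidates available",
                 k, target, length(vals)))
  idx <- seq_len(k)
  if (weighted) {
    w <- attr(vals, "sims")[idx]
    if (sum(w) == 0) return(mean(vals[idx]))
    sum(w * vals[idx]) / sum(w)
  } else {
    mean(vals[idx])
  }
}

new_prediction_result <- function(property, source, k, mode,
                                  predictions, human, neighbors = NULL) {
  structure(list(property = property, source = source, k = k, mode = mode,
                 predictions = predictions, human = human,
                 neighbors = neighbors),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("k-NN predictions (%s): %d words, property '%s', source '%s', k = %d\n",
              x$mode, length(x$predictions), x$property %||% "?",
              x$source %||% "?", x$k))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Leave-one-out k-NN extrapolation
#'
#' Predicts each normed word from all other normed words: for every word
#' the training set is the remaining words, so a word's own rating never
#' influences its prediction.
#'
#' @param s Similarity matrix.
#' @param norms Named numeric vector of human norm values; all names must
#'   be rows of `s`.
#' @param k Neighborhood size, at most `length(norms) - 1`.
#' @param property,source Optional labels carried into the result.
#' @param weighted Similarity-weighted mean instead of unweighted.
#' @param keep_neighbors Store each word's neighbor list (default `FALSE`).
#' @return A `prediction_result` with per-word `predictions` and the
#'   `human` values they are compared against.
#' @export
loo_extrapolate <- function(s, norms, k, property = NULL, source = NULL,
                            weighted = FALSE, keep_neighbors = FALSE) {
  words <- names(norms)
  if (!all(words %in% rownames(s)))
    stop("norm words missing from similarity matrix: ",
         paste(utils::head(setdiff(words, rownames(s))), collapse = ", "))
  preds <- numeric(length(words))
  names(preds) <- words
  nbrs <- if (keep_neighbors) vector("list", length(words)) else NULL
  for (i in seq_along(words)) {
    w <- words[i]
    preds[i] <- knn_predict(s, norms[-i], w, k, weighted = weighted)
    if (keep_neighbors)
      nbrs[[i]] <- names(top_k_neighbors(s, w, k, candidates = words[-i]))
  }
  if (keep_neighbors) names(nbrs) <- words
  new_prediction_result(property, source, k, "loo", preds, norms, nbrs)
}

#' Train/test (holdout) k-NN extrapolation
#'
#' Each test word is predicted from the training set only; training and
#' test sets must be disjoint.
#'
#' @param s Similarity matrix.
#' @param train_norms Named numeric vector: training words -> norm values.
#' @param test_words Character vector of words to predict, or a named
#'   numeric vector of their human values (then carried into the result
#'   for evaluation).
#' @inheritParams loo_extrapolate
#' @return A `prediction_result` over the test words.
#' @export
holdout_extrapolate <- function(s, train_norms, test_words, k,
                                property = NULL, source = NULL,
                                weighted = FALSE) {
  human <- NULL
  if (is.numeric(test_words)) {
    human <- test_words
    test_words <- names(test_words)
  }
  overlap <- intersect(test_words, names(train_norms))
  if (length(overlap))
    stop("train and test sets overlap: ",
         paste(utils::head(overlap), collapse = ", "))
  preds <- vapply(test_words, function(w)
    knn_predict(s, train_norms, w, k, weighted = weighted), numeric(1))
  new_prediction_result(property, source, k, "holdout", preds, human)
}

#' Sweep the neighborhood size k and correlate predictions with ratings
#'
#' For each k in the grid, runs leave-one-out (`mode = "loo"`, over
#' `norms`) or train/test (`mode = "holdout"`, over `train` and `test`)
#' k-NN extrapolation and records the Pearson correlation between the
#' predicted and the human values.  The neighbor ordering of each target
#' is computed once and reused across the whole grid.
#'
#' @param s Similarity matrix.
#' @param norms Named numeric vector of human values (LOO mode).
#' @param train,test Named numeric vectors for holdout mode (disjoint).
#' @param mode `"loo"` or `"holdout"`.
#' @param grid Integer vector of k values (default [default_k_grid()]).
#' @param property,source Optional labels.
#' @param weighted Similarity-weighted neighbor mean.
#' @return Object of class `ksweep`: list with `grid`, `r` (per-k Pearson
#'   correlation, `NA` if undefined), `n`, `best_k`, `best_r` (ties on r
#'   resolved toward the smaller k), `predictions` (words x grid matrix)
#'   and `human`.
#' @export
sweep_k <- function(s, norms = NULL, train = NULL, test = NULL,
                    mode = c("loo", "holdout"), grid = default_k_grid(),
                    property = NULL, source = NULL, weighted = FALSE) {
  mode <- match.arg(mode)
  if (length(grid) == 0) stop("empty k grid")
  grid <- as.integer(grid)
  if (mode == "loo") {
    if (is.null(norms)) stop("LOO mode needs 'norms'")
    targets <- names(norms)
    human <- norms
    get_train <- function(i) norms[-i]
  } else {
    if (is.null(train) || is.null(test)) stop("holdout mode needs 'train' and 'test'")
    if (length(intersect(names(train), names(test))))
      stop("train and test sets overlap")
    targets <- names(test)
    human <- test
    get_train <- function(i) train
  }
  preds <- matrix(NA_real_, length(targets), length(grid),
                  dimnames = list(targets, grid))
  for (i in seq_along(targets)) {
    vals <- ranked_train_values(s, targets[i], get_train(i))
    if (max(grid) > length(vals))
      stop(sprintf("k = %d neighbors requested for '%s' but only %d candidates available",
                   max(grid), targets[i], length(vals)))
    if (weighted) {
      w <- attr(vals, "sims")
      cw <- cumsum(w)
      cwx <- cumsum(w * vals)
      est <- ifelse(cw > 0, cwx / cw, cumsum(vals) / seq_along(vals))
      preds[i, ] <- est[grid]
    } else {
      preds[i, ] <- (cumsum(vals) / seq_along(vals))[grid]
    }
  }
  r <- vapply(seq_along(grid), function(j) {
    p <- preds[, j]
    if (stats::sd(p) == 0 || stats::sd(human) == 0) NA_real_ else
      stats::cor(p, human)
  }, numeric(1))
  if (anyNA(r))
    log_info("sweep_k: correlation undefined (constant predictions) for k = %s",
             paste(grid[is.na(r)], collapse = ", "))
  best <- which.max(r)  # first maximum -> smallest k on ties
  structure(list(property = property, source = source, mode = mode,
                 grid = grid, r = r, n = length(targets),
                 best_k = grid[best], best_r = r[best],
                 predictions = preds, human = human),
            class = "ksweep")
}

#' @export
print.ksweep <- function(x, ...) {
  cat(sprintf("k sweep (%s): %d words, %d values of k; best r = %.3f at k = %d\n",
              x$mode, x$n, length(x$grid), x$best_r, x$best_k))
  invisible(x)
}

#' Write per-word predictions to CSV
#'
#' @param result A `prediction_result`.
#' @param path Output CSV path.
#' @return Invisibly, the data frame written.
#' @export
write_predictions <- function(result, path) {
  df <- data.frame(word = names(result$predictions),
                   property = result$property %||% NA,
                   source = result$source %||% NA,
                   k = result$k,
                   predicted = unname(result$predictions),
                   human_mean = if (is.null(result$human)) NA else
                     unname(result$human[names(result$predictions)]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
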
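#' Read continued free-association records
#'
#' Parses a delimited text file of continued free-association data, in which
#' each participant produced up to three responses to a cue word.  Two
#' layouts are supported: `"wide"` (default; columns participant, cue, R1,
#' R2, R3) and `"long"` (columns participant, cue, response; one row per
#' response, pooled per participant x cue).
#'
#' Tokens are normalized by case-folding and whitespace trimming; multi-word
#' responses are kept as single tokens after trimming.  Duplicate responses
#' within one participant x cue record are dropped (first occurrence kept).
#' Malformed rows (empty cue, or no responses at all) are skipped with a
#' warning that reports how many were dropped.
#'
#' @param path Path to the delimited file.
#' @param format `"wide"` or `"long"`.
#' @param sep Field separator (default tab).
#' @param normalize Case-fold and trim tokens (default `TRUE`).
#' @return A list of association records; each record is a list with
#'   elements `participant`, `cue` and `responses` (character vector of
#'   length 1--3, duplicate-free).
#' @seealso [build_cue_by_response_counts()]
#' @export
read_association_file <- function(path, format = c("wide", "long"),
                                  sep = "\t", normalize = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          colClasses = "character", na.strings = c("NA", ""),
                          check.names = FALSE, strip.white = TRUE)
  if (nrow(df) == 0) stop("empty association file: ", path)
  norm_tok <- function(x) {
    x <- trimws(x)
    if (normalize) x <- tolower(x)
    x
  }
  if (format == "long") {
    if (ncol(df) < 3) stop("long format needs columns participant, cue, response")
    key <- paste(df[[1]], norm_tok(df[[2]]), sep = "\r")
    resp <- split(df[[3]], factor(key, levels = unique(key)))
    parts <- split(df[[1]], factor(key, levels = unique(key)))
    cues <- split(norm_tok(df[[2]]), factor(key, levels = unique(key)))
    rows <- Map(function(p, c, r) list(participant = p[1], cue = c[1],
                                       responses = r),
                parts, cues, resp)
  } else {
    if (ncol(df) < 3) stop("wide format needs participant, cue and >=1 response column")
    resp_mat <- as.matrix(df[seq(3, min(5, ncol(df)))])
    parts <- df[[1]]
    cues <- norm_tok(df[[2]])
    rows <- lapply(seq_len(nrow(df)), function(i) {
      list(participant = parts[i], cue = cues[i],
           responses = unname(resp_mat[i, ]))
    })
  }
  n_bad <- 0L
  records <- vector("list", length(rows))
  n_ok <- 0L
  for (rec in rows) {
    cue <- rec$cue
    responses <- rec$responses[!is.na(rec$responses)]
    responses <- norm_tok(responses)
    responses <- responses[nzchar(responses)]
    responses <- responses[!duplicated(responses)]
    if (is.na(cue) || !nzchar(cue) || length(responses) == 0) {
      n_bad <- n_bad + 1L
      next
    }
    n_ok <- n_ok + 1L
    records[[n_ok]] <- list(participant = as.character(rec$participant),
                            cue = cue, responses = responses)
  }
  if (n_bad > 0)
    warning(n_bad, " malformed association row(s) skipped")
  records <- records[seq_len(n_ok)]
  if (length(records) == 0) stop("no valid association records in ", path)
  log_info("read %d association records from %s", length(records), path)
  records
}

#' Tally association records into a cue-by-response count matrix
#'
#' All response positions (first, second, third associate) are pooled with
#' equal weight by default; `position_weights` allows a weighted tally.
#'
#' @param records List of association records as returned by
#'   [read_association_file()].
#' @param position_weights Optional numeric weights for response positions
#'   1..3 (recycled/truncated to each record's length).  Default equal
#'   weight 1, giving integer counts.
#' @return A sparse [Matrix::dgCMatrix] of counts, rows = cues, columns =
#'   responses, both in lexicographic order.
#' @export
build_cue_by_response_counts <- function(records, position_weights = NULL) {
  if (length(records) == 0) stop("no association records")
  lens <- vapply(records, function(r) length(r$responses), integer(1))
  if (sum(lens) == 0) stop("no responses in any record")
  cues <- rep(vapply(records, `[[`, character(1), "cue"), lens)
  resp <- unlist(lapply(records, `[[`, "responses"), use.names = FALSE)
  w <- if (is.null(position_weights)) rep(1, length(resp)) else
    unlist(lapply(lens, function(n) position_weights[seq_len(n)]), use.names = FALSE)
  row_words <- sort(unique(cues), method = "radix")
  col_words <- sort(unique(resp), method = "radix")
  m <- Matrix::sparseMatrix(i = match(cues, row_words),
                            j = match(resp, col_words),
                            x = w,
                            dims = c(length(row_words), length(col_words)),
                            dimnames = list(row_words, col_words))
  methods::as(m, "CsparseMatrix")
}

#' Restrict a cue-by-response matrix to a square cue-by-cue matrix
#'
#' Keeps only response columns that also served as cue words, so the matrix
#' becomes square over a single word list.  Rows left with a zero total are
#' dropped (logged), and the restriction is iterated to a fixed point so the
#' operation is idempotent.  Cue words that never occur as responses are
#' retained as all-zero columns (the column word list always equals the row
#' word list).
#'
#' @param m Count matrix (rows = cues, columns = responses).
#' @return Square count matrix with identical row and column word lists.
#' @export
restrict_to_square <- function(m) {
  words <- rownames(m)
  repeat {
    keep_cols <- intersect(colnames(m), words)
    totals <- Matrix::rowSums(m[words, keep_cols, drop = FALSE])
    alive <- words[totals > 0]
    if (length(alive) == length(words)) break
    log_info("restrict_to_square: dropped %d cue(s) with no surviving responses",
             length(words) - length(alive))
    words <- alive
    if (length(words) == 0) stop("restriction to square matrix left no words")
  }
  out <- Matrix::Matrix(0, length(words), length(words),
                        dimnames = list(words, words), sparse = TRUE)
  present <- intersect(colnames(m), words)
  out[, present] <- m[words, present, drop = FALSE]
  methods::as(out, "CsparseMatrix")
}

#' Read word-context co-occurrence counts from a triple file
#'
#' The file is tab-separated with header columns word, context, count.
#' Duplicate (word, context) triples are aggregated by summation.
#'
#' @param path Path to the TSV file.
#' @return Sparse count matrix, rows = words, columns = contexts,
#'   lexicographic order.
#' @export
read_cooccurrence_counts <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "numeric"),
                          strip.white = TRUE)
  if (nrow(df) == 0) stop("empty co-occurrence file: ", path)
  if (any(df[[3]] < 0)) stop("negative co-occurrence count in ", path)
  row_words <- sort(unique(df[[1]]), method = "radix")
  col_words <- sort(unique(df[[2]]), method = "radix")
  m <- Matrix::sparseMatrix(i = match(df[[1]], row_words),
                            j = match(df[[2]], col_words),
                            x = df[[3]],
                            dims = c(length(row_words), length(col_words)),
                            dimnames = list(row_words, col_words))
  methods::as(m, "CsparseMatrix")  # sparseMatrix sums duplicate triples
}

#' Read a norm table
#'
#' CSV with header `word, <property>[, rater columns]`.  When per-rater
#' columns are present they are returned as a rater x word matrix and
#' validated against the stored means (tolerance 1e-9, ignoring missing
#' ratings).
#'
#' @param path Path to the CSV file.
#' @param normalize Case-fold and trim word tokens (default `TRUE`).
#' @return An object of class `norm_table`: list with `words`, `property`
#'   (column name of the mean), `means` (named numeric) and `rater_matrix`
#'   (raters x words, or `NULL`).
#' @export
read_norm_file <- function(path, normalize = TRUE) {
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  if (nrow(df) == 0) stop("empty norm file: ", path)
  words <- as.character(df[[1]])
  words <- trimws(words)
  if (normalize) words <- tolower(words)
  if (anyDuplicated(words)) stop("duplicate words in norm file: ", path)
  property <- names(df)[2]
  means <- as.numeric(df[[2]])
  names(means) <- words
  rater_matrix <- NULL
  if (ncol(df) > 2) {
    rater_matrix <- t(as.matrix(df[, -(1:2), drop = FALSE]))
    colnames(rater_matrix) <- words
    got <- colMeans(rater_matrix, na.rm = TRUE)
    if (any(abs(got - means) > 1e-9))
      stop("rater column means disagree with stored means in ", path)
  }
  ord <- order(words, method = "radix")
  structure(list(words = words[ord], property = property,
                 means = means[ord],
                 rater_matrix = if (is.null(rater_matrix)) NULL else
                   rater_matrix[, ord, drop = FALSE]),
            class = "norm_table")
}

#' Align multiple data sources on their shared vocabulary
#'
#' Intersects the vocabularies of two or more sources (count matrices,
#' similarity matrices, norm tables, named norm vectors or plain word
#' vectors) and returns each source restricted to the shared words, in a
#' stable lexicographic order.  The result does not depend on the order in
#' which the sources are given.
#'
#' @param ... Two or more sources.
#' @return List with `words` (sorted shared vocabulary) and `views` (each
#'   input restricted to `words`; count matrices are restricted in their
#'   rows, similarity matrices in both dimensions).
#' @export
align_vocabulary <- function(...) {
  sources <- list(...)
  if (length(sources) == 1 && is.list(sources[[1]]) &&
      !inherits(sources[[1]], "norm_table") && is.null(dim(sources[[1]])) &&
      !is.numeric(sources[[1]]))
    sources <- sources[[1]]
  if (length(sources) < 2) stop("need at least two sources to align")
  vocabs <- lapply(sources, vocabulary)
  shared <- Reduce(intersect, vocabs)
  if (length(shared) == 0) stop("empty shared vocabulary")
  shared <- sort(shared, method = "radix")
  log_info("aligned %d sources on %d shared words", length(sources), length(shared))
  views <- lapply(sources, function(x) {
    if (is.character(x)) return(shared)
    if (inherits(x, "norm_table")) {
      keep <- x$words %in% shared
      x$words <- x$words[keep]
      x$means <- x$means[keep]
      if (!is.null(x$rater_matrix))
        x$rater_matrix <- x$rater_matrix[, keep, drop = FALSE]
      return(x)
    }
    if (is.matrix(x) || inherits(x, "Matrix")) {
      square <- !is.null(colnames(x)) && identical(rownames(x), colnames(x))
      out <- if (square) x[shared, shared, drop = FALSE] else
        x[shared, , drop = FALSE]
      if (!is.null(attr(x, "zero_norm")))
        attr(out, "zero_norm") <- intersect(attr(x, "zero_norm"), shared)
      return(out)
    }
    x[shared]
  })
  list(words = shared, views = views)
}
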
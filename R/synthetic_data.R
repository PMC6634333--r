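#' Configuration for the synthetic lexicon generator
#'
#' The generator emulates the three data sources the pipeline consumes: a
#' continued free-association task (at least 100 participants giving three
#' responses per cue, hence >= 300 response tokens per cue), per-rater
#' Likert judgments of lexical norms, and a word-context co-occurrence
#' channel with an independently tunable -- by default weaker -- semantic
#' signal.  Words live in a latent Gaussian semantic space; each norm is a
#' noisy linear projection of that space onto a property direction,
#' affinely mapped onto its rating scale.
#'
#' @param vocab_size Number of words V (>= 10).
#' @param latent_dim Dimension D of the latent semantic space.
#' @param properties Named list of rating scales, e.g.
#'   `list(valence = c(1, 7), aoa = c(2, 16))`.  Property directions are
#'   drawn orthonormal (requires `latent_dim >= length(properties)`), so
#'   distinct properties are independent up to sampling noise.
#' @param prop_noise_sd Noise sd added to each latent projection before the
#'   affine map to the rating scale (latent units; latent projections have
#'   unit variance, so 0.25 leaves ~94% of true-norm variance explained by
#'   the semantic space, in the region of the published norm reliabilities).
#' @param participants Participants per cue P (default 100).
#' @param responses_per_participant Responses per participant x cue (3).
#' @param beta Association sharpness (>= 0): response probability is
#'   proportional to `exp(beta * cos(latent_cue, latent_response))`.
#' @param raters Number of raters R per property.
#' @param rater_sd Rater noise sd in rating units.
#' @param beta_text Co-occurrence sharpness; below `beta` by default so the
#'   text channel carries the weaker signal.
#' @param text_budget Total co-occurrence tokens; defaults to the
#'   association channel's token count `vocab_size * participants * 3`
#'   (matched budgets).
#' @param seed Master seed; all components draw from named substreams of it.
#' @return A validated `lexicon_config` list.
#' @export
lexicon_config <- function(vocab_size = 500,
                           latent_dim = 10,
                           properties = list(valence = c(1, 7),
                                             arousal = c(1, 7),
                                             dominance = c(1, 7),
                                             aoa = c(2, 16),
                                             concreteness = c(1, 7)),
                           prop_noise_sd = 0.25,
                           participants = 100,
                           responses_per_participant = 3,
                           beta = 6,
                           raters = 20,
                           rater_sd = 0.5,
                           beta_text = 3,
                           text_budget = vocab_size * participants *
                             responses_per_participant,
                           seed = 1) {
  if (vocab_size < 10) stop("vocab_size must be >= 10")
  if (latent_dim < length(properties))
    stop("latent_dim must be >= number of properties (orthonormal directions)")
  if (prop_noise_sd < 0 || rater_sd < 0) stop("noise sds must be >= 0")
  if (beta < 0 || beta_text < 0) stop("sharpness parameters must be >= 0")
  if (participants < 1 || raters < 2) stop("need >= 1 participant and >= 2 raters")
  if (text_budget < 1) stop("text_budget must be positive")
  structure(list(vocab_size = as.integer(vocab_size),
                 latent_dim = as.integer(latent_dim),
                 properties = properties,
                 prop_noise_sd = prop_noise_sd,
                 participants = as.integer(participants),
                 responses_per_participant = as.integer(responses_per_participant),
                 beta = beta, raters = as.integer(raters),
                 rater_sd = rater_sd, beta_text = beta_text,
                 text_budget = text_budget, seed = as.integer(seed)),
            class = "lexicon_config")
}

#' Generate a synthetic lexicon
#'
#' Draws i.i.d. standard-normal latent vectors for each word and builds the
#' true norm values: for each property, the latent vectors are projected
#' onto a property direction (orthonormal across properties), Gaussian
#' noise of sd `prop_noise_sd` is added, and the result is affinely mapped
#' onto the property's rating scale (realized minimum and maximum land on
#' the scale endpoints).  Deterministic given the config seed.
#'
#' @param cfg A [lexicon_config()].
#' @return Object of class `synthetic_lexicon`: list with `words`,
#'   `latents` (V x D matrix), `norms` (V x properties matrix of true
#'   values), `directions`, and the `config`.
#' @export
generate_lexicon <- function(cfg) {
  V <- cfg$vocab_size
  D <- cfg$latent_dim
  width <- nchar(as.character(V))
  words <- sprintf("w%0*d", width, seq_len(V))
  out <- with_substream(cfg$seed, "lexicon", {
    latents <- matrix(stats::rnorm(V * D), V, D,
                      dimnames = list(words, NULL))
    q <- qr.Q(qr(matrix(stats::rnorm(D * D), D, D)))
    directions <- q[, seq_along(cfg$properties), drop = FALSE]
    colnames(directions) <- names(cfg$properties)
    raw <- latents %*% directions +
      matrix(stats::rnorm(V * length(cfg$properties), sd = cfg$prop_noise_sd),
             V, length(cfg$properties))
    list(latents = latents, directions = directions, raw = raw)
  })
  norms <- out$raw
  for (j in seq_along(cfg$properties)) {
    sc <- cfg$properties[[j]]
    x <- out$raw[, j]
    norms[, j] <- sc[1] + (sc[2] - sc[1]) * (x - min(x)) / (max(x) - min(x))
  }
  dimnames(norms) <- list(words, names(cfg$properties))
  structure(list(words = words, latents = out$latents, norms = norms,
                 directions = out$directions, config = cfg),
            class = "synthetic_lexicon")
}

#' @export
print.synthetic_lexicon <- function(x, ...) {
  cat(sprintf("synthetic lexicon: %d words, %d latent dimensions, properties: %s\n",
              length(x$words), ncol(x$latents),
              paste(colnames(x$norms), collapse = ", ")))
  invisible(x)
}

# Latent cosine matrix (diagonal 1), used by both response channels.
latent_cosine <- function(lex) {
  n <- sqrt(rowSums(lex$latents^2))
  s <- tcrossprod(lex$latents / n)
  dimnames(s) <- list(lex$words, lex$words)
  s
}

# Draw the raw association responses: for each cue and participant, 3
# distinct responses sampled without replacement with probability
# proportional to exp(beta * cos), self excluded.  Returns an integer
# matrix with columns cue, participant, r1, r2, r3.
draw_association_indices <- function(lex, participants, beta, seed) {
  V <- length(lex$words)
  npr <- lex$config$responses_per_participant
  C <- latent_cosine(lex)
  with_substream(seed, "associations", {
    out <- matrix(0L, V * participants, 2L + npr)
    row <- 0L
    for (i in seq_len(V)) {
      others <- seq_len(V)[-i]
      p <- exp(beta * (C[i, others] - max(C[i, others])))
      for (j in seq_len(participants)) {
        row <- row + 1L
        out[row, ] <- c(i, j, others[sample.int(V - 1L, npr, prob = p)])
      }
    }
    out
  })
}

#' Sample continued free-association records from a synthetic lexicon
#'
#' Each of `participants` simulated participants produces three distinct
#' responses to every cue, drawn without replacement with probability
#' proportional to `exp(beta * cos(latent_cue, latent_response))`; a cue
#' never elicits itself.
#'
#' @param lex A [generate_lexicon()] result.
#' @param participants,beta,seed Override the corresponding config fields.
#' @return List of association records (same shape as
#'   [read_association_file()] output).
#' @export
sample_association_records <- function(lex,
                                       participants = lex$config$participants,
                                       beta = lex$config$beta,
                                       seed = lex$config$seed) {
  idx <- draw_association_indices(lex, participants, beta, seed)
  npr <- lex$config$responses_per_participant
  pw <- nchar(as.character(participants))
  lapply(seq_len(nrow(idx)), function(r)
    list(participant = sprintf("p%0*d", pw, idx[r, 2]),
         cue = lex$words[idx[r, 1]],
         responses = lex$words[idx[r, 2 + seq_len(npr)]]))
}

#' Sample an association cue-by-response count matrix
#'
#' Tallies the responses drawn by [sample_association_records()] (same
#' substream, so counts and records agree for a given seed) into a square
#' cue-by-cue count matrix.  Every cue row sums to
#' `participants * responses_per_participant` tokens.
#'
#' @inheritParams sample_association_records
#' @return Sparse V x V count matrix (cues x responses, zero diagonal).
#' @export
sample_association_responses <- function(lex,
                                         participants = lex$config$participants,
                                         beta = lex$config$beta,
                                         seed = lex$config$seed) {
  idx <- draw_association_indices(lex, participants, beta, seed)
  npr <- lex$config$responses_per_participant
  V <- length(lex$words)
  i <- rep(idx[, 1], npr)
  j <- as.vector(idx[, 2 + seq_len(npr)])
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(V, V),
                            dimnames = list(lex$words, lex$words))
  methods::as(m, "CsparseMatrix")
}

#' Sample per-rater Likert judgments of one property
#'
#' Each rater's judgment of a word is the word's true norm value plus
#' Gaussian noise of sd `rater_sd`, clipped to the property's scale
#' bounds.  The expectation of the rater matrix therefore equals the true
#' values (up to clipping at the scale edges).
#'
#' @param lex A [generate_lexicon()] result.
#' @param property Property name (a column of `lex$norms`).
#' @param raters,rater_sd,seed Override the corresponding config fields.
#' @return Raters x words numeric matrix.
#' @export
sample_rater_judgments <- function(lex, property,
                                   raters = lex$config$raters,
                                   rater_sd = lex$config$rater_sd,
                                   seed = lex$config$seed) {
  if (!property %in% colnames(lex$norms)) stop("unknown property: ", property)
  truth <- lex$norms[, property]
  sc <- lex$config$properties[[property]]
  m <- with_substream(seed, paste0("raters_", property), {
    matrix(rep(truth, each = raters) +
             stats::rnorm(raters * length(truth), sd = rater_sd),
           raters, length(truth))
  })
  m <- pmin(pmax(m, sc[1]), sc[2])
  dimnames(m) <- list(sprintf("r%02d", seq_len(raters)), lex$words)
  m
}

#' Sample a word-context co-occurrence count matrix
#'
#' Draws `text_budget` tokens from a multinomial over ordered word pairs
#' with weights proportional to `exp(beta_text * cos(latent_i, latent_j))`
#' (diagonal excluded, mirroring the association channel).  With
#' `beta_text` below `beta` this channel carries the same latent structure
#' through a weaker, noisier signal.
#'
#' @param lex A [generate_lexicon()] result.
#' @param budget,beta_text,seed Override the corresponding config fields.
#' @return Sparse V x V count matrix summing exactly to `budget`.
#' @export
sample_cooccurrence_counts <- function(lex,
                                       budget = lex$config$text_budget,
                                       beta_text = lex$config$beta_text,
                                       seed = lex$config$seed) {
  V <- length(lex$words)
  C <- latent_cosine(lex)
  w <- exp(beta_text * (C - max(C)))
  diag(w) <- 0
  counts <- with_substream(seed, "cooccurrence", {
    stats::rmultinom(1, budget, as.vector(w))
  })
  m <- matrix(counts, V, V, dimnames = list(lex$words, lex$words))
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

#' Write association records in the wide TSV dialect
#'
#' Emits exactly the file layout [read_association_file()] reads
#' (participant, cue, R1, R2, R3), so synthetic data can exercise the I/O
#' layer.
#'
#' @param records Association record list.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_association_file <- function(records, path) {
  pad <- function(r) c(r, rep("", 3 - length(r)))[1:3]
  df <- data.frame(participant = vapply(records, `[[`, character(1), "participant"),
                   cue = vapply(records, `[[`, character(1), "cue"),
                   t(vapply(records, function(r) pad(r$responses), character(3))))
  names(df)[3:5] <- c("R1", "R2", "R3")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a count matrix as word-context-count triples
#'
#' @param m Count matrix.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_cooccurrence_file <- function(m, path) {
  tm <- methods::as(methods::as(m, "generalMatrix"), "TsparseMatrix")
  df <- data.frame(word = rownames(m)[tm@i + 1L],
                   context = colnames(m)[tm@j + 1L],
                   count = tm@x)
  df <- df[order(df$word, df$context, method = "radix"), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a norm table in the CSV dialect read_norm_file reads
#'
#' When a rater matrix is given, the stored means are its column means so
#' the file satisfies the norm-table invariant.
#'
#' @param path Output CSV path.
#' @param property Property name (header of the mean column).
#' @param means Named numeric vector (ignored if `rater_matrix` given).
#' @param rater_matrix Optional raters x words matrix.
#' @return Invisibly, `path`.
#' @export
write_norm_file <- function(path, property, means = NULL, rater_matrix = NULL) {
  if (!is.null(rater_matrix)) {
    means <- colMeans(rater_matrix, na.rm = TRUE)
    df <- data.frame(word = colnames(rater_matrix), m = unname(means),
                     t(rater_matrix), check.names = FALSE)
  } else {
    df <- data.frame(word = names(means), m = unname(means))
  }
  names(df)[2] <- property
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
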
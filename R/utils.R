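#' Round half away from zero
#'
#' Presentation rounding used for reported correlations: exact halves round
#' away from zero (so 0.845 -> 0.85), unlike [base::round()]'s round-to-even.
#' Raw values are always retained alongside the rounded presentation value.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2, the convention for
#'   reported correlations).
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(0.845, -0.845, 0.8449))
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic sub-seed for a named random substream.  All randomness in the
# synthetic generator flows from one master seed; each component (lexicon,
# associations, raters, cooccurrence) draws from its own substream so it can
# be regenerated independently of the others.
substream_seed <- function(seed, name) {
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 131 + code) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(substream_seed(seed, name))
  expr
}

# INFO-level progress/checkpoint log; suppressible via suppressMessages().
log_info <- function(...) {
  message("[knnorms] ", sprintf(...))
}

#' Extract the word vocabulary of a pipeline object
#'
#' @param x A count matrix (rows are words), a similarity matrix, a norm
#'   table, or a plain character vector / named numeric vector of norms.
#' @return Character vector of words.
#' @export
vocabulary <- function(x) {
  if (is.character(x)) return(x)
  if (inherits(x, "norm_table")) return(x$words)
  if (is.matrix(x) || inherits(x, "Matrix")) return(rownames(x))
  if (is.numeric(x) && !is.null(names(x))) return(names(x))
  stop("cannot extract a vocabulary from an object of class ",
       paste(class(x), collapse = "/"))
}
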
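test_that("wide and long association files parse to equivalent records", {
  wide <- tempfile(fileext = ".tsv")
  writeLines(c("participant\tcue\tR1\tR2\tR3",
               "p1\tdog\tcat\tbone\ttail",
               "p2\tdog\tCat\t\t",
               "p1\tDog \tcat\tcat\tbone"),
             wide)
  recs <- suppressMessages(read_association_file(wide))
  expect_length(recs, 3)
  expect_equal(recs[[1]]$responses, c("cat", "bone", "tail"))
  expect_equal(recs[[2]]$responses, "cat")       # case-folded, blanks dropped
  expect_equal(recs[[3]]$cue, "dog")             # trimmed
  expect_equal(recs[[3]]$responses, c("cat", "bone"))  # within-record dedup

  long <- tempfile(fileext = ".tsv")
  writeLines(c("participant\tcue\tresponse",
               "p1\tdog\tcat", "p1\tdog\tbone", "p1\tdog\ttail",
               "p2\tdog\tcat"),
             long)
  recs_l <- read_association_file(long, format = "long")
  expect_length(recs_l, 2)
  expect_equal(recs_l[[1]]$responses, c("cat", "bone", "tail"))
})

test_that("malformed rows are skipped with a warning and empty files error", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("participant\tcue\tR1\tR2\tR3",
               "p1\tdog\tcat\t\t",
               "p2\t\tcat\tdog\t",   # empty cue
               "p3\tcat\t\t\t"),     # no responses
             path)
  expect_warning(recs <- read_association_file(path), "2 malformed")
  expect_length(recs, 1)

  empty <- tempfile(fileext = ".tsv")
  writeLines("participant\tcue\tR1\tR2\tR3", empty)
  expect_error(read_association_file(empty), "empty")
})

test_that("cue-by-response tallies conserve tokens and match a brute-force tally", {
  recs <- list(list(participant = "p1", cue = "dog", responses = c("cat", "bone")),
               list(participant = "p2", cue = "dog", responses = "cat"))
  m <- build_cue_by_response_counts(recs)
  expect_equal(m["dog", "cat"], 2)
  expect_equal(m["dog", "bone"], 1)

  expect_error(build_cue_by_response_counts(list()), "no association records")

  # random record sets: token conservation + independent tally
  set.seed(42)
  words <- letters[1:6]
  for (rep in 1:3) {
    recs <- lapply(1:40, function(i) {
      cue <- sample(words[1:3], 1)
      list(participant = paste0("p", i), cue = cue,
           responses = sample(setdiff(words, cue), sample(3, 1)))
    })
    m <- build_cue_by_response_counts(recs)
    n_tokens <- sum(vapply(recs, function(r) length(r$responses), integer(1)))
    expect_equal(sum(m), n_tokens)
    tally <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
    for (r in recs) for (resp in r$responses)
      tally[r$cue, resp] <- tally[r$cue, resp] + 1
    expect_equal(as.matrix(m), tally, ignore_attr = TRUE)
  }
})

test_that("position weights produce a weighted tally", {
  recs <- list(list(participant = "p1", cue = "dog",
                    responses = c("cat", "bone", "tail")))
  m <- build_cue_by_response_counts(recs, position_weights = c(1, 0.5, 0.25))
  expect_equal(m["dog", "cat"], 1)
  expect_equal(m["dog", "bone"], 0.5)
  expect_equal(m["dog", "tail"], 0.25)
})

test_that("restrict_to_square intersects columns, pads, drops dead rows, idempotent", {
  m <- Matrix::sparseMatrix(i = c(1, 1, 2), j = c(1, 3, 2), x = c(2, 1, 3),
                            dims = c(2, 3),
                            dimnames = list(c("a", "b"), c("a", "b", "c")))
  sq <- restrict_to_square(m)
  expect_equal(rownames(sq), colnames(sq))
  expect_equal(rownames(sq), c("a", "b"))
  expect_equal(sq["a", "a"], 2)
  expect_false("c" %in% colnames(sq))

  expect_equal(as.matrix(restrict_to_square(sq)), as.matrix(sq))

  # a cue that only elicits out-of-vocabulary responses is dropped
  m2 <- Matrix::sparseMatrix(i = c(1, 2, 3), j = c(2, 1, 3), x = c(1, 2, 5),
                             dims = c(3, 3),
                             dimnames = list(c("a", "b", "c"),
                                             c("a", "b", "z")))
  expect_message(sq2 <- restrict_to_square(m2), "dropped")
  expect_equal(rownames(sq2), c("a", "b"))
  # restriction iterates to a fixed point: never a zero-total row
  expect_true(all(Matrix::rowSums(sq2) > 0))
  # fully dead matrix errors
  dead <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, 1),
                               dimnames = list("a", "z"))
  expect_error(suppressMessages(restrict_to_square(dead)), "no words")

  # 5-cue toy set equals set-algebra oracle
  m3 <- random_counts(5, 7, seed = 7)
  colnames(m3) <- c(rownames(m3)[1:4], "x1", "x2", "x3")
  sq3 <- suppressMessages(restrict_to_square(Matrix::Matrix(m3, sparse = TRUE)))
  words <- rownames(m3)
  repeat {
    keep <- words[rowSums(m3[words, intersect(colnames(m3), words), drop = FALSE]) > 0]
    if (length(keep) == length(words)) break
    words <- keep
  }
  oracle <- matrix(0, length(words), length(words), dimnames = list(words, words))
  present <- intersect(colnames(m3), words)
  oracle[, present] <- m3[words, present]
  expect_equal(as.matrix(sq3), oracle, ignore_attr = TRUE)
})

test_that("co-occurrence triples aggregate by summation and reject negatives", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("word\tcontext\tcount",
               "dog\tbark\t3", "dog\tbark\t2", "cat\tpurr\t4"),
             path)
  m <- read_cooccurrence_counts(path)
  expect_equal(m["dog", "bark"], 5)
  expect_equal(m["cat", "purr"], 4)
  expect_equal(dim(m), c(2L, 2L))

  # 10-triple file equals a hand tally
  set.seed(11)
  df <- data.frame(word = sample(c("u", "v", "w"), 10, TRUE),
                   context = sample(c("x", "y"), 10, TRUE),
                   count = sample(5, 10, TRUE))
  p2 <- tempfile(fileext = ".tsv")
  utils::write.table(df, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  m2 <- read_cooccurrence_counts(p2)
  hand <- tapply(df$count, list(df$word, df$context), sum, default = 0)
  expect_equal(as.matrix(m2)[rownames(hand), colnames(hand)], hand,
               ignore_attr = TRUE)

  neg <- tempfile(fileext = ".tsv")
  writeLines(c("word\tcontext\tcount", "dog\tbark\t-1"), neg)
  expect_error(read_cooccurrence_counts(neg), "negative")
})

test_that("norm files round-trip, with and without rater columns", {
  raters <- matrix(c(1, 2, 3, 5, 5, 6, 2, 2, 2), nrow = 3,
                   dimnames = list(paste0("r", 1:3), c("dog", "sun", "tax")))
  path <- tempfile(fileext = ".csv")
  write_norm_file(path, "valence", rater_matrix = raters)
  nt <- read_norm_file(path)
  expect_s3_class(nt, "norm_table")
  expect_equal(nt$property, "valence")
  expect_equal(nt$words, c("dog", "sun", "tax"))
  expect_equal(nt$means, colMeans(raters)[nt$words])
  expect_equal(nt$rater_matrix[, nt$words], raters[, nt$words])

  bad <- tempfile(fileext = ".csv")
  writeLines(c("word,valence,r1,r2", "dog,9,1,2"), bad)
  expect_error(read_norm_file(bad), "disagree")
})

test_that("align_vocabulary intersects, restricts consistently, order-insensitive", {
  al <- align_vocabulary(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(al$words, c("b", "c"))
  expect_equal(align_vocabulary(c("a", "b"), c("a", "b"))$words, c("a", "b"))

  m <- random_counts(4, 3, seed = 3)
  norms <- setNames(c(1, 2, 3), c("w02", "w03", "w99"))
  al2 <- suppressMessages(align_vocabulary(m, norms, c("w01", "w02", "w03")))
  expect_equal(al2$words, c("w02", "w03"))
  expect_equal(rownames(al2$views[[1]]), al2$words)
  expect_equal(names(al2$views[[2]]), al2$words)

  # order-insensitive: same shared set for any input order
  al3 <- suppressMessages(align_vocabulary(norms, c("w01", "w02", "w03"), m))
  expect_equal(al3$words, al2$words)

  # three-source toy case equals brute-force triple intersection
  v1 <- c("a", "b", "c", "d"); v2 <- c("b", "d", "e"); v3 <- c("d", "b", "f")
  expect_equal(align_vocabulary(v1, v2, v3)$words,
               sort(intersect(intersect(v1, v2), v3)))

  expect_error(align_vocabulary(c("a"), c("b")), "empty shared vocabulary")

  # zero-norm flags on similarity matrices survive (restricted) alignment
  w <- rbind(w01 = c(1, 2), w02 = c(0, 0), w03 = c(2, 1), w04 = c(1, 1))
  s <- suppressMessages(cosine_similarity(w))
  al4 <- suppressMessages(align_vocabulary(s, c("w01", "w02", "w03")))
  expect_equal(attr(al4$views[[1]], "zero_norm"), "w02")
})
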
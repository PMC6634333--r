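#!/usr/bin/env Rscript

# Step 3: leave-one-out k-NN extrapolation over the k grid.
#
# For every property and both similarity channels, predicts each word's
# rating as the (unweighted) mean rating of its k nearest neighbors among
# the remaining words, for k in {1..50, 60, 70, 80, 90, 100}, and records
# the correlation between predictions and the rater-mean norms.  Writes
# the full correlation-by-k curves and prints the per-channel maxima.

library(knnorms)

data_dir <- file.path("results", "data")

assoc <- restrict_to_square(build_cue_by_response_counts(
  read_association_file(file.path(data_dir, "associations.tsv"))))
cooc <- read_cooccurrence_counts(file.path(data_dir, "cooccurrence.tsv"))
sims <- list(associations = cosine_similarity(ppmi_transform(assoc)),
             cooccurrence = cosine_similarity(ppmi_transform(cooc)))

norm_files <- Sys.glob(file.path(data_dir, "norms_*.csv"))
tables <- lapply(norm_files, read_norm_file)
names(tables) <- vapply(tables, `[[`, character(1), "property")

curves <- list()
for (prop in names(tables)) {
  al <- align_vocabulary(sims$associations, sims$cooccurrence,
                         tables[[prop]]$means)
  for (src in names(sims)) {
    sw <- sweep_k(al$views[[match(src, names(sims))]],
                  norms = al$views[[3]], mode = "loo",
                  property = prop, source = src)
    cat(sprintf("%-13s %-13s best r = %.3f at k = %d (n = %d)\n",
                prop, src, sw$best_r, sw$best_k, sw$n))
    curves[[length(curves) + 1]] <-
      data.frame(property = prop, source = src, k = sw$grid, r = sw$r)
  }
}

path <- file.path("results", "sweep_curves.csv")
write.csv(do.call(rbind, curves), path, row.names = FALSE)
cat("correlation-by-k curves ->", path, "\n")
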
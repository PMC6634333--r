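#!/usr/bin/env Rscript

# Step 2: build the PPMI-cosine similarity spaces.
#
# Reads the files step 1 wrote (through the same readers real data would
# use), restricts the association matrix to responses that also served as
# cues, applies the PPMI weighting and the cosine measure, and writes each
# word's top-10 neighbor list per channel for inspection.

library(knnorms)

data_dir <- file.path("results", "data")
out <- "results"

assoc <- restrict_to_square(build_cue_by_response_counts(
  read_association_file(file.path(data_dir, "associations.tsv"))))
cat(sprintf("association matrix: %d x %d, %d tokens\n",
            nrow(assoc), ncol(assoc), sum(assoc)))

cooc <- read_cooccurrence_counts(file.path(data_dir, "cooccurrence.tsv"))
cat(sprintf("co-occurrence matrix: %d x %d, %d tokens\n",
            nrow(cooc), ncol(cooc), sum(cooc)))

for (channel in list(list("associations", assoc),
                     list("cooccurrence", cooc))) {
  s <- cosine_similarity(ppmi_transform(channel[[2]]))
  nz <- length(attr(s, "zero_norm"))
  cat(sprintf("%s: cosine over PPMI rows, %d zero-norm words flagged\n",
              channel[[1]], nz))
  path <- file.path(out, paste0("neighbors_", channel[[1]], ".tsv"))
  write_neighbor_lists(s, path, n = 10)
  cat(sprintf("top-10 neighbor lists -> %s\n", path))
}
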
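#!/usr/bin/env Rscript

# Step 1: generate the synthetic study data.
#
# Builds a lexicon of 500 words in a 10-dimensional latent semantic space
# with five norm properties (valence, arousal, dominance, age of
# acquisition, concreteness), then samples the three data sources the
# pipeline consumes and writes them in the exact file dialects the readers
# expect:
#   - a continued free-association file (100 participants x 3 responses
#     per cue, wide TSV),
#   - a word-context co-occurrence triple file at the matched token budget
#     but with the weaker semantic signal (sharpness 3 vs 6),
#   - one norm CSV per property with 20 per-rater columns.

library(knnorms)

seed <- 1
out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- lexicon_config(seed = seed)
lex <- generate_lexicon(cfg)
cat(sprintf("lexicon: %d words, %d latent dimensions, %d properties\n",
            length(lex$words), cfg$latent_dim, ncol(lex$norms)))

records <- sample_association_records(lex)
write_association_file(records, file.path(out, "associations.tsv"))
cat(sprintf("associations: %d records (%d tokens) -> %s\n",
            length(records), 3 * length(records),
            file.path(out, "associations.tsv")))

cooc <- sample_cooccurrence_counts(lex)
write_cooccurrence_file(cooc, file.path(out, "cooccurrence.tsv"))
cat(sprintf("co-occurrence: %d tokens over %d nonzero pairs -> %s\n",
            sum(cooc), Matrix::nnzero(cooc),
            file.path(out, "cooccurrence.tsv")))

for (prop in colnames(lex$norms)) {
  raters <- sample_rater_judgments(lex, prop)
  write_norm_file(file.path(out, paste0("norms_", prop, ".csv")), prop,
                  rater_matrix = raters)
}
cat(sprintf("norms: %d properties x %d raters -> %s\n",
            ncol(lex$norms), cfg$raters, file.path(out, "norms_<property>.csv")))

# keep the true (noise-free-rater) norm values for later comparison
write.csv(data.frame(word = lex$words, lex$norms),
          file.path(out, "true_norms.csv"), row.names = FALSE)
cat("true latent norm values -> results/data/true_norms.csv\n")
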
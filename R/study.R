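#' Read a study configuration file
#'
#' YAML configuration for [run_study()].  Unspecified fields take the
#' standard defaults: the 55-value k grid, 10,000 reliability
#' randomizations, the 1.96 confidence-interval multiplier.
#'
#' @param path Path to a YAML file.
#' @return A validated `study_config` list.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(study_config, raw)
}

#' Build a study configuration
#'
#' @param design One of `"loo"` (leave-one-out over the shared
#'   vocabulary), `"loo-subset"` (leave-one-out within a random subset of
#'   the shared vocabulary) or `"train-test"` (holdout: test words
#'   predicted from a disjoint training set).
#' @param synthetic `NULL`, or a list of [lexicon_config()] arguments; when
#'   present the study runs on generated data and no paths are needed.
#' @param association_file,cooccurrence_file Input paths (ignored when
#'   `synthetic` is given).  `cooccurrence_file` may be `NULL` (single
#'   source; no between-source comparison).
#' @param norm_files Named list property -> norm CSV path (ignored when
#'   `synthetic` is given).
#' @param properties Properties to run (default: all available).
#' @param k_grid Integer grid of neighborhood sizes.
#' @param n_rand Split-half reliability randomizations.
#' @param ci_multiplier Fisher CI half-width multiplier.
#' @param subset_size Size of the LOO subset (design `"loo-subset"`).
#' @param test_fraction Fraction of shared words held out as the test set
#'   (design `"train-test"`).
#' @param seed Master seed.
#' @param output_dir Where to write the report (`NULL`: no files written).
#' @return A `study_config` list.
#' @export
study_config <- function(design = c("loo", "loo-subset", "train-test"),
                         synthetic = NULL,
                         association_file = NULL, cooccurrence_file = NULL,
                         norm_files = NULL, properties = NULL,
                         k_grid = default_k_grid(), n_rand = 10000,
                         ci_multiplier = 1.96,
                         subset_size = 500, test_fraction = 0.25,
                         seed = 1, output_dir = NULL) {
  design <- match.arg(design)
  if (length(k_grid) == 0) stop("k grid must be nonempty")
  if (is.null(synthetic) && is.null(association_file))
    stop("need either a synthetic generator config or an association file")
  structure(list(design = design, synthetic = synthetic,
                 association_file = association_file,
                 cooccurrence_file = cooccurrence_file,
                 norm_files = norm_files, properties = properties,
                 k_grid = as.integer(unlist(k_grid)), n_rand = n_rand,
                 ci_multiplier = ci_multiplier,
                 subset_size = subset_size, test_fraction = test_fraction,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "study_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE))
}

# Load or generate all study inputs.  Returns list(counts = named list of
# count matrices per source, norms = named list property -> named numeric,
# raters = named list property -> rater matrix or NULL, truth = optional
# true-value matrix for synthetic runs).
assemble_inputs <- function(cfg) {
  if (!is.null(cfg$synthetic)) {
    gen_args <- cfg$synthetic
    gen_args$seed <- gen_args$seed %||% cfg$seed
    gcfg <- do.call(lexicon_config, gen_args)
    lex <- generate_lexicon(gcfg)
    props <- cfg$properties %||% colnames(lex$norms)
    counts <- list(associations = sample_association_responses(lex),
                   cooccurrence = sample_cooccurrence_counts(lex))
    raters <- lapply(props, function(p) sample_rater_judgments(lex, p))
    names(raters) <- props
    norms <- lapply(raters, function(m) colMeans(m, na.rm = TRUE))
    return(list(counts = counts, norms = norms, raters = raters,
                truth = lex$norms[, props, drop = FALSE]))
  }
  assoc <- restrict_to_square(build_cue_by_response_counts(
    read_association_file(cfg$association_file)))
  counts <- list(associations = assoc)
  if (!is.null(cfg$cooccurrence_file))
    counts$cooccurrence <- read_cooccurrence_counts(cfg$cooccurrence_file)
  if (is.null(cfg$norm_files)) stop("no norm files configured")
  tables <- lapply(cfg$norm_files, read_norm_file)
  props <- cfg$properties %||%
    vapply(tables, `[[`, character(1), "property")
  names(tables) <- vapply(tables, `[[`, character(1), "property")
  tables <- tables[props]
  norms <- lapply(tables, `[[`, "means")
  raters <- lapply(tables, `[[`, "rater_matrix")
  list(counts = counts, norms = norms, raters = raters, truth = NULL)
}

#' Run a full extrapolation study
#'
#' Orchestrates the whole pipeline for one configuration: assemble the
#' inputs (read files or generate a synthetic lexicon), build the
#' PPMI-cosine similarity matrix for each source, intersect all
#' vocabularies, then for every property and source sweep the k grid under
#' the configured cross-validation design and assemble the evaluation
#' battery: best-k correlation with Fisher CI, split-half reliability and
#' the disattenuated correlation (when rater data exist), residual
#' incremental R-squared in both directions and the conservative
#' dependent-correlation comparison (when two sources are present).
#' Vocabulary sizes are logged at every restriction checkpoint, and the
#' whole report is reproducible from the configuration and seed.
#'
#' @param cfg A `study_config` (or path to a YAML file).
#' @return Object of class `study_report`.
#' @export
run_study <- function(cfg) {
  if (is.character(cfg)) cfg <- read_study_config(cfg)
  inputs <- with_stage("assemble_inputs", assemble_inputs(cfg))
  sims <- with_stage("similarity", lapply(inputs$counts, function(m)
    cosine_similarity(ppmi_transform(m))))
  shared <- with_stage("align_vocabulary", {
    al <- do.call(align_vocabulary, c(unname(sims), unname(inputs$norms)))
    al$words
  })
  log_info("run_study: %d shared words across %d sources and %d norm sets",
           length(shared), length(sims), length(inputs$norms))
  sims <- lapply(sims, function(s) {
    out <- s[shared, shared]
    attr(out, "zero_norm") <- intersect(attr(s, "zero_norm"), shared)
    out
  })
  norms <- lapply(inputs$norms, function(v) v[shared])

  split <- with_stage("design", with_substream(cfg$seed, "design", {
    switch(cfg$design,
      "loo" = list(eval_words = shared),
      "loo-subset" = {
        size <- min(cfg$subset_size, length(shared))
        list(eval_words = sort(sample(shared, size), method = "radix"))
      },
      "train-test" = {
        n_test <- max(1, round(cfg$test_fraction * length(shared)))
        test <- sort(sample(shared, n_test), method = "radix")
        list(eval_words = test, train_words = setdiff(shared, test))
      })
  }))
  log_info("run_study: design '%s', %d evaluation words", cfg$design,
           length(split$eval_words))

  properties <- names(norms)
  report <- list(design = cfg$design, seed = cfg$seed,
                 n_shared = length(shared),
                 n_eval = length(split$eval_words),
                 k_grid = cfg$k_grid, properties = list())
  for (prop in properties) {
    entry <- list(sources = list())
    for (src in names(sims)) {
      sw <- with_stage(paste0("sweep_k[", prop, ",", src, "]"), {
        if (cfg$design == "train-test") {
          sweep_k(sims[[src]],
                  train = norms[[prop]][split$train_words],
                  test = norms[[prop]][split$eval_words],
                  mode = "holdout", grid = cfg$k_grid,
                  property = prop, source = src)
        } else {
          sweep_k(sims[[src]], norms = norms[[prop]][split$eval_words],
                  mode = "loo", grid = cfg$k_grid,
                  property = prop, source = src)
        }
      })
      best_pred <- sw$predictions[, as.character(sw$best_k)]
      corr <- pearson_with_ci(best_pred, sw$human, cfg$ci_multiplier)
      entry$sources[[src]] <- list(sweep = sw, correlation = corr,
                                   best_pred = best_pred)
    }
    if (!is.null(inputs$raters[[prop]])) {
      rel <- with_stage(paste0("reliability[", prop, "]"),
        split_half_reliability(
          inputs$raters[[prop]][, split$eval_words, drop = FALSE],
          n_rand = cfg$n_rand,
          seed = substream_seed(cfg$seed, paste0("rel_", prop))))
      entry$reliability <- rel
      entry$disattenuated <- lapply(entry$sources, function(e)
        disattenuate(e$correlation$r, min(1, rel$reliability)))
    }
    if (!is.null(inputs$truth)) {
      entry$truth_r <- vapply(entry$sources, function(e)
        stats::cor(e$best_pred, inputs$truth[split$eval_words, prop]),
        numeric(1))
    }
    if (length(entry$sources) == 2) {
      a <- entry$sources[[1]]; b <- entry$sources[[2]]
      h <- a$sweep$human
      entry$incremental_r2 <- list()
      entry$incremental_r2[[paste0(names(entry$sources)[2], "_beyond_",
                                   names(entry$sources)[1])]] <-
        residual_incremental_r2(h, a$best_pred, b$best_pred)
      entry$incremental_r2[[paste0(names(entry$sources)[1], "_beyond_",
                                   names(entry$sources)[2])]] <-
        residual_incremental_r2(h, b$best_pred, a$best_pred)
      entry$comparison <- compare_dependent_correlations(
        a$correlation$r, b$correlation$r,
        stats::cor(a$best_pred, b$best_pred), length(h))
    }
    report$properties[[prop]] <- entry
  }
  report <- structure(report, class = "study_report")
  if (!is.null(cfg$output_dir))
    with_stage("write_report", write_study_report(report, cfg$output_dir))
  report
}

#' Summarize a study report as a best-k correlation table
#'
#' One row per property x source: sample size, best correlation with its
#' confidence interval (two-decimal presentation values), the best k, and
#' the disattenuated correlation when reliability was available.
#'
#' @param report A `study_report`.
#' @return A data frame.
#' @export
report_table <- function(report) {
  rows <- list()
  for (prop in names(report$properties)) {
    entry <- report$properties[[prop]]
    for (src in names(entry$sources)) {
      e <- entry$sources[[src]]
      rows[[length(rows) + 1]] <- data.frame(
        property = prop, source = src, n = e$correlation$n,
        r = round_half_up(e$correlation$r),
        ci_low = round_half_up(e$correlation$ci_low),
        ci_high = round_half_up(e$correlation$ci_high),
        k = e$sweep$best_k,
        reliability = if (is.null(entry$reliability)) NA else
          round_half_up(entry$reliability$reliability),
        r_disattenuated = if (is.null(entry$disattenuated)) NA else
          round_half_up(entry$disattenuated[[src]]))
    }
  }
  do.call(rbind, rows)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study report: design '%s', %d shared words, %d evaluated\n",
              x$design, x$n_shared, x$n_eval))
  print(report_table(x))
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits `report.json` (machine-readable: per-k correlation curves, best-k
#' summaries, reliability, disattenuated correlations, incremental
#' R-squared, comparison tests), `summary.csv` (the [report_table()]
#' layout) and per-property-and-source `predictions_*.csv` files.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the JSON path.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report_table(report), file.path(dir, "summary.csv"),
                   row.names = FALSE)
  json <- list(design = report$design, seed = report$seed,
               n_shared = report$n_shared, n_eval = report$n_eval,
               k_grid = report$k_grid, properties = list())
  for (prop in names(report$properties)) {
    entry <- report$properties[[prop]]
    jp <- list(sources = list())
    for (src in names(entry$sources)) {
      e <- entry$sources[[src]]
      jp$sources[[src]] <- list(
        best_k = e$sweep$best_k, best_r = e$sweep$best_r,
        r_by_k = as.list(stats::setNames(e$sweep$r,
                                         as.character(e$sweep$grid))),
        ci = c(e$correlation$ci_low, e$correlation$ci_high),
        n = e$correlation$n)
      pred_df <- data.frame(word = names(e$best_pred),
                            property = prop, source = src,
                            k = e$sweep$best_k,
                            predicted = unname(e$best_pred),
                            human_mean = unname(e$sweep$human))
      utils::write.csv(pred_df,
                       file.path(dir, sprintf("predictions_%s_%s.csv", prop, src)),
                       row.names = FALSE)
    }
    if (!is.null(entry$reliability)) {
      jp$reliability <- entry$reliability$reliability
      jp$disattenuated <- lapply(entry$disattenuated, identity)
    }
    if (!is.null(entry$incremental_r2))
      jp$incremental_r2 <- lapply(entry$incremental_r2, function(x)
        list(r_squared = x$r_squared, p_value = x$p_value))
    if (!is.null(entry$comparison))
      jp$comparison <- list(difference = entry$comparison$difference,
                            p_conservative = entry$comparison$p,
                            p_values = as.list(entry$comparison$p_values))
    if (!is.null(entry$truth_r)) jp$truth_r <- as.list(entry$truth_r)
    json$properties[[prop]] <- jp
  }
  path <- file.path(dir, "report.json")
  jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
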
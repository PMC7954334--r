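stop_config <- function(msg) {
  stop(structure(class = c("traitminer_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Default run configuration
#'
#' The single structured configuration consumed by [cmd_simulate()] and
#' [cmd_pipeline()] (and by the command-line wrapper in
#' `inst/cli/traitminer.R`). Any field can be overridden by a YAML config
#' file or by the CLI flags; every run writes its resolved configuration
#' next to its outputs.
#'
#' @param seed Global integer seed.
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    generator = list(n_genera = 400L, species_per_genus = c(3L, 7L),
                     p_positive_trait1 = 0.34,
                     p_positive_trait2_given_trait1 = 0.43,
                     p_negation_sentence = 0.20,
                     p_silent_negative = 0.80,
                     vocab_size = 300L,
                     sentences_per_description = c(4L, 10L)),
    traits = c("fermentation", "acetate_production"),
    prep = list(mode = "winnowed"),
    model = list(kind = "cnn"),
    train = list(sizes = c(100L, 250L, 500L, 1000L), replicates = 5L,
                 batch_size = 32L, threshold = 0.5),
    tree = list(clade_signal = 0.9, n_draws = 100L)
  ), class = "run_config")
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a run configuration from YAML
#'
#' Unknown top-level fields are a configuration error; omitted fields take
#' their defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param seed Seed overriding both default and file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path = NULL, seed = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_config(paste0("config file not found: ", path))
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop_config(paste0("unknown config fields: ",
                         paste(unknown, collapse = ", ")))
    cfg <- .merge_config(cfg, user)
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  class(cfg) <- "run_config"
  cfg
}

.write_resolved <- function(cfg, out_dir) {
  ver <- as.character(utils::packageVersion("traitminer"))
  yaml::write_yaml(c(unclass(cfg), list(traitminer_version = ver)),
                   file.path(out_dir, "config.resolved.yaml"))
}

.trait_by_name <- function(name) {
  switch(name,
         fermentation = trait_fermentation(),
         acetate_production = trait_acetate(),
         stop_config(paste0("unknown trait: ", name)))
}

#' Simulate a corpus, labels and tree to disk
#'
#' Writes one article file per genus, `labels.tsv`, `manifest.json`,
#' `tree.nwk` and the resolved configuration under `out_dir`.
#'
#' @param cfg A `run_config` (see [load_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
cmd_simulate <- function(cfg = default_run_config(), out_dir) {
  gen <- tryCatch(
    do.call(generator_config, c(cfg$generator, list(seed = cfg$seed))),
    error = function(e) stop_config(conditionMessage(e)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  corp <- generate_corpus(gen, dir = out_dir)
  nwk <- generate_tree(corp$manifest, clade_signal = cfg$tree$clade_signal,
                       seed = cfg$seed + 1L)
  writeLines(nwk, file.path(out_dir, "tree.nwk"))
  .write_resolved(cfg, out_dir)
  message(sprintf("simulated %d articles, %d species; tree with %d leaves",
                  length(corp$articles), nrow(corp$manifest),
                  nrow(corp$manifest)))
  invisible(out_dir)
}

#' Run the full prediction pipeline on a corpus directory
#'
#' Parses articles, resolves labels through the keyword-candidate rule,
#' winnows descriptions, trains replicate classifiers over the configured
#' training-set sizes, writes metrics, and compares predicted and observed
#' trait trees by UniFrac against a random-subset null. All outputs, logs
#' and the resolved configuration land in `out_dir`.
#'
#' @param cfg A `run_config`.
#' @param data_dir Directory holding article `.txt` files, `labels.tsv` and
#'   `tree.nwk` (as written by [cmd_simulate()]).
#' @param out_dir Output directory.
#' @param traits Traits to run (default: those in `cfg$traits`).
#' @return Invisibly, a named list per trait with elements `run`
#'   (`learning_run`), `labels`, and `tree` (replicate tree comparison),
#'   plus `corpus`.
#' @export
cmd_pipeline <- function(cfg = default_run_config(), data_dir, out_dir,
                         traits = NULL) {
  traits <- traits %||% cfg$traits
  if (!dir.exists(data_dir)) stop_config("data_dir does not exist")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  corpus <- load_corpus(data_dir)
  message(sprintf("parsed %d species descriptions", nrow(corpus)))
  curated_all <- read_labels(file.path(data_dir, "labels.tsv"))
  tree_file <- file.path(data_dir, "tree.nwk")
  tree <- if (file.exists(tree_file)) read_newick(tree_file) else NULL

  prep <- text_prep_config(mode = cfg$prep$mode)
  spec <- do.call(model_spec, cfg$model)
  sizes <- as.integer(cfg$train$sizes)
  tconf <- train_config(batch_size = cfg$train$batch_size,
                        replicates = cfg$train$replicates,
                        threshold = cfg$train$threshold,
                        seed = cfg$seed)

  results <- list(corpus = corpus)
  all_metrics <- list()
  for (trait_name in traits) {
    trait <- .trait_by_name(trait_name)
    cand <- flag_candidates(corpus, trait)
    message(sprintf("[%s] %d candidates of %d species",
                    trait_name, length(cand), nrow(corpus)))
    curated <- curated_all[curated_all$trait == trait_name, , drop = FALSE]
    labels <- resolve_labels(corpus, cand, curated, trait)
    y <- as.integer(labels$label == "positive")
    texts <- vapply(corpus$text, winnow, character(1), trait = trait,
                    config = prep, USE.NAMES = FALSE)
    run <- run_replicates(texts, y, sizes, spec = spec, config = tconf,
                          prep = prep, trait_name = trait_name)
    all_metrics[[trait_name]] <- run$metrics

    tree_cmp <- NULL
    if (!is.null(tree)) {
      n_top <- max(sizes)
      reps <- Filter(function(r) r$n_train == n_top, run$runs)
      pred_d <- null_d <- numeric(0)
      full_null <- NULL
      for (r in seq_along(reps)) {
        rr <- reps[[r]]
        pred_pos <- leaf_name(corpus$species_name[rr$eval][rr$label == 1L])
        obs_pos <- leaf_name(labels$species_name[y == 1L])
        excl <- leaf_name(corpus$species_name[rr$train])
        cmp <- trait_tree_comparison(
          tree, pred_pos, obs_pos, exclude = excl,
          n_draws = if (r == 1L) cfg$tree$n_draws else 1L,
          seed = cfg$seed + r)
        pred_d <- c(pred_d, cmp$unifrac_distance)
        null_d <- c(null_d, cmp$null[1])
        if (r == 1L) full_null <- cmp
      }
      tt <- if (length(pred_d) >= 2L) compare_replicates(pred_d, null_d)
            else NULL
      tree_cmp <- list(replicate_predicted = pred_d,
                       replicate_null = null_d, t_test = tt,
                       first_replicate = full_null)
      jsonlite::write_json(
        list(trait = trait_name,
             unifrac_predicted = pred_d, unifrac_null = null_d,
             null_mean = full_null$null_mean, null_sd = full_null$null_sd,
             null_q05 = full_null$null_q05,
             t_statistic = if (is.null(tt)) NULL else tt$statistic,
             p_value = if (is.null(tt)) NULL else tt$p_value),
        file.path(out_dir, paste0("tree_", trait_name, ".json")),
        auto_unbox = TRUE, digits = NA, null = "null")
    }
    results[[trait_name]] <- list(run = run, labels = labels,
                                  tree = tree_cmp)
  }

  metrics <- do.call(rbind, all_metrics)
  utils::write.table(metrics, file.path(out_dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summarize_curve(metrics),
                     file.path(out_dir, "metrics_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .write_resolved(cfg, out_dir)
  invisible(results)
}
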
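# Hand-built article fixtures and independent oracles used across tests.

strcat_n <- function(s, n) paste(rep(s, n), collapse = "")

`%||%` <- function(a, b) if (is.null(a)) b else a

fixture_article <- function(genus = "Clostridium",
                            species = c("acetobutylicum", "exampleum"),
                            blocks = NULL,
                            fdi = "Genus-level sentinel text.",
                            abstract = "Short abstract.",
                            references = "1. A reference.",
                            strains = NULL) {
  if (is.null(blocks))
    blocks <- paste0("Species sentinel ", seq_along(species), ".")
  hdr <- paste(genus, species)
  if (!is.null(strains))
    hdr <- ifelse(is.na(strains), hdr,
                  sprintf("%s (strain %s)", hdr, strains))
  sp <- paste0("### ", hdr, "\n", blocks, collapse = "\n")
  paste0("# ", genus, "\n",
         "## Abstract\n", abstract, "\n",
         "## Further Descriptive Information\n", fdi, "\n",
         "## List of Species of the Genus\n", sp, "\n",
         "## References\n", references, "\n")
}

# Brute-force metric recomputation straight from raw 0/1 vectors, written
# independently of the evaluation module (different formulas where
# algebraically equivalent).
oracle_metrics <- function(pred, obs) {
  tp <- sum(pred == 1 & obs == 1); fp <- sum(pred == 1 & obs == 0)
  fn <- sum(pred == 0 & obs == 1)
  list(
    accuracy = mean(pred == obs),
    f1 = if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn),
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  )
}

# Brute-force unweighted UniFrac: enumerate every branch's descendant leaf
# set by explicit recursive walks (no postorder accumulation).
oracle_unifrac <- function(tree, set_a, set_b) {
  n_tip <- length(tree$tip.label)
  desc <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    leaves <- desc(tree$edge[e, 2])
    a <- any(leaves %in% set_a); b <- any(leaves %in% set_b)
    if (a || b) den <- den + tree$edge.length[e]
    if (xor(a, b)) num <- num + tree$edge.length[e]
  }
  if (den == 0) 0 else num / den
}

random_labeled_tree <- function(n) {
  t <- ape::rtree(n, rooted = TRUE)
  t$tip.label <- paste0("s", seq_len(n))
  t
}

# A small parsed synthetic corpus shared by several tests.
small_corpus <- function(n_genera = 30L, seed = 11L) {
  cfg <- generator_config(n_genera = n_genera, seed = seed)
  d <- file.path(tempdir(), sprintf("tm_corpus_%d_%d", n_genera, seed))
  if (!dir.exists(d)) generate_corpus(cfg, dir = d)
  g <- generate_corpus(cfg)
  corpus <- load_corpus(d)
  list(gen = g, corpus = corpus,
       manifest = g$manifest[match(corpus$species_name,
                                   g$manifest$species_name), ])
}
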
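# Phrase banks for the synthetic corpus. Fixed so that tests are stable.
# Affirmative fermentation sentences never mention acetate/acetic: acetate
# production must be signalled by its own sentences, keeping the two traits
# distinguishable and properly nested.
.AFFIRM_FERMENT <- c(
  "Ferments glucose with production of gas.",
  "Actively ferments a wide range of carbohydrates.",
  "Fermentative metabolism is observed under anaerobic conditions.",
  "Glucose and maltose are fermented to lactate and succinate.",
  "A vigorous fermenter of plant polysaccharides.",
  "Cellobiose and xylose are fermented to ethanol."
)

.AFFIRM_ACETATE <- c(
  "Ferments glucose to acetate and hydrogen.",
  "The main products of fermentation are acetate and formate.",
  "Acetic acid is the major end product of carbohydrate fermentation.",
  "Fermentation of cellobiose yields acetate and carbon dioxide."
)

# Negation traps: contain a fermentation keyword but describe its absence.
.NEGATE_FERMENT <- c(
  "Non-fermentative.",
  "Does not ferment carbohydrates.",
  "Fermentation does not occur.",
  "Strictly respiratory and never fermentative.",
  "Sugars are not fermented."
)

# Acetate negation traps for fermentative species that do not make acetate.
.NEGATE_ACETATE <- c(
  "Acetate is not produced.",
  "No acetic acid is formed during growth on sugars.",
  "End products of metabolism do not include acetate."
)

.NEUTRAL_FILLER <- c(
  "Cells are rod-shaped and occur singly or in pairs.",
  "Colonies are circular, smooth, and cream-colored.",
  "Optimal growth occurs at 37 C and pH 7.",
  "Motile by means of peritrichous flagella.",
  "Catalase-positive and oxidase-negative.",
  "Isolated from soil and freshwater sediments.",
  "The cell wall contains meso-diaminopimelic acid.",
  "Spores are not observed.",
  "Growth occurs in the presence of 2 percent sodium chloride.",
  "The major respiratory quinone is menaquinone."
)

.SYLLABLES <- c("ba", "co", "du", "fi", "ga", "lo", "mi", "nu", "pa", "re",
                "si", "tu", "ve", "xo", "za", "ke", "bo", "la", "ri", "mo")

# deterministic pseudo-word bank (no RNG; enumeration order is fixed)
.filler_vocab <- function(n) {
  two <- as.vector(outer(.SYLLABLES, .SYLLABLES, paste0))
  three <- as.vector(outer(two, .SYLLABLES, paste0))
  w <- unique(c(two, three))
  w <- w[!grepl("ferment|acetate|acetic", w)]
  if (n > length(w)) stop("vocab_size too large", call. = FALSE)
  w[seq_len(n)]
}

.latin_names <- function(n, suffix) {
  w <- .filler_vocab(min(2500L, 8000L))
  stems <- w[nchar(w) >= 4]
  out <- paste0(stems, suffix)
  if (n > length(out)) out <- paste0(rep(out, length.out = n),
                                     rep(seq_len(ceiling(n / length(out))),
                                         each = length(out))[seq_len(n)])
  out[seq_len(n)]
}

#' Configuration of the synthetic corpus generator
#'
#' Defaults emulate the statistical structure of a curated compendium
#' corpus: about 2,000 species across 400 genera, roughly a third of
#' species fermentative, and of those roughly 43% also producing acetate
#' (so the acetate trait is nested within fermentation at about the ratio
#' observed in curated trait tables). Twenty percent of non-fermentative
#' species carry a negation trap — a fermentation keyword inside a negating
#' sentence such as "Non-fermentative." — so keyword hits outnumber true
#' positives, and the remaining negatives never mention the trait at all.
#'
#' @param n_genera Number of genus articles.
#' @param species_per_genus Length-2 integer vector `(min, max)`; each
#'   genus draws its species count uniformly from this range.
#' @param p_positive_trait1 Probability a species is fermentative.
#' @param p_positive_trait2_given_trait1 Probability a fermentative species
#'   also produces acetate.
#' @param p_negation_sentence Probability a trait-negative species carries
#'   a negation-trap sentence (applies to both traits).
#' @param p_silent_negative Probability a trait-1-negative species has no
#'   fermentation keyword at all; together with `p_negation_sentence` it
#'   must not exceed 1 (any remainder is silent as well).
#' @param vocab_size Size of the pseudo-word filler vocabulary.
#' @param sentences_per_description Length-2 integer vector `(min, max)`:
#'   sentences per species block, planted sentences included.
#' @param p_subspecies Probability a species entry is a trinomial
#'   (subspecies) entry.
#' @param p_strain_id Probability a species header carries a strain ID.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_genera = 400L, species_per_genus = c(3L, 7L),
                             p_positive_trait1 = 0.34,
                             p_positive_trait2_given_trait1 = 0.43,
                             p_negation_sentence = 0.20,
                             p_silent_negative = 0.80,
                             vocab_size = 300L,
                             sentences_per_description = c(4L, 10L),
                             p_subspecies = 0.05, p_strain_id = 0.8,
                             seed = 1L) {
  probs <- c(p_positive_trait1, p_positive_trait2_given_trait1,
             p_negation_sentence, p_silent_negative, p_subspecies,
             p_strain_id)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (p_negation_sentence + p_silent_negative > 1 + 1e-12)
    stop("p_negation_sentence + p_silent_negative must not exceed 1",
         call. = FALSE)
  stopifnot(n_genera >= 1, length(species_per_genus) == 2L,
            species_per_genus[1] >= 1,
            species_per_genus[2] >= species_per_genus[1],
            vocab_size >= 20,
            length(sentences_per_description) == 2L,
            sentences_per_description[1] >= 1)
  structure(list(n_genera = as.integer(n_genera),
                 species_per_genus = as.integer(species_per_genus),
                 p_positive_trait1 = p_positive_trait1,
                 p_positive_trait2_given_trait1 =
                   p_positive_trait2_given_trait1,
                 p_negation_sentence = p_negation_sentence,
                 p_silent_negative = p_silent_negative,
                 vocab_size = as.integer(vocab_size),
                 sentences_per_description =
                   as.integer(sentences_per_description),
                 p_subspecies = p_subspecies, p_strain_id = p_strain_id,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# sample(5:5, 1) would draw from 1:5; guard degenerate ranges
.sample_range <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1)

.filler_sentence <- function(vocab) {
  n <- sample(4:8, 1)
  w <- sample(vocab, n, replace = TRUE)
  w[1] <- paste0(toupper(substr(w[1], 1, 1)), substr(w[1], 2, nchar(w[1])))
  paste0(paste(w, collapse = " "), ".")
}

.some_filler <- function(k, vocab) {
  vapply(seq_len(k), function(i) {
    if (stats::runif(1) < 0.4) sample(.NEUTRAL_FILLER, 1)
    else .filler_sentence(vocab)
  }, character(1))
}

#' Generate a synthetic article corpus with known ground truth
#'
#' Emits genus-level article texts in the [article_schema()] markup, a truth
#' manifest, and a long-format label table. Fermentative species always
#' contain at least one affirmative fermentation sentence; acetate
#' producers additionally contain an acetate sentence; negation-trap
#' negatives contain a fermentation keyword inside a negating sentence; the
#' remaining negatives carry no keyword at all. Everything else is filler
#' drawn from fixed phrase banks and a deterministic pseudo-word
#' vocabulary, so winnowing strips it. Generation is byte-identical across
#' runs with the same config.
#'
#' @param config A [generator_config()].
#' @param dir Optional directory; if given, one `.txt` file per article,
#'   `labels.tsv` and `manifest.json` are written there.
#' @return A list of class `synthetic_corpus`: `articles` (named character
#'   vector, one article text per genus), `manifest` (tibble:
#'   `species_name`, `genus`, `strain_id`, `trait1_label`, `trait2_label`,
#'   `negation_trap_t1`, `negation_trap_t2`, `planted`), and `labels`
#'   (long label tibble with `source = "synthetic_truth"`).
#' @export
generate_corpus <- function(config = generator_config(), dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)

  vocab <- .filler_vocab(config$vocab_size)
  genera <- .latin_names(config$n_genera, "bacterium")
  genera <- paste0(toupper(substr(genera, 1, 1)),
                   substr(genera, 2, nchar(genera)))
  epithet_bank <- .latin_names(5000L, "a")

  articles <- character(0)
  man <- list()
  ep_used <- 0L
  for (g in seq_along(genera)) {
    genus <- genera[g]
    n_sp <- .sample_range(config$species_per_genus[1],
                          config$species_per_genus[2])
    eps <- epithet_bank[ep_used + seq_len(n_sp)]
    ep_used <- ep_used + n_sp
    sp_names <- paste(genus, eps)
    tri <- stats::runif(n_sp) < config$p_subspecies
    sp_names[tri] <- paste(sp_names[tri], "subsp.",
                           sample(epithet_bank, sum(tri)))
    strain <- ifelse(stats::runif(n_sp) < config$p_strain_id,
                     sprintf("%s%s-%d",
                             sample(LETTERS, n_sp, replace = TRUE),
                             sample(LETTERS, n_sp, replace = TRUE),
                             sample(100:9999, n_sp, replace = TRUE)),
                     NA_character_)

    abstract <- paste(.some_filler(2, vocab), collapse = " ")
    genus_text <- paste(.some_filler(3, vocab), collapse = " ")

    blocks <- character(n_sp)
    for (s in seq_len(n_sp)) {
      t1 <- stats::runif(1) < config$p_positive_trait1
      t2 <- t1 && stats::runif(1) < config$p_positive_trait2_given_trait1
      planted <- character(0)
      trap1 <- FALSE; trap2 <- FALSE
      if (t1) {
        planted <- c(planted, sample(.AFFIRM_FERMENT, sample(1:2, 1)))
        if (t2) {
          planted <- c(planted, sample(.AFFIRM_ACETATE, 1))
        } else if (stats::runif(1) < config$p_negation_sentence) {
          planted <- c(planted, sample(.NEGATE_ACETATE, 1))
          trap2 <- TRUE
        }
      } else {
        u <- stats::runif(1)
        if (u < config$p_negation_sentence) {
          planted <- c(planted, sample(.NEGATE_FERMENT, 1))
          trap1 <- TRUE
        }  # otherwise silent: no fermentation keyword anywhere
      }
      n_total <- .sample_range(config$sentences_per_description[1],
                               config$sentences_per_description[2])
      n_fill <- max(n_total - length(planted), 1L)
      sents <- sample(c(.some_filler(n_fill, vocab), planted))
      hdr <- if (is.na(strain[s])) sp_names[s]
             else sprintf("%s (strain %s)", sp_names[s], strain[s])
      blocks[s] <- paste0("### ", hdr, "\n", paste(sents, collapse = " "))
      man[[length(man) + 1L]] <- tibble::tibble(
        species_name = sp_names[s], genus = genus, strain_id = strain[s],
        trait1_label = if (t1) "positive" else "negative",
        trait2_label = if (t2) "positive" else "negative",
        negation_trap_t1 = trap1, negation_trap_t2 = trap2,
        planted = paste(planted, collapse = " | "))
    }

    articles[[genus]] <- paste0(
      "# ", genus, "\n",
      "## Abstract\n", abstract, "\n",
      "## Further Descriptive Information\n", genus_text, "\n",
      "## List of Species of the Genus\n", paste(blocks, collapse = "\n"),
      "\n## References\n1. Example reference for ", genus, ".\n")
  }

  manifest <- do.call(rbind, man)
  labels <- rbind(
    tibble::tibble(species_name = manifest$species_name,
                   trait = "fermentation", label = manifest$trait1_label,
                   source = "synthetic_truth",
                   justification = ifelse(
                     manifest$trait1_label == "positive",
                     "planted affirmative fermentation sentence",
                     ifelse(manifest$negation_trap_t1,
                            "negation trap: keyword in negating sentence",
                            "no fermentation keyword in description"))),
    tibble::tibble(species_name = manifest$species_name,
                   trait = "acetate_production",
                   label = manifest$trait2_label,
                   source = "synthetic_truth",
                   justification = ifelse(
                     manifest$trait2_label == "positive",
                     "planted acetate production sentence",
                     ifelse(manifest$negation_trap_t2,
                            "negation trap: acetate negated",
                            "no acetate evidence"))))

  out <- structure(list(articles = articles, manifest = manifest,
                        labels = labels, config = config),
                   class = "synthetic_corpus")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (genus in names(articles))
      writeLines(articles[[genus]], file.path(dir, paste0(genus, ".txt")))
    write_labels(labels, file.path(dir, "labels.tsv"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         dataframe = "rows", na = "null")
  }
  out
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  tal <- label_tally(x$labels)
  cat(sprintf(paste0("<synthetic_corpus> %d genera, %d species ",
                     "(%d fermentative, %d acetate producers)\n"),
              length(x$articles), nrow(x$manifest),
              tal$per_trait[["fermentation"]],
              tal$per_trait[["acetate_production"]]))
  invisible(x)
}

# random rooted binary topology over the given leaf names
.rand_subtree <- function(leaves) {
  if (length(leaves) == 1L) return(leaves)
  t <- ape::rtree(length(leaves), rooted = TRUE, br = NULL)
  t$tip.label <- sample(leaves)
  sub(";$", "", ape::write.tree(t))
}

#' Generate a random phylogeny whose trait distribution is clumped
#'
#' Builds a rooted binary tree over all manifest species with exponential
#' branch lengths (rate 1). With probability `clade_signal` a species joins
#' the clade of its fermentation label (one clade of fermenters, one of
#' non-fermenters); otherwise it joins a uniformly random clade. At
#' `clade_signal = 1` the trait maps perfectly onto two clades; at 0 the
#' trait is distributed independently of the tree, giving a chance-level
#' trait–clade association.
#'
#' @param manifest Manifest tibble from [generate_corpus()].
#' @param clade_signal Probability in \[0,1\] that a species follows its
#'   trait clade.
#' @param seed Integer seed.
#' @return A newick string with one leaf per manifest species, with the
#'   clade assignment attached as attribute `"clades"` (named character
#'   vector, `"P"`/`"N"`).
#' @export
generate_tree <- function(manifest, clade_signal = 0.9, seed = 1L) {
  stopifnot(nrow(manifest) > 1L, clade_signal >= 0, clade_signal <= 1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  # species names contain spaces; newick convention replaces them with _
  leaf <- leaf_name(manifest$species_name)
  pos <- manifest$trait1_label == "positive"
  follow <- stats::runif(nrow(manifest)) < clade_signal
  clade <- ifelse(follow, ifelse(pos, "P", "N"),
                  sample(c("P", "N"), nrow(manifest), replace = TRUE))
  names(clade) <- leaf
  in_p <- leaf[clade == "P"]
  in_n <- leaf[clade == "N"]

  nw <- if (length(in_p) == 0L) .rand_subtree(in_n)
        else if (length(in_n) == 0L) .rand_subtree(in_p)
        else paste0("(", .rand_subtree(in_p), ",", .rand_subtree(in_n), ")")
  tree <- ape::read.tree(text = paste0(nw, ";"))
  tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 1)
  out <- ape::write.tree(tree)
  attr(out, "clades") <- clade
  out
}
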
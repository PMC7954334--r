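---
title: "Mining metabolic traits from written species descriptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining metabolic traits from written species descriptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Taxonomic reference works describe the metabolism of microbial species in
prose: "Ferments glucose to acetate and hydrogen", "Non-fermentative",
"Acetate is not produced". That information is valuable — fermentative
metabolism and acetate production matter to microbiome science, nutrient
cycling and synthetic biology — but it is locked in text. traitminer
implements a pipeline that turns such prose into binary trait calls:

1. **Corpus assembly.** Genus-level articles are parsed into per-species
   descriptions: the genus-level descriptive section plus the species' own
   entry in the article's species list, never a sibling species' entry.
2. **Keyword candidacy and labeling.** A trait is defined by keyword
   containment ("ferment" for fermentation; "ferment" plus "acetate" or
   "acetic" for acetate production). Matching is substring-in-word, so
   "fermenter" and "non-fermentative" both hit. Descriptions with no hit are
   negative by default; descriptions with a hit are *candidates* whose label
   comes from a curated table (a reader's verdict). This is the workflow of
   trait-database curation: only keyword hits get read.
3. **Winnowing and tokenization.** Keyword-bearing sentences are kept,
   duplicates dropped, the rest discarded; if no sentence matches every
   required keyword, nothing is kept. The joined text is truncated at
   25,000 characters and tokenized against a frequency-ranked vocabulary
   capped at 3,000 words (200,000 characters and 5,000 words in full-text
   mode). Out-of-vocabulary words are dropped; index 0 is reserved for
   padding.
4. **Classification.** A small convolutional network (embedding → 1-D
   convolution → global average pooling → dense → sigmoid) or LSTM
   (embedding → LSTM → sigmoid) is trained with binary cross-entropy and
   Adam, batch size 32, for 10 epochs (40 when the training set has at
   most 250 species). The network's job is precisely what keyword search
   cannot do: tell an affirmed trait from a negated one.
5. **Evaluation.** Accuracy $(TP+TN)/(TP+TN+FP+FN)$, F1
   $TP/[TP+\tfrac12(FP+FN)]$, precision $TP/(TP+FP)$ and sensitivity
   $TP/(TP+FN)$ on held-out species, as learning curves (mean ± SEM over
   five replicate trainings) across training-set sizes; and phylogenetically,
   as the unweighted UniFrac distance between predicted and observed
   trait-positive leaf sets on a reference tree, against a null of random
   leaf subsets of the same size.

## The synthetic corpus

Real compendium text is copyrighted, so the package carries a generator
that emits articles, labels and a phylogeny with the statistical structure
the pipeline assumes. Its defaults are the package's study conditions and
are deliberately fixed:

* ~2,000 species in 400 genera (3–7 species each), matching the scale at
  which learning curves over `n_train` up to 1,000 leave a meaningful
  evaluation set;
* 34% of species fermentative and 43% of those acetate producers,
  mirroring the roughly one-third / one-tenth prevalence of these traits
  in curated trait tables, with acetate production nested inside
  fermentation by construction;
* 20% of trait-negative species carry a *negation trap* (a planted
  sentence such as "Non-fermentative." or "Acetate is not produced."), the
  rest are silent. Keyword hits therefore outnumber true positives, which
  is exactly why a curator must read candidate descriptions — and why a
  classifier is needed at all;
* filler text is drawn from a fixed bank of neutral microbiological
  phrases and a deterministic pseudo-word vocabulary (300 words by
  default), none of which contain trait keywords.

What the generator does *not* emulate: real grammatical variety,
hedged or conditional trait statements ("ferments glucose only under…"),
OCR noise, and correlated vocabulary between trait and filler sentences.
Passing tests on this corpus show the machinery is correct and that the
network separates affirmation from negation when the signal is clean; they
do not certify accuracy on real compendium text, where phrasing is far
more varied.

The companion tree generator assigns each species to a fermenter or
non-fermenter clade with probability `clade_signal` (uniformly otherwise),
builds a random rooted binary topology per clade, and draws exponential
(rate 1) branch lengths. At `clade_signal = 1` the trait maps perfectly
onto two clades; at 0 the trait–tree association is at chance. Any
positive-branch-length tree exercises the UniFrac machinery; no inference
is implied.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `truncate_chars` | 25,000 (winnowed), 200,000 (full text) | character budget after sentence selection |
| `num_words` | 3,000 (winnowed), 5,000 (full text) | vocabulary bound; words ranked ≥ bound are dropped |
| `batch_size` / epochs | 32 / 10 (40 if `n_train` ≤ 250) | small sets need more passes to minimize the loss |
| embedding / filters / kernel / hidden / LSTM units | 16 / 16 / 5 / 16 / 32 | smallest widths that saturate the synthetic task; all overridable |
| dropout | 0.2 | on embedding and hidden dense layers (CNN) and on LSTM inputs |
| decision threshold | 0.5 | on the sigmoid output |
| replicates | 5 | SEM = sd/√5; SEM is undefined below 2 |
| null draws | 100 | random-subset UniFrac null |

Open choices the package fixes, with rationale:

* **Vocabulary fitting** defaults to training texts only (`fit_on =
  "train"`), so evaluation vocabulary never leaks into the tokenizer; a
  corpus-wide option exists for comparability.
* **Winnowing scope**: a sentence matching *any* trait keyword is kept,
  gated on every required keyword having at least one matching sentence
  somewhere; a strict per-sentence mode (`strict_sentence`) is available.
  Anywhere-in-description matching is also how candidacy is decided.
* **Replicates** resample both the train/eval split and the weights
  (`resample_split = FALSE` fixes the split), since independent trainings
  with a frozen split understate between-run variance.
* **Empty winnowed text** never reaches the network: such species carry no
  trait evidence and are predicted negative directly. A consequence worth
  knowing: label-flipping symmetry holds only for species whose text
  reaches the network.
* **Species with the same name in two articles**: the later article wins,
  with a warning.
* **Random-tree null**: "random trees with the same number of branches" is
  operationalized as uniform random leaf subsets with the cardinality of
  the predicted set; a leaf subset induces the highlighted subtree, and
  cardinality is the stated constraint. Training-split leaves are excluded
  from the predicted set, the observed set and the null draws alike.
* **UniFrac** is the unweighted two-sample form on the full tree (unique
  branch length over spanned branch length): presence/absence is the only
  abundance available. The replicate-level comparison uses Welch's t-test;
  two constant equal groups give p = 1 by convention.

## Numerical and degenerate-input behaviour

Sigmoid outputs are clipped to $[10^{-7}, 1-10^{-7}]$ inside the loss.
Weights initialize Glorot-uniform (embedding uniform ±0.05, LSTM
forget-gate bias 1); Adam uses the conventional 0.001/0.9/0.999 with
epsilon $10^{-7}$. All randomness — initialization, shuffling, dropout,
splits, generation, null draws — flows through R's RNG from explicit
seeds, so every result in the package is exactly reproducible; replicate
seeds are drawn once from the configured seed. Vocabulary rank ties break
by first occurrence in the corpus. Training with a single-class label
vector is refused (the loss is degenerate); `epochs = 0` returns the
untrained model. A batch shorter than the convolution kernel is padded up
to one kernel window. Empty candidate sets, empty corpora and absent tree
leaves are all defined (empty set, empty tibble, drop-with-warning), not
errors; a missing species-list section or malformed newick is a structured
parse error.

The classifiers are implemented natively in vectorized R (the convolution
via an im2col matrix product; backpropagation through both architectures
is verified against numerical differentiation in the test suite). At the
package's problem sizes — 2,000 species, sequences of a few dozen tokens,
training sets up to 1,000 — a full five-replicate learning curve runs in
about a minute on one CPU core.

## Problem sizes used in tests

The test suite exercises the full study conditions (≈2,000 species, 20%
negation traps, learning curve over 100/250/500/1,000 × 5 replicates,
100-draw UniFrac null) in its end-to-end file, and smaller corpora
(30–60 genera) in per-module tests. Oracle checks run on 1,000 random
confusion configurations and 1,000 random trees of up to 20 leaves, with
an independent brute-force implementation of each quantity frozen in the
test helpers.

## Limitations

* The keyword rule is containment-only: no stemming, no fuzzy matching,
  no negation detection at the labeling stage (the classifier owns that).
* The sentence splitter is a punctuation rule; abbreviations can move
  filler text between sentences, which winnowing absorbs.
* Completeness comparisons are raw count ratios by default (as such
  figures are usually quoted), with an intersection mode for strict
  name-matched coverage.
* The package consumes trees as rooted newick (midpoint-rooting unrooted
  input); it does not align sequences or infer phylogenies.
* Synthetic performance is an upper bound, not an estimate, of real-text
  performance.

## A minimal run

```{r}
library(traitminer)

cfg <- default_run_config(seed = 1)
cfg$generator$n_genera <- 60
cfg$train$sizes <- c(100, 250)
cfg$train$replicates <- 3

dir <- file.path(tempdir(), "demo")
cmd_simulate(cfg, out_dir = dir)
res <- cmd_pipeline(cfg, data_dir = dir,
                    out_dir = file.path(tempdir(), "demo_out"),
                    traits = "fermentation")
res$fermentation$run$summary
res$fermentation$tree$t_test
```
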
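# traitminer

Predicting binary metabolic traits of microbial species from their written
descriptions.

Reference works of prokaryotic systematics describe thousands of species in
prose. Whether a species ferments, and whether it produces acetate when it
does, is stated in sentences like "Ferments glucose to acetate and
hydrogen" — or denied in sentences like "Non-fermentative". Databases need
those facts as bits, and keyword search alone cannot supply them: a
substring search for `ferment` flags "fermenter" and "non-fermentative"
alike. traitminer is an end-to-end pipeline for turning such corpora into
trait tables:

* parse genus-level articles into per-species descriptions (genus-level
  descriptive text plus the species' own entry in the article's species
  list);
* flag trait candidates by keyword containment and resolve labels through
  a curated table, with non-candidates negative by default;
* winnow each description to its keyword-bearing sentences, deduplicate,
  truncate at 25,000 characters, and tokenize against a frequency-ranked
  vocabulary capped at 3,000 words;
* train small convolutional or LSTM classifiers (implemented natively in
  the package) with binary cross-entropy and Adam, batch size 32, 10–40
  epochs, to separate affirmed traits from negated ones;
* evaluate with accuracy `(TP+TN)/(TP+TN+FP+FN)`, F1 `TP/[TP+(FP+FN)/2]`,
  precision `TP/(TP+FP)` and sensitivity `TP/(TP+FN)` as learning curves
  (mean ± SEM over five replicate trainings) across training-set sizes;
* evaluate phylogenetically: the unweighted UniFrac distance — unique
  branch length over spanned branch length — between predicted and
  observed trait-positive leaf sets on a reference tree, against a null of
  random leaf subsets of the same size (Welch's t-test across replicates).

Because compendium text is copyrighted, the package ships a synthetic
corpus generator that emits articles, ground-truth labels and a phylogeny
with the statistical structure the pipeline assumes (planted affirmative
sentences, negation traps, nested traits, clade-clumped trait
distributions). Every stage is testable without any external data; see the
vignette `vignettes/trait-mining.Rmd` for the model, parameter and design
details.

## Worked example

```r
library(traitminer)

cfg <- generator_config(n_genera = 60, seed = 42)
dir <- file.path(tempdir(), "demo")
gen <- generate_corpus(cfg, dir = dir)
print(gen)
#> <synthetic_corpus> 60 genera, 292 species (97 fermentative, 37 acetate producers)

corpus <- load_corpus(dir)
trait  <- trait_fermentation()
cand   <- flag_candidates(corpus, trait)
length(cand)
#> [1] 145
```

145 of 292 descriptions contain a fermentation keyword, but only 97
species are fermentative — the other 48 are negation traps that a curator
(here, the generator's truth table) labels negative after reading:

```r
labels <- resolve_labels(corpus, cand,
                         gen$labels[gen$labels$trait == "fermentation", ],
                         trait)
y     <- as.integer(labels$label == "positive")
texts <- vapply(corpus$text, winnow, character(1), trait = trait,
                config = text_prep_config(), USE.NAMES = FALSE)
run   <- run_replicates(texts, y, sizes = c(100L, 200L),
                        config = train_config(replicates = 3L, seed = 42),
                        trait_name = "fermentation")
run$summary
#>   model trait        n_train metric       mean     sem n_replicates
#> 1 cnn   fermentation     100 accuracy    0.984 0.00902            3
#> 2 cnn   fermentation     100 f1          0.977 0.0135             3
#> 3 cnn   fermentation     100 precision   1     0                  3
#> 4 cnn   fermentation     100 sensitivity 0.955 0.0259             3
#> 5 cnn   fermentation     200 accuracy    1     0                  3
#> 6 cnn   fermentation     200 f1          1     0                  3
#> 7 cnn   fermentation     200 precision   1     0                  3
#> 8 cnn   fermentation     200 sensitivity 1     0                  3
```

With 100 training species the network already classifies held-out species
at 98.4% mean accuracy (SEM 0.9% over three replicate trainings); with
200 it is perfect on this corpus — in particular on the negation traps
that defeat keyword search. The trait tree built from those predictions
is indistinguishable from the observed one and far from random subsets:

```r
nwk  <- generate_tree(gen$manifest, clade_signal = 0.9, seed = 43)
tree <- read_newick(nwk)
rr   <- run$runs[["n200_r1"]]
trait_tree_comparison(
  tree,
  predicted_positive = leaf_name(corpus$species_name[rr$eval][rr$label == 1]),
  observed_positive  = leaf_name(labels$species_name[y == 1]),
  exclude            = leaf_name(corpus$species_name[rr$train]),
  n_draws = 100, seed = 44)
#> <trait_tree_comparison> UniFrac 0.0000 (null 0.7078 +/- 0.0517, 5th pct 0.6212, empirical p 0.000)
```

A UniFrac distance of 0 means predicted and observed positives span the
same branches; random subsets of the same size average 0.71.

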
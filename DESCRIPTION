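Package: traitminer
Title: Predicting Microbial Metabolic Traits from Written Species Descriptions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end text-mining pipeline that predicts binary metabolic
    traits of microbial species (fermentative metabolism, acetate production)
    from written species descriptions of the kind found in taxonomic reference
    articles. Parses genus-level articles into per-species descriptions, flags
    trait candidates by keyword containment, winnows descriptions to
    keyword-bearing sentences, tokenizes them against a frequency-ranked
    vocabulary, and trains small convolutional or LSTM neural-network
    classifiers (implemented natively) to separate genuine trait statements
    from negation traps such as "non-fermentative". Predictions are evaluated
    with confusion-matrix metrics and learning curves over training-set size,
    and phylogenetically by the unweighted UniFrac distance between predicted
    and observed trait leaf sets against a random-subset null. A synthetic
    corpus generator emits articles, ground-truth labels and a phylogeny with
    the statistical structure the pipeline assumes, so the whole pipeline is
    testable without any copyrighted source text.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    phyloseq,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
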
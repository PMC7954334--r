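test_that("articles parse into the four recognized sections", {
  art <- parse_article(fixture_article())
  expect_s3_class(art, "trait_article")
  expect_equal(art$genus_name, "Clostridium")
  expect_named(art$sections,
               c("abstract", "further_descriptive_information",
                 "list_of_species", "references"))
  expect_match(art$sections$abstract, "Short abstract")
  expect_match(art$sections$further_descriptive_information, "sentinel")

  # missing References is fine: empty string, no error
  txt <- fixture_article()
  txt <- sub("## References.*$", "", txt)
  art3 <- parse_article(txt)
  expect_identical(art3$sections$references, "")

  # text under unrecognized section headers is ignored
  txt2 <- sub("## References",
              "## Enrichment and Isolation\nIgnored text.\n## References",
              fixture_article())
  art4 <- parse_article(txt2)
  expect_no_match(art4$sections$list_of_species, "Ignored text")
  expect_no_match(art4$sections$references, "Ignored text")
})

test_that("a missing species-list section is a structured parse error", {
  txt <- fixture_article()
  txt <- gsub("## List of Species of the Genus", "## Something Else", txt)
  err <- expect_error(parse_article(txt), class = "traitminer_parse_error")
  expect_match(conditionMessage(err), "species-list")
})

test_that("species names are extracted in document order, deduplicated", {
  art <- parse_article(fixture_article(
    species = c("acetobutylicum", "exampleum", "tertium")))
  expect_identical(extract_species_names(art),
                   c("Clostridium acetobutylicum", "Clostridium exampleum",
                     "Clostridium tertium"))

  # repeated header listed once; subspecies kept as its own name
  art2 <- parse_article(fixture_article(
    species = c("acetobutylicum", "acetobutylicum",
                "exampleum subsp. minor"),
    blocks = c("A.", "A again.", "B.")))
  expect_identical(extract_species_names(art2),
                   c("Clostridium acetobutylicum",
                     "Clostridium exampleum subsp. minor"))

  # strain suffix is captured separately, not part of the name
  art3 <- parse_article(fixture_article(species = "exampleum",
                                        blocks = "X.", strains = "AB-123"))
  expect_identical(extract_species_names(art3), "Clostridium exampleum")
  d <- assemble_description(art3, "Clostridium exampleum")
  expect_identical(d$strain_id, "AB-123")

  # an article with a species list but no matching names warns, empty list
  art4 <- parse_article(fixture_article(species = "exampleum"))
  art4$sections$list_of_species <- "### Othergenus thing\ntext"
  expect_warning(nm <- extract_species_names(art4), "no species names")
  expect_length(nm, 0)
})

test_that("descriptions combine genus text with only the species' own block", {
  art <- parse_article(fixture_article(
    species = c("alpha", "beta", "gamma"),
    blocks = c("TOKEN-ALPHA only.", "TOKEN-BETA only.", "TOKEN-GAMMA only."),
    fdi = "GENUS-TOKEN shared text."))
  names <- extract_species_names(art)
  descs <- lapply(names, assemble_description, article = art)
  for (i in seq_along(descs)) {
    expect_match(descs[[i]]$text, "GENUS-TOKEN")
    own <- c("TOKEN-ALPHA", "TOKEN-BETA", "TOKEN-GAMMA")[i]
    expect_match(descs[[i]]$text, own)
    for (other in setdiff(c("TOKEN-ALPHA", "TOKEN-BETA", "TOKEN-GAMMA"), own))
      expect_no_match(descs[[i]]$text, other)
  }

  # empty genus section: description is the species block alone
  art2 <- parse_article(fixture_article(species = "alpha", blocks = "Own.",
                                        fdi = ""))
  expect_identical(assemble_description(art2, "Clostridium alpha")$text,
                   "Own.")

  expect_error(assemble_description(art, "Clostridium missing"),
               "not found")
})

test_that("load_corpus unions articles; duplicate species later-wins", {
  d <- withr::local_tempdir()
  writeLines(fixture_article(genus = "Aaagenus",
                             species = c("una", "dua", "tria")),
             file.path(d, "a.txt"))
  writeLines(fixture_article(genus = "Bbbgenus", species = c("one", "two")),
             file.path(d, "b.txt"))
  corpus <- load_corpus(d)
  expect_equal(nrow(corpus), 5L)
  expect_setequal(corpus$genus, c("Aaagenus", "Bbbgenus"))

  # same species in a later file overrides, with a warning
  writeLines(fixture_article(genus = "Aaagenus", species = "una",
                             blocks = "LATER version."),
             file.path(d, "c.txt"))
  expect_warning(corpus2 <- load_corpus(d), "multiple articles")
  expect_equal(nrow(corpus2), 5L)
  expect_match(corpus2$text[corpus2$species_name == "Aaagenus una"], "LATER")

  # unparseable file skipped with warning, not fatal (the duplicate from
  # c.txt still warns too)
  writeLines("not an article at all", file.path(d, "broken.txt"))
  w <- testthat::capture_warnings(corpus3 <- load_corpus(d))
  expect_true(any(grepl("skipping", w)))
  expect_equal(nrow(corpus3), 5L)

  expect_equal(nrow(load_corpus(withr::local_tempdir())), 0L)
})

test_that("corpus TSV round-trips with newline escaping", {
  d <- withr::local_tempdir()
  writeLines(fixture_article(), file.path(d, "a.txt"))
  corpus <- load_corpus(d)
  expect_true(any(grepl("\n", corpus$text, fixed = TRUE)))
  f <- file.path(d, "corpus.tsv")
  write_corpus(corpus, f)
  expect_equal(length(readLines(f)), nrow(corpus) + 1L)  # one line each
  back <- read_corpus(f)
  expect_equal(back$species_name, corpus$species_name)
  expect_equal(back$text, corpus$text)
})
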
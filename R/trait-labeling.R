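#' Define a binary metabolic trait by its keyword rule
#'
#' A trait is identified in species descriptions by keyword containment:
#' every keyword in `required` must occur somewhere in the text, and, if
#' `any_of` is non-empty, at least one of its keywords must occur too.
#' Matching is by substring containment within words (see [keyword_match()]),
#' so "ferment" matches "fermenter" and "non-fermentative" alike.
#'
#' @param name Trait name, e.g. `"fermentation"`.
#' @param required Character vector of keywords that must all be present.
#' @param any_of Optional character vector; at least one must be present.
#' @return An object of class `trait_definition`.
#' @examples
#' trait_definition("fermentation", required = "ferment")
#' @export
trait_definition <- function(name, required, any_of = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  required <- tolower(as.character(required))
  any_of <- tolower(as.character(any_of))
  if (length(required) == 0L || any(!nzchar(required)))
    stop("`required` must be a non-empty set of non-empty keywords", call. = FALSE)
  structure(
    list(name = name, required = required, any_of = any_of),
    class = "trait_definition"
  )
}

#' @export
print.trait_definition <- function(x, ...) {
  cat("<trait_definition> ", x$name, "\n", sep = "")
  cat("  required: ", paste(x$required, collapse = ", "), "\n", sep = "")
  if (length(x$any_of))
    cat("  any of:   ", paste(x$any_of, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Built-in trait definitions
#'
#' Fermentative metabolism is flagged by the single keyword "ferment";
#' acetate production additionally requires "acetate" or "acetic" anywhere
#' in the description. Acetate production is nested within fermentation:
#' a species cannot produce acetate by fermentation without fermenting.
#'
#' @return A `trait_definition`.
#' @export
trait_fermentation <- function() {
  trait_definition("fermentation", required = "ferment")
}

#' @rdname trait_fermentation
#' @export
trait_acetate <- function() {
  trait_definition("acetate_production",
                   required = "ferment",
                   any_of = c("acetate", "acetic"))
}

# Words are maximal runs of letters and hyphens, case-folded. This keeps
# "non-fermentative" as one word so substring containment catches it.
.words <- function(text) {
  lowered <- tolower(text)
  regmatches(lowered, gregexpr("[a-z-]+", lowered))
}

#' Does any word of a text contain a keyword?
#'
#' Containment matching: a keyword matches any word containing it as a
#' substring, so "ferment" matches "ferment", "fermenter" and
#' "non-fermentative". Words are maximal runs of letters and hyphens in the
#' case-folded text.
#'
#' @param text Character vector of texts.
#' @param keyword A single non-empty lowercase keyword.
#' @return Logical vector, one element per text.
#' @examples
#' keyword_match("Non-fermentative rods.", "ferment")  # TRUE
#' keyword_match("Produces acetic acid.", "ferment")   # FALSE
#' @export
keyword_match <- function(text, keyword) {
  if (!is.character(keyword) || length(keyword) != 1L || !nzchar(keyword))
    stop("`keyword` must be a single non-empty string", call. = FALSE)
  vapply(.words(text),
         function(w) any(grepl(keyword, w, fixed = TRUE)),
         logical(1))
}

#' Does a text satisfy a trait's full keyword rule?
#'
#' @param text Character vector of texts.
#' @param trait A [trait_definition()].
#' @return Logical vector, one element per text.
#' @export
matches_trait <- function(text, trait) {
  stopifnot(inherits(trait, "trait_definition"))
  words <- .words(text)
  vapply(words, function(w) {
    req <- all(vapply(trait$required,
                      function(k) any(grepl(k, w, fixed = TRUE)), logical(1)))
    if (!req) return(FALSE)
    if (length(trait$any_of) == 0L) return(TRUE)
    any(vapply(trait$any_of,
               function(k) any(grepl(k, w, fixed = TRUE)), logical(1)))
  }, logical(1))
}

#' Flag trait candidates in a corpus
#'
#' Species whose description satisfies the trait's keyword rule are
#' candidates; all others are labeled negative by default without reading.
#' This mirrors manual curation workflows where only keyword hits are read
#' in full, and it is why keyword hits always outnumber true positives when
#' descriptions contain negated keywords ("non-fermentative").
#'
#' @param corpus A corpus data frame with columns `species_name` and `text`
#'   (as returned by [load_corpus()]).
#' @param trait A [trait_definition()].
#' @return Character vector of candidate species names (corpus order).
#' @export
flag_candidates <- function(corpus, trait) {
  stopifnot(is.data.frame(corpus),
            all(c("species_name", "text") %in% names(corpus)))
  if (nrow(corpus) == 0L) return(character())
  corpus$species_name[matches_trait(corpus$text, trait)]
}

#' Resolve trait labels from candidates and a curated table
#'
#' Candidates take their label from the curated table (which records the
#' outcome of reading each flagged description in full); every non-candidate
#' is labeled negative with source `"rule_negative"`. A candidate absent from
#' the curated table is an error: a flagged description must be read before
#' it can be labeled.
#'
#' @param corpus Corpus data frame (columns `species_name`, `text`).
#' @param candidates Character vector from [flag_candidates()].
#' @param curated Data frame with columns `species_name`, `label`
#'   (`"positive"`/`"negative"`) and optionally `justification`; must cover
#'   every candidate. Rows for non-candidates are ignored.
#' @param trait A [trait_definition()].
#' @return A tibble with columns `species_name`, `trait`, `label`, `source`,
#'   `justification` — one row per corpus species, corpus order.
#' @export
resolve_labels <- function(corpus, candidates, curated, trait) {
  stopifnot(is.data.frame(corpus), is.data.frame(curated),
            all(c("species_name", "label") %in% names(curated)))
  bad <- setdiff(candidates, corpus$species_name)
  if (length(bad))
    stop("candidates not in corpus: ", paste(bad, collapse = ", "), call. = FALSE)
  missing <- setdiff(candidates, curated$species_name)
  if (length(missing))
    stop("candidates missing from curated table: ",
         paste(missing, collapse = ", "), call. = FALSE)

  idx <- match(corpus$species_name, curated$species_name)
  is_cand <- corpus$species_name %in% candidates
  label <- ifelse(is_cand, curated$label[idx], "negative")
  if (any(is_cand & !label %in% c("positive", "negative")))
    stop("curated labels must be 'positive' or 'negative'", call. = FALSE)
  just <- if ("justification" %in% names(curated))
    ifelse(is_cand, curated$justification[idx], NA_character_)
  else NA_character_
  tibble::tibble(
    species_name = corpus$species_name,
    trait = trait$name,
    label = label,
    source = ifelse(is_cand, "curated", "rule_negative"),
    justification = just
  )
}

#' Read and write label tables
#'
#' Long-format tab-separated label tables with columns `species_name`,
#' `trait`, `label`, `source`, `justification` and a header row.
#'
#' @param labels Label tibble as returned by [resolve_labels()].
#' @param path File path.
#' @return `read_labels()` returns the label tibble; `write_labels()` returns
#'   `path` invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          na.strings = "", colClasses = "character",
                          comment.char = "")
  tibble::as_tibble(df)
}

#' Tally positive labels per trait
#'
#' Counts positive species per trait in a long-format label table, plus the
#' number of species positive for every trait at once (for nested traits
#' such as acetate production within fermentation, this is the nesting
#' count).
#'
#' @param labels Long-format label tibble (possibly several traits).
#' @return A list with `per_trait` (named integer vector of positive counts)
#'   and `all_traits` (species positive for every trait present).
#' @export
label_tally <- function(labels) {
  stopifnot(all(c("species_name", "trait", "label") %in% names(labels)))
  pos <- labels[labels$label == "positive", , drop = FALSE]
  per_trait <- vapply(split(pos$species_name, factor(pos$trait)),
                      function(x) length(unique(x)), integer(1))
  traits <- unique(labels$trait)
  sets <- lapply(traits, function(tr) unique(pos$species_name[pos$trait == tr]))
  all_traits <- if (length(sets)) length(Reduce(intersect, sets)) else 0L
  list(per_trait = per_trait, all_traits = all_traits)
}
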
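#' The plain-text article schema
#'
#' Genus-level reference articles are consumed as UTF-8 plain text, one
#' article per file, in a light markup emulating the structure of taxonomic
#' compendium articles:
#'
#' ```
#' # Genusname
#' ## Abstract
#' ...
#' ## Further Descriptive Information
#' ...
#' ## List of Species of the Genus
#' ### Genusname epithet (strain AB-123)
#' ...species text...
#' ### Genusname other
#' ...
#' ## References
#' ...
#' ```
#'
#' The genus is named on the `#` title line; `##` lines open the four
#' recognized sections (unrecognized `##` sections are ignored); `###` lines
#' inside the species list open one species block each, running to the next
#' species header or the end of the section. A parenthesized
#' `(strain <ID>)` suffix on the species header is captured as the strain ID
#' and is not part of the species name. All patterns are configurable.
#'
#' @param genus_pattern Regex with one capture group for the genus title line.
#' @param section_pattern Regex with one capture group for section headers.
#' @param species_pattern Regex with one capture group for species headers.
#' @param strain_pattern Regex with one capture group extracting the strain
#'   ID from a species header; use `NULL` to disable strain capture.
#' @param section_names Named character vector mapping canonical slot names
#'   to the header text used in files.
#' @return A list of class `article_schema`.
#' @export
article_schema <- function(genus_pattern = "^#\\s+(\\S+)\\s*$",
                           section_pattern = "^##\\s+(.+?)\\s*$",
                           species_pattern = "^###\\s+(.+?)\\s*$",
                           strain_pattern = "\\(strain\\s+([^)]+)\\)",
                           section_names = c(
                             abstract = "Abstract",
                             further_descriptive_information =
                               "Further Descriptive Information",
                             list_of_species = "List of Species of the Genus",
                             references = "References")) {
  structure(list(genus_pattern = genus_pattern,
                 section_pattern = section_pattern,
                 species_pattern = species_pattern,
                 strain_pattern = strain_pattern,
                 section_names = section_names),
            class = "article_schema")
}

.section_slots <- c("abstract", "further_descriptive_information",
                    "list_of_species", "references")

#' Parse one genus-level article
#'
#' Splits an article into its four recognized sections. Text before the
#' first recognized section header, and text under unrecognized headers, is
#' ignored. A missing species-list section is an error (an article without
#' one carries no species descriptions); other missing sections yield empty
#' strings.
#'
#' @param raw_text Article text as a single string or character vector of
#'   lines.
#' @param schema An [article_schema()].
#' @param source_id Identifier for provenance (defaults to the genus name).
#' @return An object of class `trait_article`: list with `genus_name`,
#'   `sections` (named list of the four section texts) and `source_id`.
#' @export
parse_article <- function(raw_text, schema = article_schema(),
                          source_id = NULL) {
  stopifnot(inherits(schema, "article_schema"))
  lines <- if (length(raw_text) == 1L) strsplit(raw_text, "\n", fixed = TRUE)[[1]]
           else as.character(raw_text)

  gm <- regmatches(lines, regexec(schema$genus_pattern, lines))
  g_idx <- which(vapply(gm, length, integer(1)) == 2L)
  if (length(g_idx) == 0L)
    stop_parse("no genus title line matched `genus_pattern`")
  genus <- gm[[g_idx[1]]][2]

  sm <- regmatches(lines, regexec(schema$section_pattern, lines))
  s_idx <- which(vapply(sm, length, integer(1)) == 2L)
  s_name <- vapply(s_idx, function(i) sm[[i]][2], character(1))
  slot <- names(schema$section_names)[match(s_name, schema$section_names)]

  sections <- stats::setNames(as.list(rep("", length(.section_slots))),
                              .section_slots)
  keep <- !is.na(slot)
  s_idx <- s_idx[keep]; slot <- slot[keep]
  bounds <- c(s_idx, length(lines) + 1L)
  for (k in seq_along(s_idx)) {
    body <- if (s_idx[k] + 1L > bounds[k + 1L] - 1L) character(0)
            else lines[seq.int(s_idx[k] + 1L, bounds[k + 1L] - 1L)]
    # a recognized section ends where the next recognized OR unrecognized
    # `##` header begins; unrecognized sections are simply never collected
    nxt <- which(grepl(schema$section_pattern, body))
    if (length(nxt)) body <- body[seq_len(nxt[1] - 1L)]
    sections[[slot[k]]] <- paste(body, collapse = "\n")
  }

  if (!nzchar(trimws(sections$list_of_species)))
    stop_parse(sprintf(
      "article '%s' is missing its species-list section ('%s')",
      genus, schema$section_names[["list_of_species"]]))

  structure(list(genus_name = genus, sections = sections,
                 source_id = source_id %||% genus),
            class = "trait_article")
}

stop_parse <- function(msg) {
  stop(structure(class = c("traitminer_parse_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Species headers inside the list section, as (line index, full header text).
.species_headers <- function(article, schema) {
  lines <- strsplit(article$sections$list_of_species, "\n", fixed = TRUE)[[1]]
  m <- regmatches(lines, regexec(schema$species_pattern, lines))
  idx <- which(vapply(m, length, integer(1)) == 2L)
  hdr <- vapply(idx, function(i) m[[i]][2], character(1))
  # only headers that begin with the genus name are species of this genus
  ok <- startsWith(hdr, paste0(article$genus_name, " "))
  list(lines = lines, idx = idx[ok], header = hdr[ok])
}

.strip_strain <- function(header, schema) {
  if (is.null(schema$strain_pattern)) return(trimws(header))
  trimws(sub(schema$strain_pattern, "", header))
}

.strain_of <- function(header, schema) {
  if (is.null(schema$strain_pattern)) return(NA_character_)
  m <- regmatches(header, regexec(schema$strain_pattern, header))[[1]]
  if (length(m) == 2L) m[2] else NA_character_
}

#' Extract species names from a parsed article
#'
#' Finds species headers in the species-list section whose name begins with
#' the article's genus name. Subspecies, biovar, pathovar and genomospecies
#' entries are separate names, treated as species. Names are returned in
#' document order, deduplicated.
#'
#' @param article A [parse_article()] result.
#' @param schema The [article_schema()] used to parse it.
#' @return Character vector of species names; empty (with a warning) if none
#'   found.
#' @export
extract_species_names <- function(article, schema = article_schema()) {
  stopifnot(inherits(article, "trait_article"))
  sp <- .species_headers(article, schema)
  names <- unique(vapply(sp$header, .strip_strain, character(1),
                         schema = schema, USE.NAMES = FALSE))
  if (length(names) == 0L)
    warning(sprintf("no species names found in article '%s'",
                    article$genus_name), call. = FALSE)
  names
}

#' Assemble the written description of one species
#'
#' A species description is the genus-level descriptive section plus the
#' species' own block of the species list — and nothing from sibling
#' species' blocks. A block runs from the species' header line to the next
#' species header or the end of the section.
#'
#' @inheritParams extract_species_names
#' @param species_name A name returned by [extract_species_names()].
#' @return A list of class `species_description` with fields `species_name`,
#'   `genus_name`, `strain_id`, `text`, `source_article`.
#' @export
assemble_description <- function(article, species_name,
                                 schema = article_schema()) {
  stopifnot(inherits(article, "trait_article"))
  sp <- .species_headers(article, schema)
  names <- vapply(sp$header, .strip_strain, character(1),
                  schema = schema, USE.NAMES = FALSE)
  hit <- which(names == species_name)
  if (length(hit) == 0L)
    stop(sprintf("species '%s' not found in article '%s'",
                 species_name, article$genus_name), call. = FALSE)
  hit <- hit[1]
  from <- sp$idx[hit] + 1L
  to <- if (hit < length(sp$idx)) sp$idx[hit + 1L] - 1L else length(sp$lines)
  block <- if (from <= to) paste(sp$lines[from:to], collapse = "\n") else ""

  genus_text <- trimws(article$sections$further_descriptive_information)
  block <- trimws(block)
  text <- trimws(paste(genus_text, block, sep = "\n"))
  if (!nzchar(text))
    stop(sprintf("assembled description for '%s' is empty", species_name),
         call. = FALSE)

  structure(list(species_name = species_name,
                 genus_name = article$genus_name,
                 strain_id = .strain_of(sp$header[hit], schema),
                 text = text,
                 source_article = article$source_id),
            class = "species_description")
}

#' Load a corpus of species descriptions from a directory of article files
#'
#' Parses every `*.txt` article in a directory and assembles one description
#' per species. Unreadable or unparseable files are skipped with a warning.
#' If the same species name occurs in more than one article, the
#' later-parsed article wins, with a warning.
#'
#' @param directory Directory of article files.
#' @param schema An [article_schema()].
#' @param pattern Filename pattern for article files.
#' @return A tibble (the corpus) with columns `species_name`, `genus`,
#'   `strain_id`, `text`, `source_article`.
#' @export
load_corpus <- function(directory, schema = article_schema(),
                        pattern = "\\.txt$") {
  files <- sort(list.files(directory, pattern = pattern, full.names = TRUE))
  rows <- list()
  for (f in files) {
    art <- tryCatch({
      parse_article(readLines(f, warn = FALSE, encoding = "UTF-8"),
                    schema = schema,
                    source_id = basename(f))
    }, error = function(e) {
      warning(sprintf("skipping '%s': %s", basename(f), conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(art)) next
    for (nm in extract_species_names(art, schema)) {
      d <- assemble_description(art, nm, schema)
      if (nm %in% names(rows))
        warning(sprintf(
          "species '%s' appears in multiple articles; keeping '%s'",
          nm, art$source_id), call. = FALSE)
      rows[[nm]] <- d
    }
  }
  tibble::tibble(
    species_name = vapply(rows, `[[`, character(1), "species_name",
                          USE.NAMES = FALSE),
    genus = vapply(rows, `[[`, character(1), "genus_name", USE.NAMES = FALSE),
    strain_id = vapply(rows, `[[`, character(1), "strain_id",
                       USE.NAMES = FALSE),
    text = vapply(rows, `[[`, character(1), "text", USE.NAMES = FALSE),
    source_article = vapply(rows, `[[`, character(1), "source_article",
                            USE.NAMES = FALSE)
  )
}

#' Read and write a corpus as TSV
#'
#' Tab-separated with a header row; newlines inside the text column are
#' escaped as `\\n` so each species occupies one line.
#'
#' @param corpus Corpus tibble from [load_corpus()].
#' @param path File path.
#' @export
write_corpus <- function(corpus, path) {
  out <- corpus
  out$text <- gsub("\n", "\\\\n", out$text, fixed = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          na.strings = "", colClasses = "character",
                          comment.char = "")
  df$text <- gsub("\\\\n", "\n", df$text)
  tibble::as_tibble(df)
}
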
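# Bundle all extractors: one decoded record per article, a tibble per
# collection.

#' Decode one JATS article
#'
#' Runs every extractor on one document and returns the unified record:
#' metadata, contributors with identifiers, affiliations and countries,
#' publication history with the unified earliest publication date and
#' editorial lags, abstract, sectioned text and reference list.
#'
#' @param x a file path, a `jats_document`, or an XML string.
#' @param sectionsplit optional substring patterns passed to
#'   [split_into_main_sections()]; when given, `sections` holds the
#'   merged main sections.
#' @param shorten_given shorten given names to one-letter abbreviations.
#' @return An object of class `jats_article`: a named list of fields.
#' @export
decode_article <- function(x, sectionsplit = character(), shorten_given = FALSE) {
  doc <- if (is.character(x) && length(x) == 1 && !grepl("<", x, fixed = TRUE)) {
    read_jats(x)
  } else {
    as_jats_document(x)
  }
  if (!stringi::stri_detect_regex(doc$content, "<article[\\s>]")) {
    stop("no <article> element found", call. = FALSE)
  }

  history <- get_history(doc)
  pub <- compute_pub_date(history)
  lags <- publication_lags(history, pub$pub_date)
  affs <- get_affiliations(doc)
  abstract <- get_abstract(doc)
  sections <- get_sections(doc)
  if (length(sectionsplit)) {
    merged <- split_into_main_sections(sections, sectionsplit)
    sections <- tibble::tibble(title = merged$title, text = merged$text)
  }
  body_text <- paste(sections$text, collapse = " ")

  rec <- list(
    source = doc$source_path,
    title = get_simple_tag(doc, "title"),
    journal = get_simple_tag(doc, "journal"),
    doi = get_simple_tag(doc, "doi"),
    type = get_simple_tag(doc, "type"),
    volume = get_simple_tag(doc, "volume"),
    subjects = get_subjects(doc),
    keywords = get_keywords(doc),
    authors = get_contributors(doc, "author", shorten_given = shorten_given),
    editors = get_contributors(doc, "editor", shorten_given = shorten_given),
    affiliations = affs,
    countries = get_countries(affs),
    history = history,
    pub_date = pub$pub_date,
    pubyear = pub$pubyear,
    time_to_accept = lags$time_to_accept,
    time_to_publish = lags$time_to_publish,
    abstract = abstract$abstract,
    abstract_present = abstract$present,
    sections = sections,
    text_present = nchar(stringi::stri_trim_both(body_text)) >= 30,
    references = get_references(doc)$raw
  )
  structure(rec, class = "jats_article")
}

#' @export
print.jats_article <- function(x, ...) {
  cat("<jats_article>", if (is.na(x$title)) "(untitled)" else x$title, "\n")
  cat("  journal:", x$journal, " type:", x$type, " pubyear:", x$pubyear, "\n")
  cat("  authors:", nrow(x$authors), " sections:", nrow(x$sections),
      " references:", length(x$references), "\n")
  invisible(x)
}

#' @export
tidy.jats_article <- function(x, ...) {
  tibble::tibble(
    field = names(unclass(x)),
    value = lapply(unclass(x), identity)
  )
}

#' Decode a collection of JATS files into a tidy corpus
#'
#' Applies [decode_article()] to every file and stacks the records into a
#' tibble, one row per decodable article, with list columns for the
#' multi-valued fields. Files that fail to decode are logged and skipped,
#' never fatal; the result does not depend on processing order.
#'
#' @param paths character vector of file paths, or one directory
#'   containing `.xml`/`.nxml` files.
#' @param sectionsplit,shorten_given passed to [decode_article()].
#' @return A tibble of class `jats_corpus`.
#' @export
decode_collection <- function(paths, sectionsplit = character(),
                              shorten_given = FALSE) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(xml|nxml)$", full.names = TRUE)
  }
  if (!length(paths)) {
    stop("no JATS files to decode", call. = FALSE)
  }
  rows <- purrr::map(paths, function(p) {
    rec <- tryCatch(
      decode_article(p, sectionsplit = sectionsplit,
                     shorten_given = shorten_given),
      error = function(e) {
        log_event("decode_collection", paste0(p, ": ", conditionMessage(e)))
        NULL
      }
    )
    if (is.null(rec)) return(NULL)
    as_corpus_row(rec)
  })
  rows <- purrr::compact(rows)
  if (!length(rows)) {
    stop("all files failed to decode", call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("jats_corpus", class(out))
  out
}

as_corpus_row <- function(rec) {
  tibble::tibble(
    source = rec$source %|na|% NA_character_,
    title = rec$title,
    journal = rec$journal,
    doi = rec$doi,
    type = rec$type,
    volume = rec$volume,
    subjects = list(rec$subjects),
    keywords = list(rec$keywords),
    authors = list(rec$authors),
    editors = list(rec$editors),
    affiliations = list(rec$affiliations),
    countries = list(rec$countries),
    history = list(rec$history),
    pub_date = rec$pub_date,
    pubyear = rec$pubyear,
    time_to_accept = rec$time_to_accept,
    time_to_publish = rec$time_to_publish,
    abstract = rec$abstract,
    abstract_present = rec$abstract_present,
    sections = list(rec$sections),
    text_present = rec$text_present,
    references = list(rec$references)
  )
}

#' @export
glance.jats_corpus <- function(x, ...) {
  has_country <- vapply(x$countries, length, 1L) > 0
  multi <- vapply(x$countries, length, 1L) > 1
  tibble::tibble(
    n_articles = nrow(x),
    n_journals = dplyr::n_distinct(x$journal[!is.na(x$journal)]),
    frac_abstract = mean(x$abstract_present),
    frac_text = mean(x$text_present),
    frac_country = mean(has_country),
    international_share = if (any(has_country)) mean(multi[has_country]) else 0,
    earliest_pubyear = suppressWarnings(min(x$pubyear, na.rm = TRUE)),
    latest_pubyear = suppressWarnings(max(x$pubyear, na.rm = TRUE))
  )
}

#' Serialize decoded records as JSON / NDJSON
#'
#' A single record writes as one UTF-8 JSON object (section lists as
#' arrays of `{title, text}`); a corpus writes as NDJSON, one record per
#' line.
#'
#' @param article a `jats_article`.
#' @param corpus a `jats_corpus` tibble.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_article_json <- function(article, path) {
  jsonlite::write_json(article_to_list(article), path,
                       auto_unbox = TRUE, null = "null", na = "null",
                       digits = NA)
  invisible(path)
}

article_to_list <- function(article) {
  x <- unclass(article)
  x$pub_date <- if (is.na(x$pub_date)) NULL else format(x$pub_date, "%Y-%m-%d")
  x$authors <- as.data.frame(x$authors[c("surname", "given")])
  x$editors <- as.data.frame(x$editors[c("surname", "given")])
  x$affiliations <- lapply(seq_len(nrow(x$affiliations)), function(i) {
    list(text = x$affiliations$text[i],
         countries = x$affiliations$countries[[i]])
  })
  x$history <- as.data.frame(x$history)
  x$sections <- as.data.frame(x$sections)
  x
}

#' @rdname write_article_json
#' @export
write_corpus_ndjson <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    row <- as.list(corpus[i, ])
    row <- lapply(row, function(v) if (is.list(v)) v[[1]] else v)
    row$pub_date <- if (is.na(row$pub_date)) NULL else format(row$pub_date, "%Y-%m-%d")
    row$authors <- as.data.frame(row$authors[c("surname", "given")])
    row$editors <- as.data.frame(row$editors[c("surname", "given")])
    row$history <- as.data.frame(row$history)
    row$sections <- as.data.frame(row$sections)
    row$affiliations <- as.data.frame(row$affiliations["text"])
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, null = "null",
                                na = "null", digits = NA), con)
  }
  invisible(path)
}
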
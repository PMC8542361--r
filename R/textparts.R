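# Abstract, sectioned body text, sentence segmentation, references.

# render an XML block as clean floating text: figures/tables (and their
# captions) are excluded, formula elements pass through flatten_math(),
# remaining markup is dropped, characters unified, spacing fixed
clean_text_block <- function(raw) {
  x <- drop_float_elements(raw)
  # flattened formulas may contain "<": park them behind placeholders so
  # tag stripping cannot eat them
  flat <- character()
  for (tag in c("inline-formula", "disp-formula", "math")) {
    for (f in extract_fragments(x, tag)) {
      flat <- c(flat, as.character(flatten_math(f)))
      x <- stringi::stri_replace_first_fixed(
        x, f$raw_xml, sprintf("\ue002%d\ue003", length(flat))
      )
    }
  }
  x <- strip_tags(x)
  x <- convert_letters(x)
  for (i in seq_along(flat)) {
    x <- stringi::stri_replace_first_fixed(
      x, sprintf("\ue002%d\ue003", i), flat[i]
    )
  }
  fix_spacing(x)
}

#' Extract the abstract
#'
#' The abstract text is entity-converted and markup-free. Following the
#' presence rule used throughout the package, an abstract with fewer than
#' 30 characters (or an absent tag) is treated as not present.
#'
#' @param doc a `jats_document` or XML string.
#' @param as_sentences if `TRUE`, `abstract` is the [text2sentences()]
#'   segmentation instead of one floating string.
#' @return A list with `abstract` (string, or character vector of
#'   sentences) and `present` (logical).
#' @export
get_abstract <- function(doc, as_sentences = FALSE) {
  doc <- as_jats_document(doc)
  frs <- extract_fragments(doc, "abstract")
  if (!length(frs)) {
    return(list(abstract = NA_character_, present = FALSE))
  }
  text <- clean_text_block(inner_xml(frs[[1]]))
  present <- !is.na(text) && nchar(text) >= 30
  if (as_sentences) {
    return(list(abstract = text2sentences(text), present = present))
  }
  list(abstract = text, present = present)
}

#' Extract body sections
#'
#' Sections and subsections are not differentiated: every titled
#' section at any nesting depth becomes one row, flattened in reading
#' order (a parent section precedes its subsections). Untitled leading
#' body text becomes a row with an empty title. Figures, tables and their
#' captions are excluded from section text; formulas are flattened to
#' plain text.
#'
#' @param doc a `jats_document` or XML string.
#' @return A tibble with columns `title` and `text`; zero rows when the
#'   body is absent or empty.
#' @export
get_sections <- function(doc) {
  doc <- as_jats_document(doc)
  bodies <- extract_fragments(doc, "body")
  empty <- tibble::tibble(title = character(), text = character())
  if (!length(bodies)) return(empty)
  rows <- walk_sections(inner_xml(bodies[[1]]), top_level = TRUE)
  if (!length(rows)) return(empty)
  tibble::tibble(
    title = vapply(rows, `[[`, "", "title"),
    text = vapply(rows, `[[`, "", "text")
  )
}

drop_float_elements <- function(x) {
  stringi::stri_replace_all_regex(
    x,
    "(?s)<(fig|fig-group|table-wrap|table-wrap-group|supplementary-material|graphic)\\b[^>]*(?:/>|>.*?</\\1\\s*>)",
    " "
  )
}

walk_sections <- function(raw, top_level = FALSE) {
  secs <- extract_fragments(raw, "sec")
  own <- raw
  for (s in secs) own <- stringi::stri_replace_first_fixed(own, s$raw_xml, "")
  own <- drop_float_elements(own)

  rows <- list()
  if (top_level) {
    lead <- clean_text_block(own)
    if (nzchar(lead)) rows[[1]] <- list(title = "", text = lead)
  } else {
    # this sec's own title is the first top-level <title> once child secs
    # and floats are gone
    tfr <- extract_fragments(own, "title")
    title <- if (length(tfr)) clean_value(inner_xml(tfr[[1]])) else NA_character_
    if (length(tfr)) own <- stringi::stri_replace_first_fixed(own, tfr[[1]]$raw_xml, "")
    rows[[1]] <- list(
      title = if (is.na(title)) "" else title,
      text = clean_text_block(own)
    )
  }
  for (s in secs) rows <- c(rows, walk_sections(inner_xml(s)))
  rows
}

#' Merge raw sections into main sections
#'
#' Each section whose title contains any of the patterns (matched
#' case-insensitively as plain substrings) starts a group; following
#' non-matching sections are merged into it, their texts concatenated
#' with a blank line and their titles kept in the `titles` list column.
#' Sections before the first match form one leading group. An empty
#' pattern list returns the sections unchanged.
#'
#' @param sections tibble from [get_sections()] (columns `title`, `text`).
#' @param sectionsplit character vector of substring patterns, e.g.
#'   `c("intro", "method", "result", "discussion")`.
#' @return A tibble with columns `title` (the group-opening title),
#'   `titles` (list of all merged titles) and `text`.
#' @export
#' @examples
#' secs <- tibble::tibble(
#'   title = c("Introduction", "Method", "Participants", "Results", "Discussion"),
#'   text = paste("text", 1:5))
#' split_into_main_sections(secs, c("intro", "method", "result", "discussion"))$title
split_into_main_sections <- function(sections, sectionsplit = character()) {
  stopifnot(is.data.frame(sections),
            all(c("title", "text") %in% names(sections)))
  if (!nrow(sections) || !length(sectionsplit)) {
    return(tibble::tibble(title = sections$title,
                          titles = as.list(sections$title),
                          text = sections$text))
  }
  hit <- rep(FALSE, nrow(sections))
  for (p in sectionsplit) {
    hit <- hit | stringi::stri_detect_fixed(sections$title, p,
                                            case_insensitive = TRUE)
  }
  grp <- cumsum(hit)
  tibble::tibble(title = sections$title, titles = sections$title,
                 text = sections$text, grp = grp) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(
      title = .data$title[1],
      titles = list(.data$titles),
      text = paste(.data$text, collapse = "\n\n"),
      .groups = "drop"
    ) |>
    dplyr::select("title", "titles", "text")
}

load_abbreviations <- function() {
  if (!is.null(the$abbrev)) return(the$abbrev)
  ab <- readLines(system.file("extdata", "abbreviations.txt",
                              package = "jatsr", mustWork = TRUE),
                  encoding = "UTF-8")
  ab <- ab[nzchar(ab)]
  the$abbrev <- ab[order(-nchar(ab))]
  the$abbrev
}

#' Split text into sentences
#'
#' Splits at sentence-final punctuation (`. ! ?`) followed by whitespace
#' and an uppercase letter or digit. Protected positions never split:
#' decimal numbers (`p = .05`, `3.14`), a shipped abbreviation list
#' (`e.g.`, `et al.`, `Fig.`, `vs.`, ...), single-letter initials
#' (`J. R. Smith`) and leading ordinal enumerators. Joining the result
#' with single spaces reproduces the input up to whitespace.
#'
#' @param text a single string (entity-converted text).
#' @return Character vector of sentences.
#' @export
#' @examples
#' text2sentences("Smith et al. (2020) agree. We concur.")
text2sentences <- function(text) {
  stopifnot(length(text) <= 1)
  if (!length(text) || is.na(text)) return(character())
  PROT <- "\ue000"
  MARK <- "\ue001"
  x <- stringi::stri_trim_both(stringi::stri_replace_all_regex(text, "\\s+", " "))
  if (!nzchar(x)) return(character())

  # abbreviation protection (case-sensitive, word-anchored)
  for (ab in load_abbreviations()) {
    pat <- paste0("(?<![\\p{L}])",
                  stringi::stri_replace_all_fixed(ab, ".", "\\."), "\\.")
    rep <- paste0(stringi::stri_replace_all_fixed(ab, ".", PROT), PROT)
    x <- stringi::stri_replace_all_regex(x, pat, rep)
  }
  # initials: protect chains ("J. R. Smith") but not a lone capital that
  # legitimately ends a sentence ("... group A. Group B ...")
  x <- stringi::stri_replace_all_regex(
    x, "(?<=^\\p{Lu})\\.(?=\\s\\p{Lu}\\.)", PROT)
  x <- stringi::stri_replace_all_regex(
    x, "(?<=[\\s(\"']\\p{Lu})\\.(?=\\s\\p{Lu}\\.)", PROT)
  x <- stringi::stri_replace_all_regex(
    x, paste0("(?<=\\p{Lu}", PROT, " \\p{Lu})\\."), PROT)
  # decimals
  x <- stringi::stri_replace_all_regex(x, "(?<=\\d)\\.(?=\\d)", PROT)
  # leading ordinal enumerator ("1. Introduction")
  x <- stringi::stri_replace_all_regex(x, "^(\\d{1,3})\\.", paste0("$1", PROT))

  x <- stringi::stri_replace_all_regex(
    x, "([.!?]+)\\s+(?=[\\p{Lu}0-9])", paste0("$1", MARK)
  )
  out <- stringi::stri_split_fixed(x, MARK)[[1]]
  out <- stringi::stri_replace_all_fixed(out, PROT, ".")
  out[nzchar(out)]
}

#' Extract the reference list
#'
#' One row per citation element in the back matter, in listed order.
#' Free-text (`mixed-citation`) entries are cleaned to one string;
#' structured (`element-citation`) entries have their parts joined in
#' document order with `", "`.
#'
#' @param doc a `jats_document` or XML string.
#' @return A tibble with columns `index` and `raw`.
#' @export
get_references <- function(doc) {
  doc <- as_jats_document(doc)
  backs <- extract_fragments(doc, "back")
  scope <- if (length(backs)) backs[[1]]$raw_xml else doc$content
  refs <- extract_fragments(scope, "ref")
  raws <- character(length(refs))
  for (i in seq_along(refs)) {
    inner <- stringi::stri_replace_all_regex(
      inner_xml(refs[[i]]), "(?s)<label\\b[^>]*>.*?</label\\s*>", ""
    )
    cite <- extract_fragments(inner, "element-citation")
    raw <- if (length(cite)) {
      segs <- stringi::stri_split_regex(
        strip_formatting_tags(inner_xml(cite[[1]])), "(?s)<[^>]*>")[[1]]
      segs <- stringi::stri_trim_both(convert_letters(segs))
      segs <- segs[nzchar(segs) & !stringi::stri_detect_regex(segs, "^[[:punct:]]+$")]
      paste(segs, collapse = ", ")
    } else {
      stringi::stri_trim_both(convert_letters(strip_tags(inner)))
    }
    raws[i] <- fix_spacing(raw)
  }
  out <- tibble::tibble(index = seq_along(refs), raw = raws)
  out[nzchar(out$raw), , drop = FALSE]
}
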
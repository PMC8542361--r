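# Metadata extraction: simple tags, subjects/keywords, and the
# publication history with its unified earliest publication date.

#' Recognised history date-stamp labels
#'
#' The 14-label vocabulary observed across PMC publication histories.
#' Unknown labels are kept under the catch-all `"other"` and logged.
#' @export
HISTORY_LABELS <- c(
  "accepted", "collection", "ecorrected", "epreprint", "epub",
  "nihms_submitted", "pmc-release", "ppub", "print", "pub",
  "received", "retracted", "rev-recd", "submitted"
)

# the six publication-event stamps a unified publication date is drawn
# from; the remaining eight labels denote editorial/administrative events
PUB_EVENT_LABELS <- c("epub", "ppub", "print", "pub", "collection", "pmc-release")

#' Extract a simple metadata field
#'
#' Title, journal, DOI, article type and volume sit in uniformly used
#' tags and extract with plain pattern matching. Values are tag-stripped,
#' entity-converted and trimmed. The type is read from the article-level
#' `article-type` attribute, falling back to an explicit type element.
#'
#' @param doc a `jats_document` or XML string.
#' @param which one of `"title"`, `"journal"`, `"doi"`, `"type"`,
#'   `"volume"`.
#' @return A single string, or `NA_character_` when the field is absent
#'   (never an empty string).
#' @export
#' @examples
#' get_simple_tag("<article><front><title-group>
#'   <article-title>Big &#x3b1; study</article-title>
#'   </title-group></front></article>", "title")
get_simple_tag <- function(doc, which = c("title", "journal", "doi", "type", "volume")) {
  which <- match.arg(which)
  doc <- as_jats_document(doc)
  val <- switch(which,
    title = first_inner(doc, "article-title"),
    journal = first_inner(doc, "journal-title"),
    doi = {
      ids <- extract_fragments(doc, "article-id")
      hit <- purrr::detect(ids, function(f) {
        identical(unname(f$attributes["pub-id-type"]), "doi")
      })
      if (is.null(hit)) NA_character_ else inner_xml(hit)
    },
    type = {
      art <- stringi::stri_match_first_regex(
        doc$content, "<article\\b[^>]*\\barticle-type\\s*=\\s*[\"']([^\"']+)[\"']"
      )[, 2]
      if (!is.na(art)) art else first_inner(doc, "article-type")
    },
    volume = first_inner(doc, "volume")
  )
  clean_value(val)
}

first_inner <- function(doc, tag) {
  frs <- extract_fragments(doc, tag)
  if (!length(frs)) NA_character_ else inner_xml(frs[[1]])
}

clean_value <- function(val) {
  if (is.null(val) || is.na(val)) return(NA_character_)
  out <- stringi::stri_trim_both(convert_letters(strip_tags(val)))
  if (!nzchar(out)) NA_character_ else out
}

#' @rdname get_simple_tag
#' @export
get_title <- function(doc) get_simple_tag(doc, "title")

#' @rdname get_simple_tag
#' @export
get_journal <- function(doc) get_simple_tag(doc, "journal")

#' @rdname get_simple_tag
#' @export
get_doi <- function(doc) get_simple_tag(doc, "doi")

#' @rdname get_simple_tag
#' @export
get_type <- function(doc) get_simple_tag(doc, "type")

#' @rdname get_simple_tag
#' @export
get_volume <- function(doc) get_simple_tag(doc, "volume")

#' Extract subjects and keywords
#'
#' Subject elements are flattened across every nesting level of
#' `subj-group` into one list; keyword entries that consist only of
#' separator characters are dropped. Entries are entity-converted,
#' trimmed and de-duplicated preserving order.
#'
#' @param doc a `jats_document` or XML string.
#' @return character vector (possibly empty).
#' @export
#' @examples
#' get_keywords("<a><kwd-group><kwd>Covid-19</kwd><kwd>SARS-Cov-2</kwd>
#'   </kwd-group></a>")
get_subjects <- function(doc) {
  extract_string_list(doc, "subject")
}

#' @rdname get_subjects
#' @export
get_keywords <- function(doc) {
  extract_string_list(doc, "kwd")
}

extract_string_list <- function(doc, tag) {
  doc <- as_jats_document(doc)
  vals <- vapply(extract_fragments(doc, tag), inner_xml, "")
  if (!length(vals)) return(character())
  vals <- stringi::stri_trim_both(convert_letters(strip_tags(vals)))
  vals <- vals[nzchar(vals)]
  vals <- vals[!stringi::stri_detect_regex(vals, "^[[:punct:][:space:]]+$")]
  unique(vals)
}

#' Extract the publication history date stamps
#'
#' Collects every labelled `<date>` inside `<history>` and every
#' `<pub-date>` element. Labels are normalised to the 14-label
#' vocabulary in [HISTORY_LABELS]; unknown labels go to the catch-all
#' `"other"` and are logged. Stamps without a numeric year, or with an
#' out-of-range month or day, are dropped and logged. A duplicated label
#' keeps its first occurrence (logged). Month and day stay `NA` when the
#' file omits them; they are completed to 1 only at comparison time by
#' [compute_pub_date()] and [publication_lags()].
#'
#' @param doc a `jats_document` or XML string.
#' @return A tibble (class `jats_history`) with columns `label`, `year`,
#'   `month`, `day` (integers, `month`/`day` possibly `NA`).
#' @export
#' @examples
#' h <- get_history("<a><history>
#'  <date date-type='received'><day>1</day><month>3</month><year>2010</year></date>
#'  <date date-type='accepted'><day>15</day><month>6</month><year>2010</year></date>
#'  </history><pub-date pub-type='epub'><day>1</day><month>7</month><year>2010</year></pub-date></a>")
#' compute_pub_date(h)
get_history <- function(doc) {
  doc <- as_jats_document(doc)
  dates <- list()
  for (h in extract_fragments(doc, "history")) {
    dates <- c(dates, lapply(extract_fragments(h$raw_xml, "date"), function(f) {
      list(label = f$attributes["date-type"], frag = f)
    }))
  }
  dates <- c(dates, lapply(extract_fragments(doc, "pub-date"), function(f) {
    lbl <- f$attributes["pub-type"] %|na|% f$attributes["date-type"]
    list(label = lbl, frag = f)
  }))

  labels <- character(); years <- integer()
  months <- integer(); days <- integer()
  for (d in dates) {
    lbl <- normalise_label(d$label)
    y <- suppressWarnings(as.integer(first_inner(d$frag$raw_xml, "year")))
    m <- suppressWarnings(as.integer(first_inner(d$frag$raw_xml, "month")))
    dy <- suppressWarnings(as.integer(first_inner(d$frag$raw_xml, "day")))
    if (is.na(y)) {
      log_event("get_history", paste0("stamp '", lbl, "' without year dropped"))
      next
    }
    if ((!is.na(m) && (m < 1 || m > 12)) || (!is.na(dy) && (dy < 1 || dy > 31))) {
      log_event("get_history", paste0("stamp '", lbl, "' with invalid month/day dropped"))
      next
    }
    if (lbl %in% labels && lbl != "other") {
      log_event("get_history", paste0("duplicate stamp '", lbl, "' ignored (first kept)"))
      next
    }
    labels <- c(labels, lbl); years <- c(years, y)
    months <- c(months, m); days <- c(days, dy)
  }
  out <- tibble::tibble(label = labels, year = years, month = months, day = days)
  class(out) <- c("jats_history", class(out))
  out
}

`%|na|%` <- function(a, b) if (length(a) && !is.na(a)) a else b

normalise_label <- function(lbl) {
  if (!length(lbl) || is.na(lbl)) return("other")
  x <- tolower(stringi::stri_trim_both(lbl))
  x <- switch(x,
    "nihms-submitted" = "nihms_submitted",
    "pmc_release" = "pmc-release",
    "rev_recd" = "rev-recd",
    "epub-ppub" = "ppub",
    x
  )
  if (x %in% HISTORY_LABELS) x else {
    log_event("get_history", paste0("unknown date label '", lbl, "' kept as 'other'"))
    "other"
  }
}

# missing month/day complete to 1; invalid calendar dates give NA
completed_date <- function(year, month, day) {
  m <- ifelse(is.na(month), 1L, month)
  d <- ifelse(is.na(day), 1L, day)
  as.Date(sprintf("%04d-%02d-%02d", year, m, d), format = "%Y-%m-%d")
}

#' Unified earliest publication date
#'
#' The publication date is the earliest completed date over the six
#' publication-event stamps (`epub`, `ppub`, `print`, `pub`,
#' `collection`, `pmc-release`) that are present; the publication year is
#' its year. When none of the six is present, the year falls back to the
#' earliest year over all stamps and the date stays `NA`.
#'
#' @param stamps a `jats_history` tibble from [get_history()].
#' @return A list with `pub_date` (`Date` or `NA`) and `pubyear`
#'   (integer or `NA`).
#' @export
compute_pub_date <- function(stamps) {
  stopifnot(is.data.frame(stamps))
  cand <- stamps[stamps$label %in% PUB_EVENT_LABELS, , drop = FALSE]
  if (nrow(cand)) {
    dts <- completed_date(cand$year, cand$month, cand$day)
    dts <- dts[!is.na(dts)]
    if (length(dts)) {
      pd <- min(dts)
      return(list(pub_date = pd, pubyear = as.integer(format(pd, "%Y"))))
    }
  }
  if (nrow(stamps)) {
    return(list(pub_date = as.Date(NA), pubyear = min(stamps$year, na.rm = TRUE)))
  }
  list(pub_date = as.Date(NA), pubyear = NA_integer_)
}

#' Editorial lags in days
#'
#' Time to accept is the accept date minus the receive date; time to
#' publish is the unified publication date minus the accept date, both on
#' month/day-completed dates. Either lag is `NA` when an operand is
#' missing. Negative values are preserved: they are the date-stamp
#' anomaly signal.
#'
#' @param stamps a `jats_history` tibble from [get_history()].
#' @param pub_date the unified publication date (`Date` or `NA`),
#'   typically `compute_pub_date(stamps)$pub_date`.
#' @return A list with integer `time_to_accept` and `time_to_publish`.
#' @export
publication_lags <- function(stamps, pub_date = compute_pub_date(stamps)$pub_date) {
  date_of <- function(lbl) {
    r <- stamps[stamps$label == lbl, , drop = FALSE]
    if (!nrow(r)) return(as.Date(NA))
    completed_date(r$year[1], r$month[1], r$day[1])
  }
  received <- date_of("received")
  accepted <- date_of("accepted")
  tta <- if (!is.na(received) && !is.na(accepted)) {
    as.integer(accepted - received)
  } else NA_integer_
  ttp <- if (!is.na(accepted) && length(pub_date) && !is.na(pub_date)) {
    as.integer(as.Date(pub_date) - accepted)
  } else NA_integer_
  list(time_to_accept = tta, time_to_publish = ttp)
}
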
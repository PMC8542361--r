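# Bibliometric profiling of a decoded corpus: tag-use frequencies over
# publishing periods, label frequency tables, journal productivity bins,
# date-stamp anomaly counts and country co-occurrence.

TAG_USE_ELEMENTS <- c(
  "abstract", "affiliation", "author", "country", "doi", "editor",
  "history", "journal", "keywords", "references", "sections", "subject",
  "text", "title", "type", "volume"
)

# per-record presence of each content element; abstract/text follow the
# 30-character rule, everything else requires non-empty content
presence_matrix <- function(records) {
  n_of <- function(col) vapply(records[[col]], NROW, 1L)
  len_of <- function(col) vapply(records[[col]], length, 1L)
  cbind(
    abstract = records$abstract_present,
    affiliation = n_of("affiliations") > 0,
    author = n_of("authors") > 0,
    country = len_of("countries") > 0,
    doi = !is.na(records$doi),
    editor = n_of("editors") > 0,
    history = n_of("history") > 0,
    journal = !is.na(records$journal),
    keywords = len_of("keywords") > 0,
    references = len_of("references") > 0,
    sections = vapply(records$sections, function(s) any(nzchar(s$title)), NA),
    subject = len_of("subjects") > 0,
    text = records$text_present,
    title = !is.na(records$title),
    type = !is.na(records$type),
    volume = !is.na(records$volume)
  )
}

#' Tag-use frequencies over publishing periods
#'
#' For each content element, the relative frequency of records in which
#' it is present, overall and per publishing-period bin. Bins are
#' right-closed; the first bin is closed on both sides, spanning from the
#' earliest publication year to the first edge. Records without a
#' publication year count in the total column but in no period column.
#'
#' @param records a `jats_corpus` tibble from [decode_collection()].
#' @param period_edges strictly increasing years defining the bin edges.
#' @return A tibble of class `jats_tag_use` with one row per element plus
#'   a final `total_n` row holding the per-column record counts.
#' @export
tag_use_table <- function(records, period_edges = c(2000, 2005, 2010, 2015, 2020)) {
  stopifnot(is.data.frame(records))
  if (length(period_edges) && any(diff(period_edges) <= 0)) {
    stop("period_edges must be strictly increasing", call. = FALSE)
  }
  pres <- presence_matrix(records)
  yr <- records$pubyear
  lo <- suppressWarnings(min(yr, na.rm = TRUE))
  if (!is.finite(lo)) lo <- NA_integer_

  cols <- list(total = rep(TRUE, nrow(records)))
  if (length(period_edges) && !is.na(lo)) {
    lo <- min(lo, period_edges[1])
    labels <- c(
      sprintf("[%d; %d]", lo, period_edges[1]),
      if (length(period_edges) > 1) {
        sprintf("(%d; %d]", period_edges[-length(period_edges)], period_edges[-1])
      }
    )
    bounds <- c(lo - 1L, period_edges)
    for (i in seq_along(labels)) {
      cols[[labels[i]]] <- !is.na(yr) & yr > bounds[i] & yr <= bounds[i + 1]
    }
  }

  out <- tibble::tibble(element = TAG_USE_ELEMENTS)
  for (nm in names(cols)) {
    sel <- cols[[nm]]
    out[[nm]] <- if (any(sel)) {
      unname(round(colMeans(pres[sel, , drop = FALSE]), 4))
    } else {
      rep(NA_real_, length(TAG_USE_ELEMENTS))
    }
  }
  totals <- tibble::tibble(element = "total_n")
  for (nm in names(cols)) totals[[nm]] <- sum(cols[[nm]])
  out <- dplyr::bind_rows(out, totals)
  class(out) <- c("jats_tag_use", class(out))
  out
}

JOURNAL_BIN_EDGES <- c(1, 10, 100, 1000, 1e4, 1e5)
JOURNAL_BIN_LABELS <- c("1", "2-10", "11-100", "101-1000", "1001-10^4",
                        "10^4-10^5", ">10^5")

#' Frequency tables over corpus fields
#'
#' Counts per label for one field of the decoded corpus. For
#' `field = "journal"` with `bins = TRUE`, returns instead the absolute
#' (`h`) and relative (`f`) frequency of journals supplying `n` articles,
#' binned as 1, 2-10, 11-100, 101-1000, 1001-10^4, 10^4-10^5, >10^5.
#'
#' @param records a `jats_corpus` tibble.
#' @param field one of `"type"`, `"journal"`, `"date_label"`,
#'   `"author_name"`, `"editor_name"`, `"subject"`, `"keyword"`,
#'   `"country"`.
#' @param bins journal productivity bins instead of raw counts.
#' @param top_k optionally keep only the `top_k` most frequent labels.
#' @return A tibble: `label`, `n` (counts, ties broken alphabetically),
#'   or `bin`, `h`, `f` for journal bins.
#' @export
frequency_table <- function(records, field = c("type", "journal", "date_label",
                                               "author_name", "editor_name",
                                               "subject", "keyword", "country"),
                            bins = FALSE, top_k = NULL) {
  field <- match.arg(field)
  vals <- switch(field,
    type = records$type,
    journal = records$journal,
    date_label = unlist(lapply(records$history, function(h) h$label)),
    author_name = unlist(lapply(records$authors, format_names)),
    editor_name = unlist(lapply(records$editors, format_names)),
    subject = unlist(records$subjects),
    keyword = unlist(records$keywords),
    country = unlist(records$countries)
  )
  vals <- vals[!is.na(vals)]

  if (bins) {
    if (field != "journal") stop("bins are defined for field = 'journal'", call. = FALSE)
    per_journal <- table(vals)
    idx <- findInterval(as.integer(per_journal), JOURNAL_BIN_EDGES,
                        left.open = TRUE) + 1L
    h <- vapply(seq_along(JOURNAL_BIN_LABELS), function(i) sum(idx == i), 1L)
    return(tibble::tibble(bin = JOURNAL_BIN_LABELS, h = h,
                          f = if (sum(h)) round(h / sum(h), 4) else rep(NA_real_, length(h))))
  }

  tab <- table(vals)
  out <- tibble::tibble(label = names(tab), n = as.integer(tab)) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$label)
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out
}

format_names <- function(people) {
  if (!NROW(people)) return(character())
  ifelse(is.na(people$given), people$surname,
         paste0(people$surname, ", ", people$given))
}

#' Date-stamp anomaly counts
#'
#' Counts records whose accept date precedes their receive date, whose
#' unified publication date precedes their accept date (both on
#' completed dates, counted only when both operands are present), and
#' records carrying any stamp after an explicit reference date (no
#' wall-clock dependence).
#'
#' @param records a `jats_corpus` tibble.
#' @param reference_date the "today" for the future-date check.
#' @return A one-row tibble: `n_accept_before_receive`,
#'   `n_publish_before_accept`, `n_future_dates`.
#' @export
date_anomalies <- function(records, reference_date = as.Date("2021-01-01")) {
  reference_date <- as.Date(reference_date)
  future <- vapply(records$history, function(h) {
    if (!NROW(h)) return(FALSE)
    dts <- completed_date(h$year, h$month, h$day)
    any(dts > reference_date, na.rm = TRUE)
  }, NA)
  tibble::tibble(
    n_accept_before_receive = sum(records$time_to_accept < 0, na.rm = TRUE),
    n_publish_before_accept = sum(records$time_to_publish < 0, na.rm = TRUE),
    n_future_dates = sum(future)
  )
}

#' Country co-occurrence and international share
#'
#' Unordered country-pair counts over records with two or more extracted
#' countries, plus the international share: the fraction of
#' country-bearing records that carry more than one country.
#'
#' @param records a `jats_corpus` tibble.
#' @return A list with `pairs` (tibble `country1`, `country2`, `n`,
#'   with `country1 < country2`) and `international_share` (numeric).
#' @export
country_cooccurrence <- function(records) {
  sets <- records$countries
  lens <- vapply(sets, length, 1L)
  pair_rows <- lapply(sets[lens >= 2], function(cs) {
    cs <- sort(unique(cs))
    cmb <- utils::combn(cs, 2)
    tibble::tibble(country1 = cmb[1, ], country2 = cmb[2, ])
  })
  pairs <- if (length(pair_rows)) {
    dplyr::bind_rows(pair_rows) |>
      dplyr::count(.data$country1, .data$country2, name = "n") |>
      dplyr::arrange(dplyr::desc(.data$n), .data$country1, .data$country2)
  } else {
    tibble::tibble(country1 = character(), country2 = character(), n = integer())
  }
  share <- if (any(lens > 0)) sum(lens >= 2) / sum(lens >= 1) else 0
  list(pairs = pairs, international_share = share)
}

#' Date-type use and time spans
#'
#' Per history label: the share of records carrying the stamp and the
#' earliest/latest completed date observed.
#'
#' @param records a `jats_corpus` tibble.
#' @return A tibble: `label`, `rel_use`, `earliest`, `latest`.
#' @export
date_type_table <- function(records) {
  rows <- purrr::imap(records$history, function(h, i) {
    if (!NROW(h)) return(NULL)
    tibble::tibble(record = i, label = h$label,
                   date = completed_date(h$year, h$month, h$day))
  })
  all <- dplyr::bind_rows(rows)
  if (!nrow(all)) {
    return(tibble::tibble(label = character(), rel_use = numeric(),
                          earliest = as.Date(character()),
                          latest = as.Date(character())))
  }
  all |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      rel_use = round(dplyr::n_distinct(.data$record) / nrow(records), 4),
      earliest = suppressWarnings(min(.data$date, na.rm = TRUE)),
      latest = suppressWarnings(max(.data$date, na.rm = TRUE)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$label)
}

#' Write the profiling tables of a corpus as CSV files
#'
#' Writes `tag_use.csv`, `journal_bins.csv`, `date_types.csv`,
#' `type_counts.csv`, `anomalies.csv` and `country_pairs.csv` with a
#' stable column order.
#'
#' @param records a `jats_corpus` tibble.
#' @param dir output directory (created if needed).
#' @param period_edges passed to [tag_use_table()].
#' @param reference_date passed to [date_anomalies()].
#' @param top_k rows kept in the type-count table.
#' @return The directory, invisibly.
#' @export
write_profile <- function(records, dir,
                          period_edges = c(2000, 2005, 2010, 2015, 2020),
                          reference_date = as.Date("2021-01-01"),
                          top_k = 250) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  w(tag_use_table(records, period_edges), "tag_use.csv")
  w(frequency_table(records, "journal", bins = TRUE), "journal_bins.csv")
  w(date_type_table(records), "date_types.csv")
  w(frequency_table(records, "type", top_k = top_k), "type_counts.csv")
  w(date_anomalies(records, reference_date), "anomalies.csv")
  w(country_cooccurrence(records)$pairs, "country_pairs.csv")
  invisible(dir)
}
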
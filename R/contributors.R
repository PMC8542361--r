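# Contributor extraction: author/editor names with identifiers,
# affiliation strings and unified country names.

#' Extract author or editor names
#'
#' Names come from `<contrib>` elements in document order. Fully
#' capitalised name parts (a common journal style) are recased to an
#' initial capital per token, Unicode-aware, preserving hyphenated parts;
#' mixed-case input is never touched, so "McDonald" survives. Contributor
#' identifiers are harvested from `contrib-id` elements/attributes with
#' scheme detection (`orcid`, `sciprofiles`, `zoobank`, `twitter`, ...);
#' a bare 16-digit ORCID form is recognised as a fallback. A contributor
#' with neither surname nor given name is skipped and logged.
#'
#' @param doc a `jats_document` or XML string.
#' @param role `"author"` or `"editor"`.
#' @param shorten_given if `TRUE`, given names reduce to one-letter
#'   abbreviations per space/hyphen-separated token ("Wei" -> "W.").
#' @return A tibble with columns `surname`, `given`, `role` and `ids`
#'   (list column of tibbles with `scheme`, `value`).
#' @export
#' @examples
#' x <- "<a><contrib-group><contrib contrib-type='author'>
#'   <name><surname>WANG</surname><given-names>WEI</given-names></name>
#'   </contrib></contrib-group></a>"
#' get_contributors(x)$surname
get_contributors <- function(doc, role = c("author", "editor"),
                             shorten_given = FALSE) {
  role <- match.arg(role)
  doc <- as_jats_document(doc)
  contribs <- extract_fragments(doc, "contrib")
  keep <- vapply(contribs, function(f) {
    ct <- unname(f$attributes["contrib-type"])
    if (is.na(ct)) role == "author" else identical(ct, role)
  }, logical(1))
  contribs <- contribs[keep]

  surnames <- character()
  givens <- character()
  ids <- list()
  for (f in contribs) {
    surname <- clean_value(first_inner(f$raw_xml, "surname"))
    given <- clean_value(first_inner(f$raw_xml, "given-names"))
    if (is.na(given)) given <- clean_value(first_inner(f$raw_xml, "given-name"))
    if (is.na(surname) && is.na(given)) {
      nm <- clean_value(first_inner(f$raw_xml, "name")) %|na|%
        clean_value(first_inner(f$raw_xml, "string-name"))
      if (!is.na(nm)) surname <- nm
    }
    if (is.na(surname) && is.na(given)) {
      log_event("get_contributors", "contributor without any name skipped")
      next
    }
    surnames <- c(surnames, recase_allcaps(surname))
    givens <- c(givens, recase_allcaps(given))
    ids <- c(ids, list(contrib_ids(f$raw_xml)))
  }
  out <- tibble::tibble(
    surname = surnames, given = givens,
    role = rep(role, length(surnames)), ids = ids
  )
  if (shorten_given) out$given <- shorten_given_names(out$given)
  out
}

# strictly all-caps alphabetic tokens of length >= 2 get an initial
# capital; everything else passes through
recase_allcaps <- function(x) {
  if (!length(x) || is.na(x)) return(NA_character_)
  recase_token <- function(tok) {
    if (stringi::stri_detect_regex(tok, "^\\p{Lu}{2,}$")) {
      paste0(stringi::stri_sub(tok, 1, 1),
             stringi::stri_trans_tolower(stringi::stri_sub(tok, 2)))
    } else tok
  }
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    parts <- stringi::stri_split_regex(s, "(?<=[ \\-])|(?=[ \\-])")[[1]]
    paste(vapply(parts, recase_token, ""), collapse = "")
  }, "", USE.NAMES = FALSE)
}

shorten_given_names <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    toks <- stringi::stri_split_regex(s, "[ \\-]+")[[1]]
    toks <- toks[nzchar(toks)]
    paste(paste0(stringi::stri_sub(toks, 1, 1), "."), collapse = " ")
  }, "", USE.NAMES = FALSE)
}

contrib_ids <- function(raw) {
  ids <- extract_fragments(raw, "contrib-id")
  values <- character(length(ids))
  schemes <- character(length(ids))
  for (i in seq_along(ids)) {
    f <- ids[[i]]
    values[i] <- stringi::stri_trim_both(strip_tags(inner_xml(f)))
    scheme <- tolower(unname(f$attributes["contrib-id-type"]) %|na|% "")
    if (!nzchar(scheme)) {
      scheme <- if (stringi::stri_detect_regex(
        values[i], "(\\d{4}-){3}\\d{3}[0-9X]")) "orcid" else "unknown"
    }
    schemes[i] <- scheme
  }
  tibble::tibble(scheme = schemes, value = values)
}

#' Extract affiliation strings
#'
#' One entry per `<aff>` element: label markers (superscript numbers or
#' letters) are stripped, markup is removed, and tagged parts
#' (institution, address line, country, ...) are joined with `", "` in
#' document order; an untagged one-line affiliation passes through with
#' cleanup only. Countries are recognised with [get_countries()].
#'
#' @param doc a `jats_document` or XML string.
#' @return A tibble with columns `text` and `countries` (list column).
#' @export
#' @examples
#' get_affiliations("<a><aff><institution>Institute of Psychology</institution>,
#'  <addr-line>Hamburg</addr-line>, <country>Germany</country></aff></a>")
get_affiliations <- function(doc) {
  doc <- as_jats_document(doc)
  affs <- extract_fragments(doc, "aff")
  texts <- character(length(affs))
  countries <- vector("list", length(affs))
  for (i in seq_along(affs)) {
    f <- affs[[i]]
    inner <- inner_xml(f)
    inner <- stringi::stri_replace_all_regex(
      inner, "(?s)<(label|sup)\\b[^>]*>.*?</\\1\\s*>", ""
    )
    inner <- strip_formatting_tags(inner)
    # remaining structural tags delimit the comma-separated specifications
    segs <- stringi::stri_split_regex(inner, "(?s)<[^>]*>")[[1]]
    segs <- stringi::stri_trim_both(convert_letters(segs))
    segs <- stringi::stri_replace_all_regex(segs, "^[,;]+|[,;]+$", "")
    segs <- stringi::stri_trim_both(segs)
    segs <- segs[nzchar(segs)]
    texts[i] <- paste(segs, collapse = ", ")
    explicit <- vapply(extract_fragments(f$raw_xml, "country"),
                       function(cf) clean_value(inner_xml(cf)), "")
    countries[[i]] <- unify_countries(explicit, texts[i])
  }
  tibble::tibble(text = texts, countries = countries)
}

load_country_tables <- function() {
  if (!is.null(the$countries)) return(the$countries)
  canon <- utils::read.delim(
    system.file("extdata", "countries.tsv", package = "jatsr", mustWork = TRUE),
    stringsAsFactors = FALSE
  )$name
  ali <- utils::read.delim(
    system.file("extdata", "country_aliases.tsv", package = "jatsr", mustWork = TRUE),
    stringsAsFactors = FALSE
  )
  lookup <- c(stats::setNames(canon, tolower(canon)),
              stats::setNames(ali$canonical, tolower(ali$alias)))
  # longer names first so "Papua New Guinea" wins over "Guinea"
  lookup <- lookup[order(-nchar(names(lookup)))]
  the$countries <- list(canon = canon, lookup = lookup)
  the$countries
}

# map explicit country-tag content or an end-anchored dictionary match to
# canonical names
unify_countries <- function(explicit, text) {
  tab <- load_country_tables()
  out <- character()
  explicit <- explicit[!is.na(explicit) & nzchar(explicit)]
  if (length(explicit)) {
    for (e in explicit) {
      hit <- match_country(e, tab, anchored = FALSE)
      out <- c(out, if (is.na(hit)) character() else hit)
    }
  } else if (length(text) && nzchar(text)) {
    hit <- match_country(text, tab, anchored = TRUE)
    if (!is.na(hit)) out <- hit
  }
  sort(unique(out))
}

match_country <- function(x, tab, anchored) {
  # trailing addresses, postal codes, e-mail suffixes never carry the name
  x <- stringi::stri_replace_all_regex(
    x, "(?i)\\be-?mail\\s*:?\\s*\\S+$", ""
  )
  x <- stringi::stri_replace_all_regex(x, "[^\\p{L}]+$", "")
  lx <- tolower(x)
  for (i in seq_along(tab$lookup)) {
    nm <- names(tab$lookup)[i]
    if (anchored) {
      if (stringi::stri_endswith_fixed(lx, nm)) {
        pre <- stringi::stri_sub(lx, 1, nchar(lx) - nchar(nm))
        if (!nzchar(pre) ||
            stringi::stri_detect_regex(pre, "[^\\p{L}]$")) {
          return(unname(tab$lookup[i]))
        }
      }
    } else if (lx == nm) {
      return(unname(tab$lookup[i]))
    }
  }
  if (!anchored) {
    # explicit tags sometimes carry decorations: fall back to end match
    return(match_country(x, tab, anchored = TRUE))
  }
  NA_character_
}

#' Unified country names for a set of affiliations
#'
#' Explicit `<country>` tag content is preferred; otherwise a dictionary
#' search anchored at the end of each affiliation string is performed.
#' Aliases ("Peoples Rep. of China", "UNITED STATES", "UK") unify to
#' canonical names. Mid-string tokens never match, so "Georgia Institute
#' of Technology, Atlanta" yields no country.
#'
#' @param affiliations tibble from [get_affiliations()], or a character
#'   vector of affiliation strings.
#' @param country_tags optional character vector of explicit country-tag
#'   values to prefer over dictionary search.
#' @return Sorted unique character vector of canonical country names
#'   (possibly empty).
#' @export
#' @examples
#' get_countries("Institute of Psychology, University Hamburg, Germany")
#' get_countries("Georgia Institute of Technology, Atlanta")
get_countries <- function(affiliations, country_tags = character()) {
  country_tags <- country_tags[!is.na(country_tags) & nzchar(country_tags)]
  if (length(country_tags)) {
    return(unify_countries(country_tags, character()))
  }
  if (is.data.frame(affiliations)) {
    return(sort(unique(unlist(affiliations$countries))))
  }
  out <- unlist(lapply(affiliations, function(a) unify_countries(character(), a)))
  sort(unique(out))
}
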
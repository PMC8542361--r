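# Synthetic JATS fixture generation with exact ground truth.
#
# Every generated file comes with the record its canonical decode must
# produce. Quirks change only the surface encoding (entity styles,
# all-caps names, alternative space codings, untagged affiliations,
# nested subjects, formula markup, duplicate or reversed date stamps),
# never the ground-truth semantics, except where the quirk IS the
# semantics (reversed dates set the anomaly flags).

#' Dialect quirks the fixture forge can apply
#'
#' Surface-encoding variants (entity styles, all-caps names, alternative
#' space codings, untagged affiliations, nested subjects, formula markup,
#' duplicate date labels, missing month/day precision, subsectioned
#' bodies) plus the three date-anomaly plantings (reversed
#' accept/receive, publish before accept, future date), which also set
#' the ground-truth anomaly flags.
#' @export
FORGE_QUIRKS <- c(
  "hex_entities", "decimal_entities", "named_entities", "allcaps_names",
  "untagged_affiliation", "missing_month_day", "alt_space_codings",
  "nested_subjects", "inline_formula_image", "mathml_formula",
  "duplicate_date_label", "reversed_accept_receive", "publish_before_accept",
  "future_date", "subsectioned_body"
)

pools <- list(
  journal = c("PLoS ONE", "Scientific Reports", "BMC Genomics",
              "Journal of Cell Biology", "Frontiers in Psychology",
              "The Lancet Microbe", "eLife", "Nature Communications"),
  type = c("research-article", "research-article", "research-article",
           "review-article", "case-report", "editorial", "correction"),
  surname = c("Wang", "Smith", "Chen", "Müller", "Garcia", "Kim", "Li",
              "Johnson", "Okafor", "Silva", "Nakamura", "Kowalski"),
  given = c("Wei", "Anna", "José", "Ming", "Maria", "John", "Yuki",
            "Pavel", "Aisha", "Lars", "Jean-Luc", "Sofia"),
  institution = c("Institute of Psychology", "Department of Biology",
                  "School of Medicine", "Center for Genomics",
                  "Institute of Public Health", "Department of Statistics"),
  city = c("Hamburg", "Boston", "Beijing", "Oxford", "Seoul", "Kyoto",
           "Lagos", "Warsaw", "Toronto", "Melbourne"),
  country = c("Germany", "United States", "China", "United Kingdom",
              "South Korea", "Japan", "Brazil", "France", "Italy",
              "Netherlands", "Canada", "Australia"),
  subject = c("Biology", "Genetics", "Psychology", "Epidemiology",
              "Research Article", "Microbiology", "Neuroscience"),
  keyword = c("Covid-19", "SARS-Cov-2", "meta-analysis", "replication",
              "gene expression", "cohort study", "machine learning",
              "public health", "α-diversity", "biomarkers"),
  opener = c("The", "This", "Our", "A further", "An additional"),
  noun = c("model", "cohort", "assay", "trial", "analysis", "dataset",
           "protocol", "sample", "pipeline", "survey"),
  verb = c("reveals", "predicts", "confirms", "suggests", "captures",
           "quantifies", "supports", "clarifies"),
  adj = c("robust", "significant", "modest", "consistent", "unexpected",
          "heterogeneous", "stable"),
  obj = c("variation", "effects", "associations", "differences",
          "patterns", "trends"),
  tail = c("in the study population", "across replicates",
           "under both conditions", "at follow-up", "between groups",
           "over time")
)

rs <- function(pool, n = 1) sample(pool, n, replace = n > length(pool))

make_sentence <- function() {
  paste0(rs(pools$opener), " ", rs(pools$noun), " ", rs(pools$verb), " ",
         rs(pools$adj), " ", rs(pools$obj), " ", rs(pools$tail), ".")
}

make_text <- function(k) paste(replicate(k, make_sentence()), collapse = " ")

#' Describe one synthetic fixture
#'
#' Configuration for [generate_article()]. Content is drawn
#' deterministically from `seed`; explicit `fields` override the draw;
#' `quirks` toggle surface-encoding variants (and the date-anomaly
#' plantings, which also set the ground-truth anomaly flags).
#'
#' @param seed integer; same spec and seed give byte-identical XML.
#' @param quirks subset of `FORGE_QUIRKS`.
#' @param with_abstract,with_keywords,with_editor,with_volume,with_body,with_references,with_orcid,with_country
#'   plant (or omit) the respective field.
#' @param n_countries 1 for a national, 2+ for an international record.
#' @param fields named list of explicit values (`title`, `journal`,
#'   `doi`, `type`, `volume`, `surname`, `given`, ...) overriding the
#'   random draw.
#' @param country_tagged force (`TRUE`) or forbid (`FALSE`) an explicit
#'   `<country>` tag; `NA` resolves from the quirks. Forcing it together
#'   with the `untagged_affiliation` quirk is contradictory and errors.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, quirks = character(),
                         with_abstract = TRUE, with_keywords = TRUE,
                         with_editor = FALSE, with_volume = TRUE,
                         with_body = TRUE, with_references = TRUE,
                         with_orcid = FALSE, with_country = TRUE,
                         n_countries = 1L, fields = list(),
                         country_tagged = NA) {
  bad <- setdiff(quirks, FORGE_QUIRKS)
  if (length(bad)) stop("unknown quirks: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(
    list(seed = as.integer(seed), quirks = quirks,
         with_abstract = with_abstract, with_keywords = with_keywords,
         with_editor = with_editor, with_volume = with_volume,
         with_body = with_body, with_references = with_references,
         with_orcid = with_orcid, with_country = with_country,
         n_countries = as.integer(n_countries), fields = fields,
         country_tagged = country_tagged),
    class = "fixture_spec"
  )
}

# surface encoding of one text node: XML escaping, then the requested
# entity style for non-ASCII characters
tnode <- function(x, quirks, spaces = FALSE) {
  x <- stringi::stri_replace_all_fixed(x, c("&", "<", ">"),
                                       c("&amp;", "&lt;", "&gt;"),
                                       vectorize_all = FALSE)
  if (spaces && "alt_space_codings" %in% quirks) {
    alt <- c("\u00a0", "\u2002", "\u2003", "\u2009", "\u3000")
    pieces <- stringi::stri_split_fixed(x, " ")[[1]]
    if (length(pieces) > 1) {
      seps <- sample(alt, length(pieces) - 1, replace = TRUE)
      x <- paste0(pieces, c(seps, ""), collapse = "")
    }
  }
  chars <- unique(stringi::stri_extract_all_regex(x, "[^\\x01-\\x7F]")[[1]])
  chars <- chars[!is.na(chars)]
  if (!length(chars)) return(x)
  repl <- if ("hex_entities" %in% quirks) {
    sprintf("&#x%X;", vapply(chars, utf8ToInt, 1L))
  } else if ("decimal_entities" %in% quirks) {
    sprintf("&#%d;", vapply(chars, utf8ToInt, 1L))
  } else if ("named_entities" %in% quirks) {
    tab <- load_tables()$entities
    rev_tab <- stats::setNames(paste0("&", names(tab), ";"), tab)
    out <- rev_tab[chars]
    ifelse(is.na(out), sprintf("&#x%X;", vapply(chars, utf8ToInt, 1L)), out)
  } else {
    return(x)
  }
  stringi::stri_replace_all_fixed(x, chars, repl, vectorize_all = FALSE)
}

date_xml <- function(label, y, m, d, element = "date") {
  attr_name <- if (element == "date") "date-type" else "pub-type"
  paste0("<", element, " ", attr_name, "=\"", label, "\">",
         if (!is.na(d)) paste0("<day>", d, "</day>") else "",
         if (!is.na(m)) paste0("<month>", m, "</month>") else "",
         "<year>", y, "</year></", element, ">")
}

empty_people <- function() {
  tibble::tibble(surname = character(), given = character(),
                 role = character(), ids = list())
}

#' Generate one synthetic JATS article with ground truth
#'
#' @param spec a [fixture_spec()].
#' @return A list with `xml` (the article as one string) and `truth`
#'   (the exact record [decode_article()] must produce, plus an
#'   `anomalies` list with `reversed_accept_receive`,
#'   `publish_before_accept`, `future_date` and `image_formula` flags).
#' @export
#' @examples
#' fx <- generate_article(fixture_spec(seed = 7, quirks = "hex_entities"))
#' decode_article(fx$xml)$title == fx$truth$title
generate_article <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  q <- spec$quirks
  untagged <- "untagged_affiliation" %in% q
  if (untagged && isTRUE(spec$country_tagged)) {
    stop("contradictory quirks: untagged_affiliation with a structured country tag",
         call. = FALSE)
  }
  country_tagged <- if (is.na(spec$country_tagged)) !untagged else spec$country_tagged

  withr::with_seed(spec$seed, generate_article_impl(spec, q, untagged, country_tagged))
}

generate_article_impl <- function(spec, q, untagged, country_tagged) {
  fld <- spec$fields
  pick <- function(nm, default) fld[[nm]] %||% default

  greekish <- sample(c("α", "β", ""), 1)
  title <- pick("title", fix_spacing(paste(
    "Assessing", if (nzchar(greekish)) paste0(greekish, "-level") else "baseline",
    rs(pools$noun), "effects in", rs(pools$obj),
    "of the", rs(pools$noun)
  )))
  journal <- pick("journal", rs(pools$journal))
  doi <- pick("doi", sprintf("10.%d/jats.%d.%05d",
                             sample(1000:9999, 1), sample(2001:2020, 1),
                             sample(1:99999, 1)))
  type <- pick("type", rs(pools$type))
  volume <- if (spec$with_volume) pick("volume", as.character(sample(1:40, 1))) else NA_character_
  subjects <- pick("subjects", rs(pools$subject, sample(1:3, 1)))
  keywords <- if (spec$with_keywords) pick("keywords", rs(pools$keyword, sample(2:4, 1))) else character()

  n_auth <- pick("n_authors", sample(2:4, 1))
  authors <- tibble::tibble(
    surname = pick("surname", rs(pools$surname, n_auth)),
    given = pick("given", rs(pools$given, n_auth)),
    role = "author",
    ids = lapply(seq_len(n_auth), function(i) {
      if (spec$with_orcid && i == 1) {
        tibble::tibble(scheme = "orcid",
                       value = sprintf("0000-000%d-%04d-%03dX",
                                       sample(1:9, 1), sample(0:9999, 1),
                                       sample(0:999, 1)))
      } else {
        tibble::tibble(scheme = character(), value = character())
      }
    })
  )
  editors <- if (spec$with_editor) {
    tibble::tibble(surname = rs(pools$surname), given = rs(pools$given),
                   role = "editor",
                   ids = list(tibble::tibble(scheme = character(),
                                             value = character())))
  } else empty_people()

  n_aff <- max(1L, spec$n_countries)
  aff_countries <- if (spec$with_country) rs(pools$country, n_aff) else rep(NA_character_, n_aff)
  if (spec$with_country && n_aff > 1) {
    while (anyDuplicated(aff_countries)) aff_countries <- rs(pools$country, n_aff)
  }
  aff_parts <- lapply(seq_len(n_aff), function(i) {
    c(rs(pools$institution), rs(pools$city),
      if (!is.na(aff_countries[i])) aff_countries[i])
  })
  affiliations <- tibble::tibble(
    text = vapply(aff_parts, paste, "", collapse = ", "),
    countries = lapply(aff_countries, function(cc) {
      if (is.na(cc)) character() else cc
    })
  )
  countries <- sort(unique(aff_countries[!is.na(aff_countries)]))

  # --- publication history -------------------------------------------------
  received <- as.Date("2009-01-01") + sample(0:3650, 1)
  accepted <- received + sample(30:200, 1)
  if ("reversed_accept_receive" %in% q) accepted <- received - sample(30:90, 1)
  epub <- accepted + sample(10:100, 1)
  if ("publish_before_accept" %in% q) epub <- accepted - sample(10:60, 1)

  ymd <- function(d) list(y = as.integer(format(d, "%Y")),
                          m = as.integer(format(d, "%m")),
                          d = as.integer(format(d, "%d")))
  r <- ymd(received); a <- ymd(accepted); e <- ymd(epub)
  stamps <- tibble::tibble(
    label = c("received", "accepted", "epub"),
    year = c(r$y, a$y, e$y),
    month = c(r$m, a$m, e$m),
    day = c(r$d, a$d, e$d)
  )
  if ("missing_month_day" %in% q) {
    stamps <- dplyr::bind_rows(stamps, tibble::tibble(
      label = "ppub", year = e$y + 1L, month = NA_integer_, day = NA_integer_))
  }
  if ("future_date" %in% q) {
    stamps <- dplyr::bind_rows(stamps, tibble::tibble(
      label = "pmc-release", year = 2100L, month = 1L, day = 14L))
  }
  class(stamps) <- c("jats_history", class(stamps))

  pub <- compute_pub_date_rule(stamps)
  tta <- as.integer(accepted - received)
  ttp <- as.integer(pub$pub_date - accepted)

  # --- text parts ----------------------------------------------------------
  abstract <- if (spec$with_abstract) pick("abstract", make_text(sample(2:4, 1))) else NA_character_
  sec_specs <- if (spec$with_body) {
    base <- list(
      list(title = "Introduction", text = make_text(2)),
      list(title = "Method", text = make_text(2)),
      list(title = "Results", text = make_text(2)),
      list(title = "Discussion", text = make_text(2))
    )
    if ("subsectioned_body" %in% q) {
      base <- append(base, list(
        list(title = "Participants", text = make_text(1), parent = "Method"),
        list(title = "Measures", text = make_text(1), parent = "Method")
      ), after = 2)
    }
    base
  } else list()

  formula_truth <- NULL
  if (spec$with_body && "mathml_formula" %in% q) formula_truth <- "p<0.05"
  image_formula <- spec$with_body && "inline_formula_image" %in% q

  sections <- if (length(sec_specs)) {
    tibble::tibble(
      title = vapply(sec_specs, `[[`, "", "title"),
      text = vapply(sec_specs, `[[`, "", "text")
    )
  } else tibble::tibble(title = character(), text = character())
  if (!is.null(formula_truth)) {
    i <- which(sections$title == "Results")[1]
    sections$text[i] <- paste(sections$text[i], formula_truth,
                              make_sentence())
  }

  references <- if (spec$with_references) {
    vapply(seq_len(sample(3:6, 1)), function(i) {
      fix_spacing(sprintf("%s, %s. (%d). %s %s %s. %s, %d, %d-%d.",
              rs(pools$surname), substr(rs(pools$given), 1, 1),
              sample(1990:2020, 1), rs(pools$opener), rs(pools$noun),
              rs(pools$obj), rs(pools$journal), sample(1:40, 1),
              sample(1:400, 1), sample(401:800, 1)))
    }, "")
  } else character()

  truth <- list(
    source = NA_character_,
    title = title, journal = journal, doi = doi, type = type,
    volume = volume, subjects = subjects, keywords = keywords,
    authors = authors, editors = editors, affiliations = affiliations,
    countries = countries, history = stamps,
    pub_date = pub$pub_date, pubyear = pub$pubyear,
    time_to_accept = tta, time_to_publish = ttp,
    abstract = abstract,
    abstract_present = !is.na(abstract) && nchar(abstract) >= 30,
    sections = sections,
    text_present = nchar(paste(sections$text, collapse = " ")) >= 30,
    references = references,
    anomalies = list(
      reversed_accept_receive = "reversed_accept_receive" %in% q,
      publish_before_accept = "publish_before_accept" %in% q,
      future_date = "future_date" %in% q,
      image_formula = image_formula
    )
  )

  xml <- build_xml(spec, q, untagged, country_tagged, truth, aff_parts,
                   aff_countries, sec_specs, formula_truth, image_formula)
  list(xml = xml, truth = truth)
}

# the earliest-date rule, restated for ground-truth construction
compute_pub_date_rule <- function(stamps) {
  cand <- stamps[stamps$label %in% PUB_EVENT_LABELS, ]
  dts <- as.Date(sprintf("%04d-%02d-%02d", cand$year,
                         ifelse(is.na(cand$month), 1L, cand$month),
                         ifelse(is.na(cand$day), 1L, cand$day)))
  dts <- dts[!is.na(dts)]
  if (length(dts)) {
    pd <- min(dts)
    list(pub_date = pd, pubyear = as.integer(format(pd, "%Y")))
  } else if (nrow(stamps)) {
    list(pub_date = as.Date(NA), pubyear = min(stamps$year))
  } else {
    list(pub_date = as.Date(NA), pubyear = NA_integer_)
  }
}

build_xml <- function(spec, q, untagged, country_tagged, truth, aff_parts,
                      aff_countries, sec_specs, formula_truth, image_formula) {
  t_ <- function(x, spaces = FALSE) tnode(x, q, spaces = spaces)
  caps <- function(x) {
    if ("allcaps_names" %in% q) stringi::stri_trans_toupper(x) else x
  }

  contrib <- function(p, i, role) {
    ids <- p$ids[[i]]
    paste0(
      "<contrib contrib-type=\"", role, "\">",
      if (nrow(ids)) paste0("<contrib-id contrib-id-type=\"", ids$scheme,
                            "\">", ids$value, "</contrib-id>", collapse = ""),
      "<name><surname>", t_(caps(p$surname[i])), "</surname>",
      "<given-names>", t_(caps(p$given[i])), "</given-names></name>",
      "</contrib>"
    )
  }
  contribs <- paste0(
    "<contrib-group>",
    paste(vapply(seq_len(nrow(truth$authors)),
                 function(i) contrib(truth$authors, i, "author"), ""),
          collapse = ""),
    "</contrib-group>",
    if (nrow(truth$editors)) paste0(
      "<contrib-group content-type=\"editors\">",
      paste(vapply(seq_len(nrow(truth$editors)),
                   function(i) contrib(truth$editors, i, "editor"), ""),
            collapse = ""),
      "</contrib-group>"
    ) else ""
  )

  affs <- paste(vapply(seq_along(aff_parts), function(i) {
    parts <- aff_parts[[i]]
    if (untagged || !country_tagged) {
      paste0("<aff id=\"aff", i, "\">", t_(paste(parts, collapse = ", ")), "</aff>")
    } else {
      has_country <- !is.na(aff_countries[i])
      n <- length(parts)
      paste0("<aff id=\"aff", i, "\"><label>", i, "</label>",
             "<institution>", t_(parts[1]), "</institution>",
             "<addr-line>", t_(parts[2]), "</addr-line>",
             if (has_country) paste0("<country>", t_(parts[n]), "</country>") else "",
             "</aff>")
    }
  }, ""), collapse = "")

  subj <- if ("nested_subjects" %in% q && length(truth$subjects) > 1) {
    nest <- ""
    for (s in rev(truth$subjects)) {
      nest <- paste0("<subject>", t_(s), "</subject>",
                     if (nzchar(nest)) paste0("<subj-group>", nest, "</subj-group>") else "")
    }
    paste0("<article-categories><subj-group>", nest,
           "</subj-group></article-categories>")
  } else {
    paste0("<article-categories><subj-group>",
           paste0("<subject>", vapply(truth$subjects, t_, ""), "</subject>",
                  collapse = ""),
           "</subj-group></article-categories>")
  }

  h <- truth$history
  pub_labels <- h$label %in% PUB_EVENT_LABELS
  hist_dates <- paste(vapply(which(!pub_labels), function(i) {
    date_xml(h$label[i], h$year[i], h$month[i], h$day[i])
  }, ""), collapse = "")
  if ("duplicate_date_label" %in% q) {
    hist_dates <- paste0(hist_dates,
                         date_xml("received", h$year[h$label == "received"] + 1L, 1L, 1L))
  }
  pub_dates <- paste(vapply(which(pub_labels), function(i) {
    date_xml(h$label[i], h$year[i], h$month[i], h$day[i], element = "pub-date")
  }, ""), collapse = "")

  kwd <- if (length(truth$keywords)) {
    paste0("<kwd-group>",
           paste0("<kwd>", vapply(truth$keywords, t_, ""), "</kwd>",
                  collapse = ""),
           "</kwd-group>")
  } else ""

  abstract <- if (!is.na(truth$abstract)) {
    paste0("<abstract><p>", t_(truth$abstract, spaces = TRUE), "</p></abstract>")
  } else ""

  sec_xml <- function(s) {
    body_text <- s$text
    extra <- ""
    if (identical(s$title, "Results")) {
      if (!is.null(formula_truth)) {
        truth_text <- truth$sections$text[match(s$title, truth$sections$title)]
        parts <- stringi::stri_split_fixed(truth_text,
                                           paste0(" ", formula_truth, " "))[[1]]
        body_text <- NULL
        extra <- paste0(
          "<p>", t_(parts[1]),
          " <inline-formula><mml:math><mml:mi>p</mml:mi>",
          "<mml:mo>&#x3C;</mml:mo><mml:mn>0.05</mml:mn></mml:math>",
          "</inline-formula> ", t_(parts[2]), "</p>"
        )
      } else if (image_formula) {
        extra <- paste0(
          "<p>", t_(s$text),
          " <inline-formula><inline-graphic xlink:href=\"f1.gif\"/>",
          "</inline-formula></p>"
        )
        body_text <- NULL
      }
    }
    paste0("<sec><title>", t_(s$title), "</title>",
           if (!is.null(body_text)) paste0("<p>", t_(body_text), "</p>"),
           extra, "%CHILDREN%</sec>")
  }

  body <- if (length(sec_specs)) {
    tops <- Filter(function(s) is.null(s$parent), sec_specs)
    xml_secs <- vapply(tops, function(s) {
      children <- Filter(function(c) identical(c$parent, s$title), sec_specs)
      child_xml <- paste(vapply(children, function(c) {
        sub("%CHILDREN%", "", sec_xml(c), fixed = TRUE)
      }, ""), collapse = "")
      sub("%CHILDREN%", child_xml, sec_xml(s), fixed = TRUE)
    }, "")
    paste0("<body>", paste(xml_secs, collapse = ""), "</body>")
  } else ""

  back <- if (length(truth$references)) {
    paste0("<back><ref-list>",
           paste0("<ref id=\"B", seq_along(truth$references), "\">",
                  "<mixed-citation>", vapply(truth$references, t_, ""),
                  "</mixed-citation></ref>", collapse = ""),
           "</ref-list></back>")
  } else ""

  paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<!DOCTYPE article PUBLIC \"-//NLM//DTD JATS (Z39.96) Journal Archiving DTD v1.2\" \"JATS-archivearticle1.dtd\">\n",
    "<article xmlns:mml=\"http://www.w3.org/1998/Math/MathML\" ",
    "xmlns:xlink=\"http://www.w3.org/1999/xlink\" article-type=\"",
    truth$type, "\">",
    "<front><journal-meta><journal-title-group><journal-title>",
    t_(truth$journal), "</journal-title></journal-title-group></journal-meta>",
    "<article-meta>",
    "<article-id pub-id-type=\"doi\">", truth$doi, "</article-id>",
    subj,
    "<title-group><article-title>", t_(truth$title, spaces = TRUE),
    "</article-title></title-group>",
    contribs, affs, pub_dates,
    if (!is.na(truth$volume)) paste0("<volume>", truth$volume, "</volume>") else "",
    "<history>", hist_dates, "</history>",
    kwd, abstract,
    "</article-meta></front>",
    body, back, "</article>"
  )
}

#' Default feature prevalences for a forged corpus
#'
#' Shares of records carrying each plantable feature, chosen to resemble
#' a recent open-access corpus (abstracts and body text nearly
#' omnipresent, editors rare, about a third of country-bearing records
#' international). Anomaly plantings default to a small handful so the
#' profiler has something to count.
#'
#' @return Named list of prevalences in `[0, 1]`.
#' @export
default_prevalence <- function() {
  list(
    abstract = 0.9, keywords = 0.6, editor = 0.15, volume = 0.5,
    body = 0.9, references = 0.9, orcid = 0.3, country = 0.95,
    multi_country = 0.3,
    reversed_accept_receive = 0.02, publish_before_accept = 0.02,
    future_date = 0.01
  )
}

quirk_prevalence <- function(profile = c("default", "messy", "clean")) {
  profile <- match.arg(profile)
  switch(profile,
    clean = stats::setNames(numeric(0), character(0)),
    default = c(hex_entities = 0.3, decimal_entities = 0.1,
                named_entities = 0.1, allcaps_names = 0.2,
                untagged_affiliation = 0.25, missing_month_day = 0.2,
                alt_space_codings = 0.15, nested_subjects = 0.2,
                inline_formula_image = 0.05, mathml_formula = 0.15,
                duplicate_date_label = 0.05, subsectioned_body = 0.25),
    messy = c(hex_entities = 0.5, decimal_entities = 0.2,
              named_entities = 0.2, allcaps_names = 0.5,
              untagged_affiliation = 0.5, missing_month_day = 0.4,
              alt_space_codings = 0.4, nested_subjects = 0.4,
              inline_formula_image = 0.15, mathml_formula = 0.3,
              duplicate_date_label = 0.15, subsectioned_body = 0.5)
  )
}

# deterministic allocation: round(n * p) records get the feature; the
# rotating offset decorrelates features without any sampling
allocate <- function(n, p, rank) {
  k <- round(n * p)
  if (k <= 0) return(logical(n))
  idx <- ((seq_len(k) - 1L + (rank - 1L) * 7L) %% n) + 1L
  seq_len(n) %in% idx
}

#' Generate a corpus of synthetic JATS files with a truth manifest
#'
#' Writes `n` article files plus `manifest.ndjson` (one ground-truth
#' record per line). Feature prevalences are realised by deterministic
#' allocation -- exactly `round(n * p)` records carry each feature -- so
#' profiler tests are exact, with no sampling error. Same seed, same
#' directory contents.
#'
#' @param n number of articles (>= 1).
#' @param dir output directory (created if needed).
#' @param seed integer seed driving all content draws.
#' @param prevalence named list as [default_prevalence()]; values in
#'   `[0, 1]`.
#' @param quirk_profile `"default"`, `"messy"` or `"clean"` surface-quirk
#'   mix.
#' @return Invisibly, the truth manifest as a tibble (one row per file,
#'   same columns as [decode_collection()] plus the anomaly flags).
#' @export
generate_corpus <- function(n, dir, seed = 1L,
                            prevalence = default_prevalence(),
                            quirk_profile = c("default", "messy", "clean")) {
  stopifnot(n >= 1)
  prevalence <- utils::modifyList(default_prevalence(), prevalence)
  stopifnot(all(unlist(prevalence) >= 0), all(unlist(prevalence) <= 1))
  qp <- quirk_prevalence(match.arg(quirk_profile))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  feats <- names(prevalence)
  feat_on <- vapply(seq_along(feats), function(f) {
    allocate(n, prevalence[[feats[f]]], f)
  }, logical(n))
  if (n == 1) feat_on <- matrix(feat_on, nrow = 1,
                                dimnames = list(NULL, feats)) else colnames(feat_on) <- feats
  quirk_on <- if (length(qp)) {
    m <- vapply(seq_along(qp), function(f) {
      allocate(n, qp[[f]], f + length(feats))
    }, logical(n))
    if (n == 1) m <- matrix(m, nrow = 1)
    colnames(m) <- names(qp)
    m
  } else matrix(logical(0), nrow = n, ncol = 0)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    on <- feat_on[i, ]
    quirks <- colnames(quirk_on)[quirk_on[i, ]]
    for (a in c("reversed_accept_receive", "publish_before_accept", "future_date")) {
      if (isTRUE(on[[a]])) quirks <- c(quirks, a)
    }
    if ("untagged_affiliation" %in% quirks && !on[["country"]]) {
      quirks <- setdiff(quirks, "untagged_affiliation")
    }
    spec <- fixture_spec(
      seed = (seed * 10007L + i * 97L) %% 2147483647L,
      quirks = quirks,
      with_abstract = on[["abstract"]], with_keywords = on[["keywords"]],
      with_editor = on[["editor"]], with_volume = on[["volume"]],
      with_body = on[["body"]], with_references = on[["references"]],
      with_orcid = on[["orcid"]], with_country = on[["country"]],
      n_countries = if (on[["country"]] && on[["multi_country"]]) 2L else 1L
    )
    fx <- generate_article(spec)
    path <- file.path(dir, sprintf("article_%05d.xml", i))
    writeLines(fx$xml, path, useBytes = TRUE)
    truth <- fx$truth
    truth$source <- path
    rows[[i]] <- truth
  }

  manifest <- dplyr::bind_rows(lapply(rows, function(tr) {
    an <- tr$anomalies
    tr$anomalies <- NULL
    row <- as_corpus_row(tr)
    row$source <- tr$source
    row$reversed_accept_receive <- an$reversed_accept_receive
    row$publish_before_accept <- an$publish_before_accept
    row$future_date <- an$future_date
    row$image_formula <- an$image_formula
    row
  }))
  write_corpus_ndjson(manifest[, !(names(manifest) %in%
    c("reversed_accept_receive", "publish_before_accept", "future_date",
      "image_formula"))],
    file.path(dir, "manifest.ndjson"))
  invisible(manifest)
}
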
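# Shared fixtures and reference implementations used across the suite.

minimal_article <- function(body = "", front_extra = "") {
  paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<article article-type=\"research-article\"><front>",
    "<journal-meta><journal-title-group><journal-title>Test Journal",
    "</journal-title></journal-title-group></journal-meta>",
    "<article-meta>",
    "<title-group><article-title>A minimal test article</article-title></title-group>",
    front_extra,
    "</article-meta></front>", body, "</article>"
  )
}

# record comparison: every ground-truth field must decode identically
expect_record_equal <- function(rec, truth) {
  truth$anomalies <- NULL
  for (f in names(truth)) {
    expect_equal(unclass(rec)[[f]], truth[[f]], ignore_attr = TRUE,
                 label = sprintf("decoded field '%s'", f),
                 expected.label = sprintf("planted field '%s'", f))
  }
}

# random strings exercising entities, mixed spaces, markup and styled
# characters, for the conversion idempotence property
random_conversion_input <- function() {
  bits <- c(
    "plain words", "&#x3B1;", "&#945;", "&alpha;", "&amp;", "&mdash;",
    "&unknown;", "&#x;", "<italic>x</italic>", "<b>y</b>",
    "\u00a0", "\u2009", "\u2003", "\u2014", "\u2212", "\uff21",
    intToUtf8(0x1D400), "\u201cq\u201d", "3.14", "p &lt; .05",
    "https://example.org/x", "e.g. test", "  ", "A-b", "ß", "ü"
  )
  paste(sample(bits, sample(3:10, 1), replace = TRUE), collapse = " ")
}

# independent O(n^2) reference for main-section merging
brute_force_split <- function(sections, patterns) {
  if (!nrow(sections) || !length(patterns)) {
    return(list(titles = as.list(sections$title), texts = sections$text))
  }
  matches <- vapply(sections$title, function(t) {
    any(vapply(patterns, function(p) {
      grepl(tolower(p), tolower(t), fixed = TRUE)
    }, NA))
  }, NA)
  groups <- list()
  cur_titles <- character()
  cur_texts <- character()
  flush <- function() {
    if (length(cur_titles)) {
      groups[[length(groups) + 1]] <<- list(titles = cur_titles,
                                            texts = cur_texts)
    }
  }
  for (i in seq_len(nrow(sections))) {
    if (matches[i]) {
      flush()
      cur_titles <- sections$title[i]
      cur_texts <- sections$text[i]
    } else {
      cur_titles <- c(cur_titles, sections$title[i])
      cur_texts <- c(cur_texts, sections$text[i])
    }
  }
  flush()
  list(titles = lapply(groups, `[[`, "titles"),
       texts = vapply(groups, function(g) paste(g$texts, collapse = "\n\n"), ""))
}

random_sections <- function(n = NULL) {
  titles <- c("Introduction", "Background", "Method", "Participants",
              "Measures", "Analysis", "Results", "Main findings",
              "Discussion", "Limitations", "Conclusion", "Appendix")
  n <- n %||% sample(1:8, 1)
  tibble::tibble(
    title = sample(titles, n, replace = TRUE),
    text = replicate(n, paste(sample(letters, 8), collapse = ""))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
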
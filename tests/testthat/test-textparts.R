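test_that("the abstract presence rule uses the 30-character boundary", {
  abst <- function(txt) paste0("<a><abstract><p>", txt, "</p></abstract></a>")
  txt29 <- strrep("a", 29)
  txt30 <- strrep("a", 30)
  expect_false(get_abstract(abst(txt29))$present)
  expect_true(get_abstract(abst(txt30))$present)
  expect_false(get_abstract("<a><body><p>no abstract</p></body></a>")$present)

  out <- get_abstract(abst("First sentence here. Second sentence there."),
                      as_sentences = TRUE)
  expect_length(out$abstract, 2)
})

test_that("sections flatten in reading order with untitled leads kept", {
  body <- paste0(
    "<body><p>Leading untitled text of the body.</p>",
    "<sec><title>Intro</title><p>intro text</p>",
    "<sec><title>Participants</title><p>part text</p></sec>",
    "<sec><title>Measures</title><p>meas text</p></sec></sec>",
    "<sec><title>Results</title><p>res text</p></sec></body>"
  )
  secs <- get_sections(paste0("<article>", body, "</article>"))
  expect_equal(secs$title, c("", "Intro", "Participants", "Measures", "Results"))
  expect_equal(secs$text[1], "Leading untitled text of the body.")
  expect_equal(secs$text[3], "part text")

  expect_equal(nrow(get_sections("<article><body></body></article>")), 0)
  expect_equal(nrow(get_sections("<article></article>")), 0)
})

test_that("figures, tables and captions stay out of section text", {
  body <- paste0(
    "<body><sec><title>Results</title><p>before</p>",
    "<fig id=\"f1\"><caption><title>Figure caption title</title>",
    "<p>caption text</p></caption><graphic xlink:href=\"x.gif\"/></fig>",
    "<table-wrap><caption><p>table caption</p></caption></table-wrap>",
    "<p>after</p></sec></body>"
  )
  secs <- get_sections(paste0("<article>", body, "</article>"))
  expect_equal(secs$title, "Results")
  expect_equal(secs$text, "before after")
})

test_that("main-section merging groups by matching titles", {
  secs <- tibble::tibble(
    title = c("Introduction", "Method", "Participants", "Results", "Discussion"),
    text = paste("text", 1:5)
  )
  patterns <- c("intro", "method", "result", "discussion")
  merged <- split_into_main_sections(secs, patterns)
  expect_equal(nrow(merged), 4)
  expect_equal(merged$title, c("Introduction", "Method", "Results", "Discussion"))
  expect_equal(merged$titles[[2]], c("Method", "Participants"))
  expect_equal(merged$text[2], "text 2\n\ntext 3")

  # empty pattern list is the identity
  ident <- split_into_main_sections(secs, character())
  expect_equal(ident$title, secs$title)
  expect_equal(ident$text, secs$text)

  # nothing matches: one group with everything
  none <- split_into_main_sections(secs, "zzz")
  expect_equal(nrow(none), 1)

  # leading sections before the first match form their own group
  lead <- split_into_main_sections(secs, c("method", "result"))
  expect_equal(nrow(lead), 3)
  expect_equal(lead$titles[[1]], c("Introduction"))
})

test_that("main-section merging conserves text and matches the brute-force reference", {
  set.seed(11)
  patterns <- c("intro", "method", "result", "discussion")
  for (i in 1:40) {
    secs <- random_sections()
    merged <- split_into_main_sections(secs, patterns)
    ref <- brute_force_split(secs, patterns)
    expect_equal(merged$text, ref$texts)
    expect_equal(merged$titles, ref$titles)
    # conservation: concatenated group text equals concatenated input text
    expect_equal(paste(merged$text, collapse = "\n\n"),
                 paste(secs$text, collapse = "\n\n"))
    # group count bounds
    expect_lte(nrow(merged), nrow(secs))
    n_match <- sum(vapply(secs$title, function(t)
      any(vapply(patterns, function(p) grepl(p, tolower(t), fixed = TRUE), NA)), NA))
    expect_lte(nrow(merged), n_match + 1)
  }
})

test_that("sentence splitting protects decimals, abbreviations and initials", {
  expect_length(text2sentences("The model fits. The test was significant (p < .05)."), 2)
  expect_length(text2sentences("Estimates (M = 3.5, SD = 1.2) were stable."), 1)
  expect_equal(text2sentences("Smith et al. (2020) agree. We concur."),
               c("Smith et al. (2020) agree.", "We concur."))
  expect_length(text2sentences("J. R. Smith and M. K. Lee replied."), 1)
  expect_length(text2sentences("See Fig. 3 for details."), 1)
  expect_length(text2sentences(""), 0)
  expect_length(text2sentences(NA_character_), 0)
})

test_that("sentence splitting agrees with the hand-segmented oracle", {
  oracle <- read.delim(test_path("sentences_oracle.tsv"),
                       stringsAsFactors = FALSE, quote = "", sep = "\t")
  n_sent <- 0
  for (i in seq_len(nrow(oracle))) {
    expected <- strsplit(oracle$sentences[i], "|", fixed = TRUE)[[1]]
    got <- text2sentences(oracle$text[i])
    expect_equal(got, expected, label = sprintf("oracle case %d (%s)", i,
                                                substr(oracle$text[i], 1, 40)))
    n_sent <- n_sent + length(expected)
  }
  expect_gte(n_sent, 50)
})

test_that("joining sentences with spaces reconstructs the input (property)", {
  set.seed(5)
  norm <- function(x) stringi::stri_trim_both(gsub("\\s+", " ", x))
  for (i in 1:60) {
    k <- sample(1:6, 1)
    txt <- paste(replicate(k, paste0(
      paste(sample(c("Alpha", "beta", "et al.", "p = .05", "Fig. 2", "gamma",
                     "(2020)", "3.14", "No. 7"), sample(2:5, 1), replace = TRUE),
            collapse = " "), ".")), collapse = " ")
    expect_equal(paste(text2sentences(txt), collapse = " "), norm(txt))
  }
})

test_that("references extract per citation element in order", {
  back <- paste0(
    "<back><ref-list>",
    "<ref id=\"B1\"><mixed-citation>Alpha A. (2001). First work. J One, 1, 1-10.</mixed-citation></ref>",
    "<ref id=\"B2\"><mixed-citation>Beta B. (2002). Second work. J Two, 2, 2-20.</mixed-citation></ref>",
    "<ref id=\"B3\"><mixed-citation>Gamma C. (2003). Third work. J Three, 3, 3-30.</mixed-citation></ref>",
    "</ref-list></back>"
  )
  refs <- get_references(paste0("<article>", back, "</article>"))
  expect_equal(refs$index, 1:3)
  expect_match(refs$raw[2], "^Beta B")

  structured <- paste0(
    "<article><back><ref-list><ref id=\"B1\"><element-citation publication-type=\"journal\">",
    "<person-group><name><surname>Blanca</surname><given-names>M</given-names></name></person-group>",
    "<year>2018</year><article-title>Skewness and kurtosis</article-title>",
    "<source>Methodology</source><volume>9</volume></element-citation></ref>",
    "</ref-list></back></article>"
  )
  refs2 <- get_references(structured)
  expect_equal(nrow(refs2), 1)
  for (part in c("Blanca", "M", "2018", "Skewness and kurtosis", "Methodology", "9")) {
    expect_match(refs2$raw, part, fixed = TRUE)
  }
  expect_equal(nrow(get_references(minimal_article())), 0)
})
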
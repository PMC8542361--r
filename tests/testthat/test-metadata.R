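test_that("simple tags extract entity-converted, trimmed values or are absent", {
  xml <- minimal_article(front_extra = paste0(
    "<article-id pub-id-type=\"pmid\">123</article-id>",
    "<article-id pub-id-type=\"doi\">10.1000/x.1</article-id>"
  ))
  expect_equal(get_title(xml), "A minimal test article")
  expect_equal(get_journal(xml), "Test Journal")
  expect_equal(get_doi(xml), "10.1000/x.1")
  expect_equal(get_type(xml), "research-article")
  expect_identical(get_volume(xml), NA_character_)

  entity_title <- "<article><article-title>Big &#x3b1; <italic>study</italic></article-title></article>"
  expect_equal(get_title(entity_title), "Big α study")
})

test_that("subjects flatten across nesting and keywords drop separator entries", {
  nested <- paste0("<a><article-categories><subj-group>",
                   "<subject>Biology</subject>",
                   "<subj-group><subject>Genetics</subject></subj-group>",
                   "</subj-group></article-categories></a>")
  expect_equal(get_subjects(nested), c("Biology", "Genetics"))

  kw <- "<a><kwd-group><kwd>Covid-19</kwd><kwd>;</kwd><kwd>SARS-Cov-2</kwd></kwd-group></a>"
  expect_equal(get_keywords(kw), c("Covid-19", "SARS-Cov-2"))
  expect_equal(get_keywords("<a><p>no keywords</p></a>"), character())
})

hist_xml <- function(dates) paste0("<a><history>", dates, "</history></a>")

test_that("get_history collects stamps and drops invalid or duplicate ones", {
  h <- get_history(hist_xml(paste0(
    "<date date-type=\"received\"><day>1</day><month>3</month><year>2010</year></date>",
    "<date date-type=\"accepted\"><day>15</day><month>6</month><year>2010</year></date>",
    "<date date-type=\"epub\"><day>1</day><month>7</month><year>2010</year></date>"
  )))
  expect_equal(nrow(h), 3)
  expect_equal(h$label, c("received", "accepted", "epub"))

  jats_log(clear = TRUE)
  h2 <- get_history(hist_xml(paste0(
    "<date date-type=\"received\"><day>42</day><month>3</month><year>2010</year></date>",
    "<date date-type=\"accepted\"><month>6</month></date>",
    "<date date-type=\"epub\"><year>2010</year></date>",
    "<date date-type=\"epub\"><year>2012</year></date>"
  )))
  expect_equal(h2$label, "epub")
  expect_equal(h2$year, 2010L)
  lg <- jats_log(clear = TRUE)
  expect_true(any(grepl("invalid month/day", lg$message)))
  expect_true(any(grepl("without year", lg$message)))
  expect_true(any(grepl("duplicate", lg$message)))

  # unknown labels land in the catch-all
  h3 <- get_history(hist_xml(
    "<date date-type=\"resubmitted\"><year>2011</year></date>"))
  expect_equal(h3$label, "other")
})

test_that("the recognised label vocabulary has exactly 14 entries", {
  expect_length(HISTORY_LABELS, 14)
  for (lbl in HISTORY_LABELS) {
    xml <- if (lbl %in% c("epub", "ppub", "print", "pub", "collection", "pmc-release")) {
      paste0("<a><pub-date pub-type=\"", lbl, "\"><year>2015</year></pub-date></a>")
    } else {
      hist_xml(paste0("<date date-type=\"", lbl, "\"><year>2015</year></date>"))
    }
    expect_equal(get_history(xml)$label, lbl)
  }
})

test_that("the unified publication date is the minimum over the six event stamps", {
  h <- get_history(paste0(
    "<a><pub-date pub-type=\"epub\"><day>3</day><month>9</month><year>2005</year></pub-date>",
    "<pub-date pub-type=\"ppub\"><day>1</day><month>8</month><year>2005</year></pub-date></a>"
  ))
  pub <- compute_pub_date(h)
  expect_equal(pub$pub_date, as.Date("2005-08-01"))
  expect_equal(pub$pubyear, 2005L)

  # year-only stamps complete month/day to 1
  h2 <- get_history("<a><pub-date pub-type=\"ppub\"><year>1999</year></pub-date></a>")
  expect_identical(h2$month, NA_integer_)
  expect_equal(compute_pub_date(h2)$pub_date, as.Date("1999-01-01"))

  # no event stamp: year falls back to the earliest over all stamps
  h3 <- get_history(hist_xml(
    "<date date-type=\"accepted\"><day>2</day><month>5</month><year>2011</year></date>"))
  pub3 <- compute_pub_date(h3)
  expect_true(is.na(pub3$pub_date))
  expect_equal(pub3$pubyear, 2011L)

  empty <- get_history("<a></a>")
  pub4 <- compute_pub_date(empty)
  expect_true(is.na(pub4$pub_date) && is.na(pub4$pubyear))
})

test_that("pub date selection is invariant to stamp order and consistent with pubyear", {
  base <- tibble::tibble(
    label = c("epub", "collection", "accepted", "ppub"),
    year = c(2010L, 2008L, 2009L, 2011L),
    month = c(5L, NA, 2L, 1L),
    day = c(7L, NA, 1L, NA)
  )
  ref <- compute_pub_date(base)
  expect_equal(ref$pubyear, as.integer(format(ref$pub_date, "%Y")))
  set.seed(1)
  for (i in 1:20) {
    shuffled <- base[sample(nrow(base)), ]
    expect_equal(compute_pub_date(shuffled), ref)
  }
})

test_that("editorial lags are day differences and may be negative", {
  h <- get_history(hist_xml(paste0(
    "<date date-type=\"received\"><day>1</day><month>5</month><year>2020</year></date>",
    "<date date-type=\"accepted\"><day>1</day><month>4</month><year>2020</year></date>"
  )))
  lags <- publication_lags(h, as.Date("2020-03-01"))
  expect_equal(lags$time_to_accept, -30L)
  expect_equal(lags$time_to_publish, -31L)

  only_received <- get_history(hist_xml(
    "<date date-type=\"received\"><day>1</day><month>5</month><year>2020</year></date>"))
  lags2 <- publication_lags(only_received)
  expect_true(is.na(lags2$time_to_accept) && is.na(lags2$time_to_publish))
})
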
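# a tiny in-memory corpus with full control over every field
toy_corpus <- function(n, abstracts = n, pubyears = rep(2012L, n),
                       countries = NULL, histories = NULL,
                       tta = rep(NA_integer_, n), ttp = rep(NA_integer_, n),
                       journals = rep("J", n), types = rep("research-article", n)) {
  empty_hist <- tibble::tibble(label = character(), year = integer(),
                               month = integer(), day = integer())
  out <- tibble::tibble(
    source = sprintf("f%02d.xml", seq_len(n)),
    title = "T", journal = journals, doi = "10.1/x", type = types,
    volume = NA_character_,
    subjects = replicate(n, "S", simplify = FALSE),
    keywords = replicate(n, character(), simplify = FALSE),
    authors = replicate(n, tibble::tibble(
      surname = "A", given = "B", role = "author",
      ids = list(tibble::tibble(scheme = character(), value = character()))),
      simplify = FALSE),
    editors = replicate(n, jatsr:::empty_people(), simplify = FALSE),
    affiliations = replicate(n, tibble::tibble(text = "X", countries = list(character())),
                             simplify = FALSE),
    countries = countries %||% replicate(n, character(), simplify = FALSE),
    history = histories %||% replicate(n, empty_hist, simplify = FALSE),
    pub_date = as.Date(sprintf("%d-01-01", pubyears)),
    pubyear = pubyears,
    time_to_accept = tta, time_to_publish = ttp,
    abstract = ifelse(seq_len(n) <= abstracts, strrep("a", 40), NA_character_),
    abstract_present = seq_len(n) <= abstracts,
    sections = replicate(n, tibble::tibble(title = "Intro", text = strrep("t", 40)),
                         simplify = FALSE),
    text_present = TRUE,
    references = replicate(n, "ref one", simplify = FALSE)
  )
  class(out) <- c("jats_corpus", class(out))
  out
}

test_that("tag-use frequencies follow the presence rules and the period binning", {
  corp <- toy_corpus(10, abstracts = 7,
                     pubyears = c(1999L, 2003L, 2005L, rep(2012L, 7)))
  tu <- tag_use_table(corp, period_edges = c(2000, 2005))
  expect_equal(tu$total[tu$element == "abstract"], 0.70)
  expect_equal(tu$total[tu$element == "doi"], 1)
  expect_equal(tu$total[tu$element == "keywords"], 0)
  # first bin closed on both sides; right-closed elsewhere
  expect_named(tu, c("element", "total", "[1999; 2000]", "(2000; 2005]"))
  totals <- tu[tu$element == "total_n", -1]
  expect_equal(unlist(totals, use.names = FALSE), c(10, 1, 2))
})

test_that("an empty keyword group counts as not present", {
  xml <- minimal_article(front_extra = "<kwd-group></kwd-group>")
  rec <- decode_article(xml)
  expect_equal(rec$keywords, character())
})

test_that("records without a publication year stay out of period columns", {
  corp <- toy_corpus(4, pubyears = c(2010L, 2010L, NA, NA))
  tu <- tag_use_table(corp, period_edges = c(2015))
  totals <- tu[tu$element == "total_n", ]
  expect_equal(totals$total, 4)
  expect_equal(totals[["[2010; 2015]"]], 2)
  expect_error(tag_use_table(corp, period_edges = c(2015, 2010)),
               "strictly increasing")
})

test_that("journal productivity bins match the printed bin edges", {
  journals <- c("a", "b", rep("c", 5), rep("d", 150))
  corp <- toy_corpus(length(journals), journals = journals)
  jb <- frequency_table(corp, "journal", bins = TRUE)
  expect_equal(jb$bin, c("1", "2-10", "11-100", "101-1000", "1001-10^4",
                         "10^4-10^5", ">10^5"))
  expect_equal(jb$h, c(2L, 1L, 0L, 1L, 0L, 0L, 0L))
  expect_equal(sum(jb$h), 4)
  expect_equal(jb$f, round(jb$h / 4, 4))
})

test_that("frequency tables count labels with a top-k selector", {
  corp <- toy_corpus(4, types = c(rep("research-article", 3), "review"))
  ft <- frequency_table(corp, "type")
  expect_equal(ft$label, c("research-article", "review"))
  expect_equal(ft$n, c(3L, 1L))
  expect_equal(nrow(frequency_table(corp, "type", top_k = 1)), 1)
  expect_error(frequency_table(corp, "nope"))
})

test_that("date anomalies count reversed lags and future stamps", {
  hist_future <- tibble::tibble(label = "accepted", year = 2100L,
                                month = 1L, day = 14L)
  corp <- toy_corpus(
    5,
    tta = c(-30L, -1L, 10L, NA, 5L),
    ttp = c(5L, 5L, -31L, NA, NA),
    histories = c(replicate(4, tibble::tibble(
      label = "epub", year = 2012L, month = 1L, day = 1L), simplify = FALSE),
      list(hist_future))
  )
  an <- date_anomalies(corp, reference_date = as.Date("2021-01-01"))
  expect_equal(an$n_accept_before_receive, 2L)
  expect_equal(an$n_publish_before_accept, 1L)
  expect_equal(an$n_future_dates, 1L)

  clean <- toy_corpus(3)
  an2 <- date_anomalies(clean)
  expect_equal(unlist(an2), c(n_accept_before_receive = 0L,
                              n_publish_before_accept = 0L,
                              n_future_dates = 0L))
})

test_that("country co-occurrence enumerates unordered pairs and the international share", {
  corp <- toy_corpus(3, countries = list(
    c("United Kingdom", "United States"),
    "United States",
    c("Germany", "United Kingdom", "United States")
  ))
  cc <- country_cooccurrence(corp)
  expect_equal(cc$international_share, 2 / 3)
  pairs <- cc$pairs
  key <- paste(pairs$country1, pairs$country2, sep = "|")
  expect_equal(pairs$n[key == "United Kingdom|United States"], 2L)
  expect_equal(pairs$n[key == "Germany|United States"], 1L)
  expect_equal(pairs$n[key == "Germany|United Kingdom"], 1L)

  none <- country_cooccurrence(toy_corpus(2))
  expect_equal(nrow(none$pairs), 0)
  expect_equal(none$international_share, 0)
})

test_that("decode_collection skips corrupt files and is order-invariant", {
  dir <- withr::local_tempdir()
  man <- generate_corpus(10, dir, seed = 3, quirk_profile = "clean")
  corp <- decode_collection(dir)
  expect_equal(nrow(corp), 10)
  expect_equal(sort(corp$title), sort(man$title))

  # one corrupt file: logged skip, not fatal
  writeLines("this is not an article at all", file.path(dir, "article_99999.xml"))
  jats_log(clear = TRUE)
  corp2 <- decode_collection(dir)
  expect_equal(nrow(corp2), 10)
  lg <- jats_log(clear = TRUE)
  expect_true(any(grepl("article_99999", lg$message)))

  # shuffled paths give the same multiset of records
  paths <- list.files(dir, pattern = "article_\\d{5}\\.xml$", full.names = TRUE)
  paths <- paths[!grepl("99999", paths)]
  set.seed(1)
  corp3 <- decode_collection(sample(paths))
  expect_equal(dplyr::arrange(corp2, .data$source)$title,
               dplyr::arrange(corp3, .data$source)$title)

  expect_error(decode_collection(withr::local_tempdir()), "no JATS files")
})

test_that("profile CSVs are written with stable names", {
  corp <- toy_corpus(6, abstracts = 4)
  out <- withr::local_tempdir()
  write_profile(corp, out)
  expect_setequal(list.files(out),
                  c("tag_use.csv", "journal_bins.csv", "date_types.csv",
                    "type_counts.csv", "anomalies.csv", "country_pairs.csv"))
  tu <- read.csv(file.path(out, "tag_use.csv"), check.names = FALSE)
  expect_equal(tu$total[tu$element == "abstract"], round(4 / 6, 4))
})

test_that("glance and tidy summarise corpus and article", {
  dir <- withr::local_tempdir()
  generate_corpus(6, dir, seed = 8, quirk_profile = "clean")
  corp <- decode_collection(dir)
  g <- glance(corp)
  expect_equal(g$n_articles, 6)
  expect_true(g$frac_abstract >= 0 && g$frac_abstract <= 1)

  art <- decode_article(generate_article(fixture_spec(seed = 2))$xml)
  td <- tidy(art)
  expect_true(all(c("title", "history", "sections") %in% td$field))
})
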
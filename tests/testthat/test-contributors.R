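contrib_xml <- function(inner, type = "author") {
  paste0("<a><contrib-group><contrib contrib-type=\"", type, "\">",
         inner, "</contrib></contrib-group></a>")
}

name_xml <- function(surname, given) {
  paste0("<name><surname>", surname, "</surname>",
         "<given-names>", given, "</given-names></name>")
}

test_that("all-caps names recase to an initial capital; mixed case is untouched", {
  au <- get_contributors(contrib_xml(name_xml("WANG", "WEI")))
  expect_equal(au$surname, "Wang")
  expect_equal(au$given, "Wei")

  au2 <- get_contributors(contrib_xml(name_xml("McDonald", "Jean-Luc")))
  expect_equal(au2$surname, "McDonald")
  expect_equal(au2$given, "Jean-Luc")

  # hyphenated all-caps parts recase per token; Unicode-aware
  au3 <- get_contributors(contrib_xml(name_xml("MÜLLER-SMITH", "van DER")))
  expect_equal(au3$surname, "Müller-Smith")
  expect_equal(au3$given, "van Der")
})

test_that("given names shorten to one-letter abbreviations per token", {
  xml <- contrib_xml(name_xml("Wang", "Wei"))
  expect_equal(get_contributors(xml, shorten_given = TRUE)$given, "W.")
  xml2 <- contrib_xml(name_xml("Smith", "Anna Maria"))
  expect_equal(get_contributors(xml2, shorten_given = TRUE)$given, "A. M.")
  # contributor count is invariant under shortening
  expect_equal(nrow(get_contributors(xml2, shorten_given = TRUE)),
               nrow(get_contributors(xml2)))
})

test_that("contributor identifiers are harvested with scheme detection", {
  xml <- contrib_xml(paste0(
    "<contrib-id contrib-id-type=\"orcid\">0000-0002-1825-0097</contrib-id>",
    name_xml("Okafor", "Aisha")))
  ids <- get_contributors(xml)$ids[[1]]
  expect_equal(ids$scheme, "orcid")
  expect_equal(ids$value, "0000-0002-1825-0097")

  # missing type attribute: the 16-digit form is recognised as ORCID
  xml2 <- contrib_xml(paste0(
    "<contrib-id>0000-0002-1825-0097</contrib-id>", name_xml("A", "B")))
  expect_equal(get_contributors(xml2)$ids[[1]]$scheme, "orcid")
})

test_that("editors are selected by role and nameless contributors are skipped", {
  xml <- paste0("<a><contrib-group>",
                "<contrib contrib-type=\"author\">", name_xml("Kim", "Yuki"), "</contrib>",
                "<contrib contrib-type=\"editor\">", name_xml("Silva", "Maria"), "</contrib>",
                "<contrib contrib-type=\"author\"><email>x@y.org</email></contrib>",
                "</contrib-group></a>")
  jats_log(clear = TRUE)
  expect_equal(get_contributors(xml, "author")$surname, "Kim")
  expect_equal(get_contributors(xml, "editor")$surname, "Silva")
  expect_true(any(grepl("without any name", jats_log(clear = TRUE)$message)))
})

test_that("affiliations join tagged parts and pass untagged lines through", {
  tagged <- paste0("<a><aff id=\"a1\"><label>1</label>",
                   "<institution>Institute of Psychology</institution>",
                   "<addr-line>Hamburg</addr-line>",
                   "<country>Germany</country></aff></a>")
  affs <- get_affiliations(tagged)
  expect_equal(affs$text, "Institute of Psychology, Hamburg, Germany")
  expect_equal(affs$countries[[1]], "Germany")

  untagged <- paste0("<a><aff>Institute of Psychology, University Hamburg, ",
                     "Von-Melle-Park 5, 20146 Hamburg, Germany</aff></a>")
  affs2 <- get_affiliations(untagged)
  expect_equal(affs2$text,
               "Institute of Psychology, University Hamburg, Von-Melle-Park 5, 20146 Hamburg, Germany")
  expect_equal(affs2$countries[[1]], "Germany")
})

test_that("country recognition unifies aliases and anchors at the string end", {
  expect_equal(get_countries("Institute of Botany, Peoples Rep. of China"),
               "China")
  expect_equal(get_countries("Dept of History, UNITED STATES"), "United States")
  expect_equal(get_countries("School of Law, UK."), "United Kingdom")
  # mid-string country words never match
  expect_equal(get_countries("Georgia Institute of Technology, Atlanta"),
               character())
  # trailing decorations are tolerated
  expect_equal(get_countries("University of Oslo, Norway. e-mail: a@b.no"),
               "Norway")
  expect_equal(get_countries("Seoul National University, South Korea 08826"),
               "South Korea")
})

test_that("country output is canonical, unique, sorted and idempotent", {
  affs <- get_affiliations(paste0(
    "<a><aff><institution>X</institution><country>Republic of Korea</country></aff>",
    "<aff>Dept of Physics, Germany</aff>",
    "<aff>Other Dept, Germany</aff></a>"))
  cc <- get_countries(affs)
  expect_equal(cc, c("Germany", "South Korea"))
  canon <- jatsr:::load_country_tables()$canon
  expect_true(all(cc %in% canon))
  # re-unifying canonical names changes nothing
  expect_equal(get_countries(cc), sort(cc))
})
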
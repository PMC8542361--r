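Package: jatsr
Title: Decode NISO-JATS Coded XML Articles into Tidy Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Extracts unified metadata, abstract, sectioned text and
    reference lists from NISO-JATS coded XML articles (PMC-style NXML),
    tolerant of real-world dialect variation: entity and Unicode
    representation differences, alternative publication-history date
    stamps, all-caps contributor names, tagged and untagged affiliations,
    and formula markup. Includes a character-representation unifier, a
    publication-history harmoniser computing the earliest publication
    date and editorial lags, affiliation country recognition, a corpus
    profiler producing bibliometric tables and date-stamp sanity checks,
    and a synthetic fixture generator with exact ground truth for
    offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringi,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    stringr,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
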
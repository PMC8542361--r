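# Character representation unification.
#
# PMC content codes special characters as hexadecimal (&#x3B1;), decimal
# (&#945;) or named (&alpha;) entities, uses a zoo of Unicode spaces and
# dashes, and renders the same letter in bold/italic/script math variants.
# Everything here maps those onto one canonical representation so that
# downstream regex search works on plain text.

load_tables <- function() {
  if (!is.null(the$tables)) return(the$tables)
  path <- function(f) system.file("extdata", f, package = "jatsr", mustWork = TRUE)
  ent <- utils::read.delim(path("entities.tsv"), stringsAsFactors = FALSE)
  entities <- stats::setNames(
    vapply(strtoi(ent$codepoint, 16L), intToUtf8, ""), ent$name
  )
  spaces <- vapply(strtoi(utils::read.delim(path("spaces.tsv"))$codepoint, 16L),
                   intToUtf8, "")
  hyphens <- vapply(strtoi(utils::read.delim(path("hyphens.tsv"))$codepoint, 16L),
                    intToUtf8, "")
  char_class <- function(chars) {
    paste0("[", paste(sprintf("\\x{%04X}", vapply(chars, utf8ToInt, 1L)),
                      collapse = ""), "]")
  }
  the$tables <- list(
    entities = entities, spaces = spaces, hyphens = hyphens,
    space_class = char_class(spaces), hyphen_class = char_class(hyphens),
    synonyms = build_synonym_map()
  )
  the$tables
}

# Styled character variants -> plain equivalents. The math-alphanumeric
# block (U+1D400-) is arithmetic: 13 styles x 52 Latin letters, Greek runs
# of 58, digit runs of 10; fullwidth forms are an ASCII offset. Computed
# rather than shipped.
build_synonym_map <- function() {
  map <- character()
  latin <- c(LETTERS, letters)
  cps <- 0x1D400:0x1D6A3
  map[vapply(cps, intToUtf8, "")] <- latin[((cps - 0x1D400) %% 52L) + 1L]
  map[c(intToUtf8(0x1D6A4), intToUtf8(0x1D6A5))] <- c("i", "j")

  greek58 <- c(
    strsplit(intToUtf8(c(0x391:0x3A1, 0x398, 0x3A3:0x3A9, 0x2207)), "")[[1]],
    strsplit(intToUtf8(c(0x3B1:0x3C9, 0x2202, 0x3B5, 0x3B8, 0x3BA, 0x3C6,
                         0x3C1, 0x3C0)), "")[[1]]
  )
  cps <- 0x1D6A8:0x1D7CB
  map[vapply(cps, intToUtf8, "")] <- greek58[((cps - 0x1D6A8) %% 58L) + 1L]
  map[intToUtf8(0x3F4)] <- intToUtf8(0x398)  # capital theta variant

  cps <- 0x1D7CE:0x1D7FF
  map[vapply(cps, intToUtf8, "")] <- as.character((cps - 0x1D7CE) %% 10L)

  cps <- 0xFF01:0xFF5E
  map[vapply(cps, intToUtf8, "")] <- vapply(cps - 0xFF01 + 0x21, intToUtf8, "")

  lig <- c("ﬀ" = "ff", "ﬁ" = "fi", "ﬂ" = "fl",
           "ﬃ" = "ffi", "ﬄ" = "ffl", "ﬆ" = "st")
  quotes <- c("‘" = "'", "’" = "'", "‚" = "'", "‛" = "'",
              "“" = "\"", "”" = "\"", "„" = "\"",
              "‟" = "\"", "′" = "'", "″" = "\"",
              "…" = "...")
  ops <- c("×" = "x", "÷" = "/", "⁄" = "/", "∕" = "/",
           "≤" = "<=", "≥" = ">=", "≠" = "!=",
           "⩽" = "<=", "⩾" = ">=", "∼" = "~")
  c(map, lig, quotes, ops)
}

#' Character and entity tables
#'
#' The lookup tables behind [convert_letters()]: named-entity map, the
#' space codings (all unified to a plain space; more than 20 by design),
#' the hyphen/dash codings (unified to `-`) and the styled-character
#' synonym map (math-alphanumeric, fullwidth, ligature, quote and operator
#' variants mapped to plain equivalents).
#'
#' @return A list with elements `entities` (named character), `spaces`
#'   (character), `hyphens` (character) and `synonyms` (named character).
#' @export
#' @examples
#' length(entity_tables()$spaces) > 20
entity_tables <- function() load_tables()

decode_numeric_entities <- function(x, log_malformed = TRUE) {
  if (log_malformed && any(stringi::stri_detect_regex(x, "&#x?;"))) {
    log_event("convert_letters", "malformed numeric entity left verbatim")
  }
  found <- unique(unlist(stringi::stri_extract_all_regex(
    x, "&#(?:x[0-9a-fA-F]+|[0-9]+);", omit_no_match = TRUE
  )))
  if (!length(found)) return(x)
  cp <- ifelse(
    stringi::stri_detect_fixed(found, "x", case_insensitive = TRUE),
    strtoi(stringi::stri_sub(found, 4, -2), 16L),
    strtoi(stringi::stri_sub(found, 3, -2), 10L)
  )
  valid <- !is.na(cp) & cp > 0 & cp <= 0x10FFFF & !(cp >= 0xD800 & cp <= 0xDFFF)
  if (any(!valid) && log_malformed) {
    log_event("convert_letters",
              paste("invalid entity left verbatim:",
                    paste(found[!valid], collapse = " ")))
  }
  if (!any(valid)) return(x)
  stringi::stri_replace_all_fixed(
    x, found[valid], vapply(cp[valid], intToUtf8, ""),
    vectorize_all = FALSE
  )
}

decode_named_entities <- function(x, entities, log_unknown = TRUE) {
  found <- unique(unlist(stringi::stri_extract_all_regex(
    x, "&[A-Za-z][A-Za-z0-9]*;", omit_no_match = TRUE
  )))
  if (!length(found)) return(x)
  nm <- stringi::stri_sub(found, 2, -2)
  known <- nm %in% names(entities)
  if (any(!known) && log_unknown) {
    log_event("convert_letters",
              paste("unknown named entity left verbatim:",
                    paste(unique(nm[!known]), collapse = " ")))
  }
  if (!any(known)) return(x)
  stringi::stri_replace_all_fixed(
    x, found[known], unname(entities[nm[known]]), vectorize_all = FALSE
  )
}

FORMATTING_TAGS <- c(
  "italic", "bold", "b", "i", "u", "em", "strong", "sub", "sup", "sc",
  "underline", "overline", "monospace", "roman", "sans-serif", "strike",
  "styled-content", "named-content", "ext-link", "uri", "a"
)

strip_formatting_tags <- function(x) {
  pat <- paste0("</?(?:", paste(FORMATTING_TAGS, collapse = "|"),
                ")(?=[\\s/>])[^>]*>")
  stringi::stri_replace_all_regex(x, pat, "")
}

convert_pass <- function(x, tab, first_pass) {
  # each step runs only on the elements that can be affected
  on <- function(cond, f) {
    i <- which(!is.na(cond) & cond)
    if (length(i)) x[i] <<- f(x[i])
    invisible(NULL)
  }
  on(stringi::stri_detect_fixed(x, "&"), function(v) {
    v <- decode_numeric_entities(v, log_malformed = first_pass)
    decode_named_entities(v, tab$entities, log_unknown = first_pass)
  })
  on(stringi::stri_detect_fixed(x, "<"), strip_formatting_tags)
  on(stringi::stri_detect_regex(x, "https?://|www\\."), function(v) {
    stringi::stri_replace_all_regex(v, "(?:https?://|www\\.)[^\\s<>\"')\\]]+", "")
  })
  on(stringi::stri_detect_regex(x, "[^\\x01-\\x7F]"), function(v) {
    v <- stringi::stri_replace_all_regex(v, tab$space_class, " ")
    v <- stringi::stri_replace_all_regex(v, tab$hyphen_class, "-")
    v <- stringi::stri_replace_all_fixed(
      v, names(tab$synonyms), unname(tab$synonyms), vectorize_all = FALSE
    )
    stringi::stri_trans_nfc(v)
  })
  stringi::stri_replace_all_regex(x, "[ \t]+", " ")
}

#' Unify character representations to plain Unicode text
#'
#' Replaces hexadecimal (`&#x3B1;`) and decimal (`&#945;`) numeric
#' entities and the covered named entities (`&alpha;`) with their Unicode
#' characters, maps every space coding to a plain space and every
#' hyphen/dash variant to `-`, folds styled math-alphanumeric, fullwidth
#' and ligature characters to their plain equivalents, removes hyperlinks
#' and HTML formatting tags, collapses runs of spaces and returns
#' NFC-normalised text. The conversion is run to a fixpoint, so it is
#' idempotent and resolves double-encoded entities. Malformed or unknown
#' entities are left verbatim and logged.
#'
#' @param text character vector.
#' @return character vector of the same length.
#' @export
#' @examples
#' convert_letters("&#x03b1; = .05")
#' convert_letters("a b c")
convert_letters <- function(text) {
  if (!length(text)) return(character())
  tab <- load_tables()
  x <- ifelse(is.na(text), NA_character_, enc2utf8(as.character(text)))
  for (pass in 1:6) {
    nx <- convert_pass(x, tab, first_pass = pass == 1L)
    if (identical(nx, x)) break
    x <- nx
  }
  x
}

#' Correct spacing irregularities
#'
#' Applies a fixed, documented rule set: whitespace runs collapse to one
#' space; no space before `, . ; : ? ! ) ] %` (a space before a decimal
#' point, as in `p = .05`, is handled by the operator rule, and `.` kept
#' when followed by a digit); no space after `(` or `[`; spaces around `=`
#' removed; a missing space after sentence-final punctuation restored when
#' a lowercase letter abuts an uppercase one; ends trimmed. Idempotent.
#'
#' @param text character vector.
#' @return character vector of the same length.
#' @export
#' @examples
#' fix_spacing("result ( p = .05 ) .")
fix_spacing <- function(text) {
  x <- stringi::stri_replace_all_regex(text, "\\s+", " ")
  x <- stringi::stri_replace_all_regex(x, " (?=[,;:?!%)\\]])", "")
  x <- stringi::stri_replace_all_regex(x, " (?=\\.(?![0-9]))", "")
  x <- stringi::stri_replace_all_regex(x, "(?<=[(\\[]) ", "")
  x <- stringi::stri_replace_all_regex(x, " ?= ?", "=")
  x <- stringi::stri_replace_all_regex(x, "(?<=[a-z])([.?!])(?=[A-Z])", "$1 ")
  stringi::stri_trim_both(x)
}

LATEX_MACROS <- local({
  greek <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta",
             "theta", "iota", "kappa", "lambda", "mu", "nu", "xi", "omicron",
             "pi", "rho", "sigma", "tau", "upsilon", "phi", "chi", "psi",
             "omega")
  gcp <- c(0x3B1:0x3BF, 0x3C0, 0x3C1, 0x3C3:0x3C9)
  up <- paste0(toupper(substr(greek, 1, 1)), substr(greek, 2, 99))
  ucp <- c(0x391:0x39F, 0x3A0, 0x3A1, 0x3A3:0x3A9)
  ops <- c(times = "x", pm = "+/-", mp = "-/+", cdot = "*", ast = "*",
           leqslant = "<=", geqslant = ">=", leq = "<=", geq = ">=",
           neq = "!=", le = "<=", ge = ">=", ne = "!=", lt = "<", gt = ">",
           sim = "~", approx = "~", infty = "∞", rightarrow = "->",
           leftarrow = "<-", propto = "∝", circledR = "(R)", sum = "∑",
           prod = "∏", int = "∫", partial = "∂", nabla = "∇",
           varepsilon = "\u3B5", vartheta = "\u3D1", varphi = "\u3C6",
           varrho = "\u3C1", varsigma = "\u3C2", varpi = "\u3D6",
           circ = "°", degree = "°", prime = "'", percent = "%")
  c(stats::setNames(vapply(gcp, intToUtf8, ""), greek),
    stats::setNames(vapply(ucp, intToUtf8, ""), up),
    ops)
})

flatten_latex <- function(x) {
  x <- stringi::stri_replace_all_regex(x, "\\$\\$|\\$|\\\\[()\\[\\]]", "")
  for (i in 1:3) {
    x <- stringi::stri_replace_all_regex(
      x, "\\\\[dt]?frac\\{([^{}]*)\\}\\{([^{}]*)\\}", "$1/$2"
    )
  }
  x <- stringi::stri_replace_all_regex(x, "\\\\sqrt\\{([^{}]*)\\}", "√($1)")
  nm <- names(LATEX_MACROS)[order(-nchar(names(LATEX_MACROS)))]
  x <- stringi::stri_replace_all_regex(
    x, paste0("\\\\", nm, "(?![A-Za-z])"),
    unname(LATEX_MACROS[nm]), vectorize_all = FALSE
  )
  # unknown macros degrade to their arguments
  x <- stringi::stri_replace_all_regex(x, "\\\\[A-Za-z]+\\*?", "")
  stringi::stri_replace_all_regex(x, "[{}^_~]|\\\\", "")
}

#' Flatten a formula element to plain text
#'
#' Renders MathML elements, `<inline-formula>`/`<disp-formula>` wrappers
#' and MathJax/LaTeX notation as plain text in reading order. Styled
#' character variants fold to plain equivalents; LaTeX delimiters are
#' stripped and a fixed macro table (greek letters, fractions to `a/b`,
#' comparison and product operators, sub/superscripts to their bare
#' arguments) is applied, unknown macros degrading to concatenated
#' arguments. A formula represented only by a hyper-referenced image
#' yields `""` with attribute `image_formula = TRUE` and a log entry.
#'
#' @param fragment a `jats_fragment` (from [extract_fragments()]) or a
#'   character string of formula markup/notation.
#' @return A single string; whitespace inside the formula is removed.
#' @export
#' @examples
#' flatten_math("$$\\alpha$$")
#' flatten_math("<math><mi>p</mi><mo>&#x3C;</mo><mn>0.05</mn></math>")
flatten_math <- function(fragment) {
  raw <- if (inherits(fragment, "jats_fragment")) fragment$raw_xml else fragment
  if (length(raw) != 1) stop("flatten_math() takes one formula", call. = FALSE)

  has_graphic <- stringi::stri_detect_regex(raw, "<(?:inline-)?graphic\\b")
  visible <- strip_tags(stringi::stri_replace_all_regex(
    raw, "(?s)<(?:inline-)?graphic\\b[^>]*(?:/>|>.*?</(?:inline-)?graphic\\s*>)", ""
  ))
  if (has_graphic && !nzchar(stringi::stri_trim_both(visible))) {
    log_event("flatten_math", "image-only formula yields empty text")
    return(structure("", image_formula = TRUE))
  }

  maths <- extract_fragments(raw, "math")
  tex <- extract_fragments(raw, "tex-math")
  body <- if (length(maths)) {
    paste(vapply(maths, function(f) inner_xml(f), ""), collapse = " ")
  } else if (length(tex)) {
    paste(vapply(tex, function(f) inner_xml(f), ""), collapse = " ")
  } else {
    raw
  }
  body <- stringi::stri_replace_all_regex(
    body, "(?s)<(?:inline-)?graphic\\b[^>]*(?:/>|>.*?</(?:inline-)?graphic\\s*>)", ""
  )
  x <- strip_tags(body, sep = "")
  x <- convert_letters(x)
  x <- flatten_latex(x)
  x <- stringi::stri_replace_all_regex(x, "\\s+", "")
  structure(x, image_formula = FALSE)
}
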
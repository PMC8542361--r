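#' Read a JATS/NXML article file
#'
#' Reads the file as text, honouring the encoding declared in the XML
#' prolog. Undeclared or wrongly declared files fall back to UTF-8 and
#' then to Latin-1 (every byte sequence is valid Latin-1, so decoding
#' always succeeds); any fallback is logged. DOCTYPE declarations are kept
#' verbatim and never resolved over the network.
#'
#' @param path path to an XML file.
#' @return An object of class `jats_document`: a list with `source_path`,
#'   `content` (the decoded text) and `declared_encoding` (`NA` when the
#'   prolog declares none).
#' @export
#' @examples
#' f <- tempfile(fileext = ".xml")
#' writeLines("<article><front></front></article>", f)
#' doc <- read_jats(f)
#' substr(doc$content, 1, 9)
read_jats <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read JATS file (no such file): ", path, call. = FALSE)
  }
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) == 0) {
    stop("empty JATS file: ", path, call. = FALSE)
  }
  # sniff the prolog as Latin-1: always decodable, ASCII-compatible
  head_txt <- iconv(list(bytes[seq_len(min(length(bytes), 400L))]),
                    from = "latin1", to = "UTF-8")
  declared <- stringi::stri_match_first_regex(
    head_txt, "encoding\\s*=\\s*[\"']([^\"']+)[\"']"
  )[, 2]

  decode <- function(from) {
    out <- tryCatch(iconv(list(bytes), from = from, to = "UTF-8"),
                    error = function(e) NA_character_)
    out
  }
  content <- NA_character_
  if (!is.na(declared)) content <- decode(declared)
  if (is.na(content)) {
    if (!is.na(declared)) log_event("read_jats", paste0(path, ": declared encoding '", declared, "' failed, trying UTF-8"))
    content <- decode("UTF-8")
  }
  if (is.na(content)) {
    log_event("read_jats", paste0(path, ": not valid UTF-8, decoded as Latin-1"))
    content <- decode("latin1")
  }
  if (is.na(content) || !nzchar(content)) {
    stop("could not decode JATS file: ", path, call. = FALSE)
  }
  structure(
    list(source_path = path, content = content, declared_encoding = declared),
    class = "jats_document"
  )
}

#' @export
print.jats_document <- function(x, ...) {
  cat("<jats_document> ", x$source_path, " (",
      nchar(x$content), " chars)\n", sep = "")
  invisible(x)
}

as_jats_document <- function(x) {
  if (inherits(x, "jats_document")) return(x)
  if (is.character(x) && length(x) >= 1) {
    return(structure(
      list(source_path = NA_character_,
           content = paste(x, collapse = "\n"),
           declared_encoding = NA_character_),
      class = "jats_document"
    ))
  }
  stop("expected a jats_document or a character string", call. = FALSE)
}

#' Extract all occurrences of an element from a document
#'
#' Locates every top-level occurrence of `tag_name` by balanced-tag
#' scanning, so extraction works even when the surrounding document is not
#' well-formed XML. Namespace prefixes are ignored: `<mml:math>` is found
#' under `tag_name = "math"`. Comments are masked before scanning.
#'
#' @param doc a `jats_document` (or a character string of XML).
#' @param tag_name plain element name, without angle brackets or prefix.
#' @return A list of `jats_fragment` objects in document order, each with
#'   `tag_name`, `raw_xml` (the full element) and `attributes` (named
#'   character vector). Absence gives an empty list, never an error.
#' @export
#' @examples
#' frs <- extract_fragments("<a><kwd>x</kwd><kwd a='1'>y</kwd></a>", "kwd")
#' length(frs)
#' frs[[2]]$attributes
extract_fragments <- function(doc, tag_name) {
  doc <- as_jats_document(doc)
  if (!grepl("^[A-Za-z][A-Za-z0-9._-]*$", tag_name)) {
    stop("tag_name must be a plain element name: ", tag_name, call. = FALSE)
  }
  x <- stringi::stri_replace_all_regex(doc$content, "(?s)<!--.*?-->", "")
  esc <- stringi::stri_replace_all_regex(tag_name, "([.\\-])", "\\\\$1")
  open_pat <- paste0("<(?:[A-Za-z0-9._\\-]+:)?", esc, "(?=[\\s/>])[^>]*>")
  close_pat <- paste0("</(?:[A-Za-z0-9._\\-]+:)?", esc, "\\s*>")

  op <- stringi::stri_locate_all_regex(x, open_pat)[[1]]
  cl <- stringi::stri_locate_all_regex(x, close_pat)[[1]]
  if (all(is.na(op[, 1]))) return(list())
  op <- op[!is.na(op[, 1]), , drop = FALSE]
  cl <- cl[!is.na(cl[, 1]), , drop = FALSE]

  pos <- c(op[, 1], cl[, 1])
  end <- c(op[, 2], cl[, 2])
  is_open <- rep(c(TRUE, FALSE), c(nrow(op), nrow(cl)))
  self_close <- c(stringi::stri_sub(x, op[, 2] - 1L, op[, 2]) == "/>",
                  rep(FALSE, nrow(cl)))
  o <- order(pos)
  pos <- pos[o]; end <- end[o]; is_open <- is_open[o]; self_close <- self_close[o]

  out <- list()
  depth <- 0L
  start <- NA_integer_
  for (i in seq_along(pos)) {
    if (is_open[i]) {
      if (self_close[i]) {
        if (depth == 0L) out[[length(out) + 1L]] <- c(pos[i], end[i])
      } else {
        if (depth == 0L) start <- pos[i]
        depth <- depth + 1L
      }
    } else {
      if (depth > 0L) {
        depth <- depth - 1L
        if (depth == 0L) {
          out[[length(out) + 1L]] <- c(start, end[i])
          start <- NA_integer_
        }
      }
    }
  }
  if (depth > 0L && !is.na(start)) {
    log_event("extract_fragments",
              paste0("unclosed <", tag_name, "> element skipped"))
  }
  lapply(out, function(rng) {
    raw_xml <- stringi::stri_sub(x, rng[1], rng[2])
    new_fragment(tag_name, raw_xml)
  })
}

new_fragment <- function(tag_name, raw_xml) {
  open_tag <- stringi::stri_match_first_regex(raw_xml, "(?s)^<[^>]*>")[, 1]
  attrs <- parse_attributes(open_tag %||% "")
  structure(
    list(tag_name = tag_name, raw_xml = raw_xml, attributes = attrs),
    class = "jats_fragment"
  )
}

parse_attributes <- function(open_tag) {
  m <- stringi::stri_match_all_regex(
    open_tag, "([A-Za-z_][A-Za-z0-9_.:\\-]*)\\s*=\\s*(\"[^\"]*\"|'[^']*')"
  )[[1]]
  if (nrow(m) == 0 || all(is.na(m[, 1]))) return(stats::setNames(character(), character()))
  vals <- stringi::stri_sub(m[, 3], 2, -2)
  stats::setNames(vals, m[, 2])
}

#' @export
print.jats_fragment <- function(x, ...) {
  cat("<jats_fragment> <", x$tag_name, "> ",
      nchar(x$raw_xml), " chars\n", sep = "")
  invisible(x)
}

# element content without its own outer tags; "" for self-closing elements
inner_xml <- function(frag) {
  raw <- if (inherits(frag, "jats_fragment")) frag$raw_xml else frag
  if (stringi::stri_detect_regex(raw, "(?s)^<[^>]*/>$")) return("")
  stringi::stri_replace_first_regex(
    stringi::stri_replace_last_regex(raw, "(?s)</[^>]*>$", ""),
    "(?s)^<[^>]*>", ""
  )
}

# drop every remaining tag, separating with spaces so words never merge
strip_tags <- function(x, sep = " ") {
  out <- stringi::stri_replace_all_regex(x, "(?s)<[^>]*>", sep)
  stringi::stri_trim_both(stringi::stri_replace_all_regex(out, "[ \t]+", " "))
}
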
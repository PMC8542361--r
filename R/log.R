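#' Session log of decoding irregularities
#'
#' Extractors never fail on irregular content; instead they record what
#' they had to skip or leave verbatim (malformed entities, duplicate date
#' labels, invalid dates, nameless contributors, unreadable files,
#' image-only formulas). The log accumulates per session.
#'
#' @param clear logical; if `TRUE`, empty the log after returning it.
#' @return A tibble with columns `context`, `message`.
#' @export
#' @examples
#' convert_letters("bad &#x; entity")
#' jats_log()
jats_log <- function(clear = FALSE) {
  entries <- the$log %||% list()
  out <- if (length(entries)) {
    tibble::tibble(
      context = vapply(entries, `[[`, "", "context"),
      message = vapply(entries, `[[`, "", "message")
    )
  } else {
    tibble::tibble(context = character(), message = character())
  }
  if (clear) the$log <- list()
  out
}

log_event <- function(context, message) {
  the$log <- c(the$log %||% list(), list(list(context = context, message = message)))
  invisible(NULL)
}
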
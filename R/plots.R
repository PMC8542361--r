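# ggplot2 views of the profiler tables.

#' @describeIn tag_use_table Line plot of tag-use frequency per period,
#'   one line per content element.
#' @param object a `jats_tag_use` table.
#' @param ... unused.
#' @export
autoplot.jats_tag_use <- function(object, ...) {
  df <- object[object$element != "total_n", , drop = FALSE]
  long <- tidyr::pivot_longer(df, cols = -c("element", "total"),
                              names_to = "period", values_to = "frequency")
  long$period <- factor(long$period, levels = setdiff(names(df), c("element", "total")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$period, y = .data$frequency,
                                     colour = .data$element,
                                     group = .data$element)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "publishing period", y = "records with extractable content",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Frequency bar chart for a corpus field
#'
#' The data behind the type/keyword/name distributions: top labels of a
#' [frequency_table()], on a log-scaled count axis.
#'
#' @param records a `jats_corpus` tibble.
#' @param field passed to [frequency_table()].
#' @param top_k labels shown.
#' @return A ggplot object.
#' @export
plot_field_counts <- function(records, field = "type", top_k = 25) {
  tab <- frequency_table(records, field, top_k = top_k)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$n,
                                    y = stats::reorder(.data$label, .data$n))) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "articles (log scale)", y = NULL,
                  title = paste("Most frequent", field, "labels")) +
    ggplot2::theme_minimal()
}

#' Editorial-lag distribution
#'
#' Histograms of time to accept and time to publish in days; negative
#' values flag date-stamp errors.
#'
#' @param records a `jats_corpus` tibble.
#' @return A ggplot object.
#' @export
plot_publication_lags <- function(records) {
  df <- tidyr::pivot_longer(
    records[, c("time_to_accept", "time_to_publish")],
    cols = dplyr::everything(), names_to = "lag", values_to = "days"
  )
  df <- df[!is.na(df$days), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$days)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "red") +
    ggplot2::facet_wrap(~lag, scales = "free") +
    ggplot2::labs(x = "days", y = "articles") +
    ggplot2::theme_minimal()
}
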
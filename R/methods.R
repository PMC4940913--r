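# Tidiers and plots for the result containers.

#' Tidy a counts table into long form
#'
#' @param x A `tag_counts` tibble.
#' @param ... Unused.
#' @return A tibble with one row per (sample, tag): `sample`, `marker`,
#'   `allele`, `tag_name`, `count`.
#' @export
tidy.tag_counts <- function(x, ...) {
  info <- attr(x, "tag_info")
  long <- tidyr::pivot_longer(as_tibble(x), -"sample",
                              names_to = "tag_name",
                              values_to = "count")
  if (!is.null(info)) {
    long <- left_join(long, info, by = "tag_name")
  }
  long[c("sample", "marker", "allele", "tag_name", "count")]
}

#' One-row summary of a counting run
#'
#' @param x A `tag_counts` tibble.
#' @param ... Unused.
#' @return A tibble with `n_samples`, `n_tags`, `n_markers`,
#'   `total_reads`, `matched_reads`, `discarded_reads` (read tallies are
#'   `NA` when `x` was read back from CSV rather than counted).
#' @export
glance.tag_counts <- function(x, ...) {
  info <- attr(x, "tag_info")
  d <- attr(x, "discards")
  tibble(
    n_samples = nrow(x),
    n_tags = ncol(x) - 1L,
    n_markers = if (!is.null(info)) length(unique(info$marker)) else NA_integer_,
    total_reads = if (!is.null(d)) sum(d$reads) else NA_integer_,
    matched_reads = if (!is.null(d)) sum(d$matched) else NA_integer_,
    discarded_reads = if (!is.null(d)) sum(d$discarded) else NA_integer_
  )
}

#' Tidy a genotype table into long form
#'
#' @param x A `tag_genotypes` tibble.
#' @param ... Unused.
#' @return A tibble with columns `sample`, `marker`, `genotype`.
#' @export
tidy.tag_genotypes <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"sample", names_to = "marker",
                      values_to = "genotype")
}

#' Plot a counts table
#'
#' `type = "depth"` shows the distribution of non-zero per-cell read
#' depths (log10 x axis), the first thing to inspect when deciding depth
#' thresholds for genotype calling; `type = "sample"` shows total
#' matched reads per sample, which flags failed barcodes.
#'
#' @param object A `tag_counts` tibble.
#' @param type `"depth"` or `"sample"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tag_counts <- function(object, type = c("depth", "sample"), ...) {
  type <- match.arg(type)
  long <- tidy.tag_counts(object)
  if (type == "depth") {
    ggplot2::ggplot(dplyr::filter(long, .data$count > 0),
                    ggplot2::aes(x = .data$count)) +
      ggplot2::geom_histogram(bins = 30) +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "reads per sample x tag cell (non-zero)",
                    y = "cells")
  } else {
    per <- long %>% group_by(.data$sample) %>%
      summarise(reads = sum(.data$count), .groups = "drop")
    ggplot2::ggplot(per, ggplot2::aes(x = .data$sample, y = .data$reads)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "sample", y = "matched reads") +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                         vjust = 0.5))
  }
}
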
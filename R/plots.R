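# ggplot2 views of the standard result tables.

#' Plot a read length distribution
#'
#' Bars of total read fraction per insert length, with the distinct-tag
#' fraction overlaid as points.
#'
#' @param x Tibble from [length_distribution()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(x, ...) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$total_fraction),
                      fill = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$distinct_fraction)) +
    ggplot2::labs(x = "read length (nt)", y = "fraction of reads",
                  title = "Small RNA length distribution") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.mir_length_dist <- function(object, ...) {
  plot_length_distribution(object, ...)
}

#' Plot the read-class partition
#'
#' @param x Tibble from [summarize_classes()].
#' @param weight `"total"` (count-weighted) or `"distinct"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot_class_summary <- function(x, weight = c("total", "distinct"), ...) {
  weight <- match.arg(weight)
  col <- paste0(weight, "_fraction")
  ggplot2::ggplot(x, ggplot2::aes(
    x = stats::reorder(.data$class, .data[[col]]),
    y = .data[[col]])) +
    ggplot2::geom_col(fill = "darkolivegreen") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = paste(weight, "fraction"),
                  title = "Read classes") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.mir_class_summary <- function(object, ...) {
  plot_class_summary(object, ...)
}

#' Plot candidate MFEI against precursor length
#'
#' The conventional 0.85 MFEI screen is drawn as a dashed line.
#'
#' @param x Candidate tibble from [predict_mirnas()].
#' @param mfei_min Screen threshold to draw (default 0.85).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot_mfei <- function(x, mfei_min = 0.85, ...) {
  ggplot2::ggplot(x, ggplot2::aes(x = nchar(.data$pre_seq), y = .data$mfei)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$star_supported)) +
    ggplot2::geom_hline(yintercept = mfei_min, linetype = "dashed") +
    ggplot2::labs(x = "precursor length (nt)", y = "MFEI",
                  title = "Hairpin candidates") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.mir_candidates <- function(object, ...) plot_mfei(object, ...)

#' Tidy and summarise pipeline runs
#'
#' `tidy()` returns the confirmed candidate table (or library A's
#' candidates for single-library runs); `glance()` a one-row run
#' summary.
#'
#' @param x A `germmir_run`.
#' @param ... Ignored.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.germmir_run <- function(x, ...) {
  out <- if (!is.null(x$confirmed)) x$confirmed else x$libs$A$candidates
  tibble::as_tibble(out)
}

#' @rdname tidy.germmir_run
#' @exportS3Method generics::glance
glance.germmir_run <- function(x, ...) {
  tibble::tibble(
    n_libraries = length(x$libs),
    raw_reads = sum(vapply(x$log, function(l) l$raw, numeric(1))),
    distinct_reads = sum(vapply(x$log, function(l) l$distinct, numeric(1))),
    n_candidates = sum(x$summary$n_candidates),
    n_confirmed = x$summary$n_confirmed,
    n_families = max(x$families$family, 0L),
    n_targeted_mirnas = x$summary$n_targeted_mirnas,
    elapsed_s = x$elapsed
  )
}
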
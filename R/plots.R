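#' Plot fragment statistics
#'
#' Contrasts the length distribution of whole RNAs with that of their
#' independent fragments, the usual first look at how much a partitioning
#' step shortens the folding problems.
#'
#' @param object A [fragment_stats()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fragment_stats <- function(object, ...) {
  lengths <- dplyr::bind_rows(
    tibble::tibble(what = "RNA", length = object$per_rna$length),
    tibble::tibble(what = "i-fragment",
                   length = object$fragments$fragment_length)
  )
  ggplot2::ggplot(lengths, ggplot2::aes(x = .data$length,
                                        fill = .data$what)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.55, bins = 40) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "length (nt)", y = "count", fill = NULL,
                  title = "Whole RNAs vs independent fragments") +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' @param object A trained `rna_labeler`.
#' @param ... Unused.
#' @return A ggplot object with loss and validation MCC per epoch.
#' @export
autoplot.rna_labeler <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, c("train_loss", "val_mcc"),
                              names_to = "series")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a base-composition contrast
#'
#' @param composition A [context_composition()] tibble.
#' @return A grouped bar chart of per-base frequencies in the exterior-loop
#'   vs non-exterior-loop context groups.
#' @export
plot_composition <- function(composition) {
  long <- tidyr::pivot_longer(
    composition, c("freq_exterior", "freq_non_exterior"),
    names_to = "group", values_to = "frequency"
  ) |>
    dplyr::mutate(group = ifelse(.data$group == "freq_exterior",
                                 "exterior loop", "non-exterior"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$base, y = .data$frequency,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "frequency", fill = NULL,
                  title = "Sequence context composition by label") +
    ggplot2::theme_minimal()
}

#' Plot paired with/without-partition performance
#'
#' @param evaluation Result of [evaluate_with_without()].
#' @return A scatter plot of per-RNA pair-level F1, partitioned vs direct.
#' @export
plot_with_without <- function(evaluation) {
  per <- evaluation$per_rna
  ggplot2::ggplot(per, ggplot2::aes(x = .data$F1_without,
                                    y = .data$F1_with)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "pair-level F1, direct fold",
                  y = "pair-level F1, partition + assemble") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
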
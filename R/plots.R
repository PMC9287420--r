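#' Plot feature-category break densities
#'
#' Bar chart of breaks/Mb per genomic feature category.
#'
#' @param object an `annotation_summary` from [annotate_breaks()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.annotation_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$category, y = .data$density_per_mb)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "breaks / Mb",
                  title = "Break density by genomic feature") +
    ggplot2::theme_minimal()
}

#' Plot a TSS metaprofile
#'
#' Break density as a function of strand-oriented distance from the TSS.
#'
#' @param object a `tss_metaprofile` from [tss_metaprofile()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.tss_metaprofile <- function(object, ...) {
  mid <- (object$bin_start + object$bin_end) / 2
  ggplot2::ggplot(mutate(as_tibble(object), mid = mid),
                  ggplot2::aes(x = .data$mid, y = .data$density)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "distance from TSS (bp, downstream positive)",
                  y = "breaks / gene / M library breaks") +
    ggplot2::theme_minimal()
}

#' Plot an expression-decile coverage comparison
#'
#' Boxplot-style summaries (median, quartiles, 5/95% whiskers) of per-gene
#' TSS break coverage by expression decile and sample.
#'
#' @param object a `decile_comparison`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.decile_comparison <- function(object, ...) {
  ggplot2::ggplot(object$box,
                  ggplot2::aes(x = factor(.data$expression_bin),
                               fill = .data$sample,
                               ymin = .data$q05, lower = .data$q25,
                               middle = .data$median, upper = .data$q75,
                               ymax = .data$q95)) +
    ggplot2::geom_boxplot(stat = "identity",
                          position = ggplot2::position_dodge(width = 0.8),
                          width = 0.7) +
    ggplot2::labs(x = "expression decile (1 = lowest FPKM)",
                  y = "TSS window coverage",
                  title = "Break coverage by expression decile") +
    ggplot2::theme_minimal()
}

#' Plot gene-length association of body break coverage
#'
#' Mean per-kb gene-body coverage by gene-length decile.
#'
#' @param object a `length_association`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.length_association <- function(object, ...) {
  ggplot2::ggplot(object$per_bin,
                  ggplot2::aes(x = factor(.data$length_bin),
                               y = .data$mean_coverage)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "gene length decile (1 = shortest)",
                  y = "body breaks / kb / M library breaks") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
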
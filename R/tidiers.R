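#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a break extraction
#'
#' @param x a `break_extraction` object.
#' @param ... unused.
#' @return the break tibble (`chrom`, `pos`, `sample`).
#' @export
tidy.break_extraction <- function(x, ...) x$breaks

#' One-row QC summary of a break extraction
#'
#' @param x a `break_extraction` object.
#' @param ... unused.
#' @return the one-row counter tibble.
#' @export
glance.break_extraction <- function(x, ...) x$report

#' @export
tidy.decile_comparison <- function(x, ...) x$tests

#' @export
glance.decile_comparison <- function(x, ...) {
  tibble(n_bins = nrow(x$tests),
         n_significant = sum(x$tests$p_value < 0.05),
         min_p = min(x$tests$p_value))
}

#' @export
glance.paired_wilcoxon <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         n_pairs_used = x$n_pairs_used, direction = x$direction,
         degenerate = x$degenerate, method = x$method)
}

#' @export
tidy.length_association <- function(x, ...) x$per_bin

#' @export
glance.length_association <- function(x, ...) {
  mutate(x$spearman, degenerate = x$degenerate)
}

#' @export
tidy.feature_partition <- function(x, ...) as_tibble(x$intervals)

#' @export
glance.feature_partition <- function(x, ...) {
  tidyr::pivot_wider(x$territory, names_from = "category",
                     values_from = "territory_bp")
}
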
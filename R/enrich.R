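#' Call per-gene TSS break enrichment between two conditions
#'
#' Computes, for every expressed gene (FPKM > 0), the depth-corrected fold
#' change of case over control TSS-window break counts and returns the
#' genes exceeding the fold-change threshold, ranked. The fold change is
#' `((count_case + pseudocount) / lib_case) / ((count_control +
#' pseudocount) / lib_control)`: the pseudocount stabilizes near-zero
#' counts and the library ratio corrects for sequencing depth. Genes with
#' fewer than `min_support` raw breaks across the two samples are not
#' called.
#'
#' @param cov_case,cov_control per-gene count tibbles (`gene_id`, `count`)
#'   from [tss_window_counts()] with `half_width = 250`, over the same gene
#'   universe.
#' @param expr expression tibble (`gene_id`, `fpkm`).
#' @param lib_case,lib_control library sizes (total retained breaks).
#' @param fc_threshold minimum fold change to call (exclusive).
#' @param min_support minimum `count_case + count_control`.
#' @param pseudocount added to both raw counts before forming the ratio.
#' @return an `enrichment_calls` tibble of called genes: `gene_id`,
#'   `count_case`, `count_control`, `norm_case`, `norm_control` (per
#'   million), `fold_change`, `fpkm`, `rank`, sorted by descending fold
#'   change (ties by gene_id). The full per-gene table (all expressed
#'   genes, uncalled included) is attached as attribute `all_genes`.
#' @export
call_enriched <- function(cov_case, cov_control, expr,
                          lib_case, lib_control,
                          fc_threshold = 1.5, min_support = 5,
                          pseudocount = 0.5) {
  universe <- inner_join(rename(cov_case, count_case = "count"),
                         rename(cov_control, count_control = "count"),
                         by = "gene_id") |>
    inner_join(expr, by = "gene_id") |>
    filter(.data$fpkm > 0)
  if (nrow(universe) == 0) abort("empty expressed-gene universe")

  universe <- universe |>
    mutate(
      norm_case = normalize_library(.data$count_case, lib_case),
      norm_control = normalize_library(.data$count_control, lib_control),
      fold_change = ((.data$count_case + pseudocount) / lib_case) /
        ((.data$count_control + pseudocount) / lib_control),
      supported = .data$count_case + .data$count_control >= min_support
    )

  calls <- universe |>
    filter(.data$fold_change > fc_threshold, .data$supported) |>
    arrange(desc(.data$fold_change), .data$gene_id) |>
    mutate(rank = row_number()) |>
    select("gene_id", "count_case", "count_control", "norm_case",
           "norm_control", "fold_change", "fpkm", "rank")
  attr(calls, "all_genes") <- universe
  attr(calls, "fc_threshold") <- fc_threshold
  class(calls) <- c("enrichment_calls", class(calls))
  calls
}

#' Check whether enrichment calls are driven by expression level
#'
#' Compares the FPKM distribution of called genes with that of all
#' expressed genes (two-sample Wilcoxon rank-sum test plus a quantile
#' overlay), to ask whether the called set is merely an expression-shifted
#' sample rather than genuinely break-enriched.
#'
#' @param calls an `enrichment_calls` tibble.
#' @param expr expression tibble (`gene_id`, `fpkm`).
#' @param min_calls below this call count the summary is flagged
#'   underpowered.
#' @return a list with `n_called`, `underpowered`, `p_value` (NA when
#'   underpowered), `shifted` (p < 0.05), and `quantiles` (tibble of FPKM
#'   quantiles for the called and the expressed-gene background).
#' @export
enrichment_vs_expression <- function(calls, expr, min_calls = 5) {
  expressed <- filter(expr, .data$fpkm > 0)
  called <- filter(expressed, .data$gene_id %in% calls$gene_id)
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  quantiles <- tibble(
    quantile = qs,
    called = if (nrow(called) > 0) {
      quantile(called$fpkm, qs, type = 7, names = FALSE)
    } else {
      NA_real_
    },
    background = quantile(expressed$fpkm, qs, type = 7, names = FALSE)
  )
  if (nrow(called) < min_calls) {
    return(list(n_called = nrow(called), underpowered = TRUE,
                p_value = NA_real_, shifted = NA, quantiles = quantiles))
  }
  wt <- suppressWarnings(
    wilcox.test(called$fpkm, expressed$fpkm, alternative = "two.sided"))
  list(n_called = nrow(called), underpowered = FALSE,
       p_value = wt$p.value, shifted = wt$p.value < 0.05,
       quantiles = quantiles)
}
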
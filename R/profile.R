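#' Bin genes into expression deciles
#'
#' Genes with FPKM > 0 are ranked ascending by FPKM (ties broken by
#' `gene_id`, so the cut is deterministic) and divided into `n_bins`
#' rank-based bins of near-equal size (sizes differ by at most 1). Bin
#' `n_bins` holds the most highly expressed genes. Genes with FPKM = 0 are
#' excluded and counted.
#'
#' @param expr expression tibble (`gene_id`, `fpkm`).
#' @param n_bins number of bins (default 10, i.e. deciles).
#' @return tibble `gene_id`, `fpkm`, `expression_bin` (integer 1..n_bins)
#'   for the FPKM > 0 genes, with the number of excluded zero-FPKM genes
#'   as attribute `n_zero_excluded`.
#' @export
bin_genes_by_expression <- function(expr, n_bins = 10) {
  pos <- filter(expr, .data$fpkm > 0)
  n_zero <- nrow(expr) - nrow(pos)
  if (nrow(pos) < n_bins) {
    abort(sprintf("need at least %d genes with FPKM > 0, have %d",
                  n_bins, nrow(pos)))
  }
  pos <- arrange(pos, .data$fpkm, .data$gene_id)
  # rank cut into n_bins near-equal groups, lowest expression first
  pos$expression_bin <- as.integer(
    ceiling(seq_len(nrow(pos)) / nrow(pos) * n_bins))
  attr(pos, "n_zero_excluded") <- n_zero
  pos
}

#' Per-gene break counts in a TSS-centered window
#'
#' Counts, for each gene, the breaks of one sample whose position falls in
#' `[TSS - half_width, TSS + half_width)`, with the TSS at `tx_start` for +
#' genes and `tx_end - 1` for - genes. No priority resolution is applied: a
#' break inside two genes' windows counts for both (overlapping genes are
#' reported as such downstream).
#'
#' @param breaks break tibble from one sample.
#' @param genes gene tibble.
#' @param half_width window half-width in bp (500 for coverage boxplots,
#'   250 for enrichment calling).
#' @return tibble `gene_id`, `count`.
#' @export
tss_window_counts <- function(breaks, genes, half_width = 500) {
  anchored <- add_gene_anchors(genes)
  counts <- integer(nrow(genes))
  for (cr in unique(anchored$chrom)) {
    gi <- which(anchored$chrom == cr)
    bp <- breaks$pos[breaks$chrom == cr]
    if (length(bp) == 0) next
    wins <- IRanges::IRanges(anchored$tss[gi] - half_width + 1,
                             anchored$tss[gi] + half_width)
    pts <- IRanges::IRanges(bp + 1, width = 1)
    counts[gi] <- IRanges::countOverlaps(wins, pts)
  }
  tibble(gene_id = anchored$gene_id, count = counts)
}

#' Library-size normalization
#'
#' Scales raw window counts to breaks per million library breaks, so
#' samples sequenced to different depths are comparable.
#'
#' @param counts numeric vector of raw counts.
#' @param library_size total retained breaks of the sample (> 0).
#' @return numeric vector of per-million counts.
#' @export
normalize_library <- function(counts, library_size) {
  if (is.na(library_size) || library_size <= 0) {
    abort("library_size must be > 0")
  }
  counts * 1e6 / library_size
}

#' Strand-oriented TSS metaprofile
#'
#' Maps each break near a TSS to its transcription-oriented offset
#' (downstream positive), histograms offsets into fixed-width bins tiling
#' `[-flank, flank)`, and normalizes by gene count and library size. A
#' break inside several genes' flanks contributes to each.
#'
#' @param breaks break tibble from one sample.
#' @param genes gene tibble (typically an expression-decile subset).
#' @param flank half-width of the profiled region in bp.
#' @param bin_width histogram bin width in bp (`flank` must be a multiple).
#' @param library_size total retained breaks of the sample; defaults to
#'   `nrow(breaks)`.
#' @return a `tss_metaprofile` tibble: `bin_start`, `bin_end` (offsets),
#'   `count`, `density` (= count / n_genes / million library breaks), with
#'   `n_genes` and `library_size` attributes.
#' @export
tss_metaprofile <- function(breaks, genes, flank = 2000, bin_width = 100,
                            library_size = nrow(breaks)) {
  if (nrow(genes) == 0) abort("metaprofile needs a nonempty gene subset")
  if (flank %% bin_width != 0) abort("flank must be a multiple of bin_width")
  anchored <- add_gene_anchors(genes)
  offsets <- double(0)
  for (cr in unique(anchored$chrom)) {
    gi <- which(anchored$chrom == cr)
    bp <- breaks$pos[breaks$chrom == cr]
    if (length(bp) == 0) next
    wins <- IRanges::IRanges(anchored$tss[gi] - flank + 1,
                             anchored$tss[gi] + flank)
    pts <- IRanges::IRanges(bp + 1, width = 1)
    ov <- IRanges::findOverlaps(pts, wins)
    g <- gi[S4Vectors::subjectHits(ov)]
    p <- bp[S4Vectors::queryHits(ov)]
    off <- ifelse(anchored$strand[g] == "+",
                  p - anchored$tss[g], anchored$tss[g] - p)
    offsets <- c(offsets, off[off >= -flank & off < flank])
  }
  edges <- seq(-flank, flank, by = bin_width)
  counts <- if (length(offsets) > 0) {
    tabulate(findInterval(offsets, edges), nbins = length(edges) - 1)
  } else {
    integer(length(edges) - 1)
  }
  out <- tibble(
    bin_start = edges[-length(edges)],
    bin_end = edges[-1],
    count = counts,
    density = counts / nrow(genes) / (library_size / 1e6)
  )
  attr(out, "n_genes") <- nrow(genes)
  attr(out, "library_size") <- library_size
  class(out) <- c("tss_metaprofile", class(out))
  out
}

#' Expression-decile condition comparison
#'
#' For each expression bin, runs a paired two-sided Wilcoxon signed-rank
#' test between two samples' per-gene normalized TSS window coverage, and
#' summarizes each sample's distribution as boxplot statistics (quartiles,
#' median, 5/95% whiskers; linear-interpolation quantiles).
#'
#' @param cov_a,cov_b per-gene coverage tibbles (`gene_id`, `count`) from
#'   [tss_window_counts()] for the two samples, over the same gene universe.
#' @param bins expression-bin tibble from [bin_genes_by_expression()].
#' @param labels length-2 character vector naming the samples.
#' @param lib_a,lib_b library sizes used for per-million normalization
#'   (defaults: total counts are taken as given, i.e. no rescaling).
#' @return a `decile_comparison` object with `tests` (per-bin tibble:
#'   `expression_bin`, `n_genes`, `statistic`, `p_value`, `direction`) and
#'   `box` (per-bin, per-sample quantile tibble). [tidy()] returns `tests`.
#' @export
decile_comparison <- function(cov_a, cov_b, bins, labels = c("a", "b"),
                              lib_a = NULL, lib_b = NULL) {
  universe <- inner_join(rename(cov_a, a = "count"),
                         rename(cov_b, b = "count"), by = "gene_id") |>
    inner_join(select(bins, "gene_id", "expression_bin"), by = "gene_id")
  if (!is.null(lib_a)) universe$a <- normalize_library(universe$a, lib_a)
  if (!is.null(lib_b)) universe$b <- normalize_library(universe$b, lib_b)

  tests <- list()
  box <- list()
  for (bin in sort(unique(universe$expression_bin))) {
    sub <- universe[universe$expression_bin == bin, , drop = FALSE]
    if (nrow(sub) < 2) {
      inform(sprintf("expression bin %d has < 2 genes; skipped", bin))
      next
    }
    wt <- paired_wilcoxon(sub$a, sub$b)
    tests[[length(tests) + 1]] <- tibble(
      expression_bin = bin, n_genes = nrow(sub),
      statistic = wt$statistic, p_value = wt$p_value,
      direction = unname(c("x>y" = labels[1], "x<y" = labels[2],
                           none = "none")[wt$direction]),
      degenerate = wt$degenerate
    )
    qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
    for (i in 1:2) {
      v <- if (i == 1) sub$a else sub$b
      q <- quantile(v, qs, type = 7, names = FALSE)
      box[[length(box) + 1]] <- tibble(
        expression_bin = bin, sample = labels[i],
        q05 = q[1], q25 = q[2], median = q[3], q75 = q[4], q95 = q[5],
        mean = mean(v)
      )
    }
  }
  structure(list(tests = bind_rows(tests), box = bind_rows(box),
                 labels = labels),
            class = "decile_comparison")
}

#' @export
print.decile_comparison <- function(x, ...) {
  cat(sprintf("<decile_comparison> %s vs %s, %d bins\n",
              x$labels[1], x$labels[2], nrow(x$tests)))
  print(x$tests)
  invisible(x)
}

#' Gene-length association of gene-body break coverage
#'
#' Bins genes into rank-based length deciles and relates gene length to
#' per-kb gene-body break coverage: breaks in the oriented body window
#' `[TSS + inner_flank, TTS - inner_flank)` divided by body length in kb
#' and library size (per million). The trend statistic is the Spearman rank
#' correlation of gene length with normalized body coverage, the signature
#' of replication-stress-associated breakage of long genes.
#'
#' @param breaks break tibble from one sample.
#' @param genes gene tibble; genes whose body window is empty are dropped.
#' @param library_size total retained breaks of the sample.
#' @param n_length_bins number of length bins.
#' @param inner_flank bp excluded at each gene end (the TSS/TTS windows).
#' @return a `length_association` object with `per_gene` (gene_id,
#'   gene_length, body_count, coverage_per_kb_pm, length_bin), `per_bin`
#'   summaries, and `spearman` (estimate, p_value, n). [glance()] returns
#'   the trend row; `degenerate` is `TRUE` when all lengths are equal.
#' @export
length_association <- function(breaks, genes, library_size = nrow(breaks),
                               n_length_bins = 10, inner_flank = 250) {
  anchored <- add_gene_anchors(genes)
  anchored$body_start <- anchored$tx_start + inner_flank
  anchored$body_end <- anchored$tx_end - inner_flank
  anchored <- filter(anchored, .data$body_end > .data$body_start)
  if (nrow(anchored) == 0) abort("no gene has a nonempty body window")

  counts <- integer(nrow(anchored))
  for (cr in unique(anchored$chrom)) {
    gi <- which(anchored$chrom == cr)
    bp <- breaks$pos[breaks$chrom == cr]
    if (length(bp) == 0) next
    wins <- IRanges::IRanges(anchored$body_start[gi] + 1, anchored$body_end[gi])
    counts[gi] <- IRanges::countOverlaps(wins, IRanges::IRanges(bp + 1, width = 1))
  }

  per_gene <- tibble(
    gene_id = anchored$gene_id,
    gene_length = anchored$gene_length,
    body_length_kb = (anchored$body_end - anchored$body_start) / 1e3,
    body_count = counts
  ) |>
    mutate(coverage_per_kb_pm =
             normalize_library(.data$body_count, library_size) /
             .data$body_length_kb)

  degenerate <- length(unique(per_gene$gene_length)) == 1
  if (degenerate) {
    per_gene$length_bin <- 1L
    spearman <- tibble(estimate = NA_real_, p_value = NA_real_,
                       n = nrow(per_gene))
    inform("all genes have the same length; length trend undefined")
  } else {
    ord <- order(per_gene$gene_length, per_gene$gene_id)
    bin <- integer(nrow(per_gene))
    bin[ord] <- as.integer(ceiling(seq_along(ord) / length(ord) * n_length_bins))
    per_gene$length_bin <- bin
    ct <- suppressWarnings(
      cor.test(per_gene$gene_length, per_gene$coverage_per_kb_pm,
               method = "spearman", exact = FALSE))
    spearman <- tibble(estimate = unname(ct$estimate),
                       p_value = ct$p.value, n = nrow(per_gene))
  }

  per_bin <- per_gene |>
    group_by(.data$length_bin) |>
    summarise(n_genes = n(),
              median_length = stats::median(.data$gene_length),
              mean_coverage = mean(.data$coverage_per_kb_pm),
              median_coverage = stats::median(.data$coverage_per_kb_pm),
              .groups = "drop")

  structure(list(per_gene = per_gene, per_bin = per_bin, spearman = spearman,
                 degenerate = degenerate),
            class = "length_association")
}

#' @export
print.length_association <- function(x, ...) {
  if (x$degenerate) {
    cat("<length_association> degenerate: all genes the same length\n")
  } else {
    cat(sprintf("<length_association> Spearman rho = %.3f (p = %.3g, n = %d)\n",
                x$spearman$estimate, x$spearman$p_value, x$spearman$n))
  }
  invisible(x)
}
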
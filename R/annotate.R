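FEATURE_LEVELS <- c("tss", "promoter", "tts", "gene_body", "intergenic")

# Oriented windows around the TSS/TTS boundary coordinates. All intervals
# are 0-based half-open in chromosome coordinates. For a + gene with
# tx interval [s, e): tss = [s-250, s+250), promoter = [s-1000, s-250),
# body = [s+250, e-250), tts = [e-250, e+250). For a - gene the layout
# mirrors around the opposite boundary (upstream = larger coordinates).
#' Per-gene annotation windows
#'
#' Computes the four feature windows of one gene in its transcriptional
#' orientation: a TSS window of `tss_flank` bp either side of the start
#' boundary, an upstream promoter from `promoter_flank` to `tss_flank` bp
#' before it, the gene body between the inner window edges, and a TTS
#' window around the termination boundary. Windows are clipped to the
#' chromosome; a gene shorter than `2 * tss_flank` has an empty body.
#'
#' @param genes a gene tibble (`gene_id`, `chrom`, `strand`, `tx_start`,
#'   `tx_end`).
#' @param chrom_sizes tibble `chrom`, `length` used for clipping.
#' @param tss_flank,promoter_flank,tts_flank window sizes in bp.
#' @return a long tibble `gene_id`, `chrom`, `category`, `start`, `end`
#'   (0-based half-open; empty windows are dropped).
#' @export
gene_windows <- function(genes, chrom_sizes = NULL,
                         tss_flank = 250, promoter_flank = 1000,
                         tts_flank = 250) {
  plus <- genes$strand == "+"
  s <- genes$tx_start
  e <- genes$tx_end
  win <- function(category, start, end) {
    tibble(gene_id = genes$gene_id, chrom = genes$chrom, category = category,
           start = start, end = end)
  }
  out <- bind_rows(
    win("tss",
        ifelse(plus, s - tss_flank, e - tss_flank),
        ifelse(plus, s + tss_flank, e + tss_flank)),
    win("promoter",
        ifelse(plus, s - promoter_flank, e + tss_flank),
        ifelse(plus, s - tss_flank, e + promoter_flank)),
    win("gene_body",
        ifelse(plus, s + tss_flank, s + tts_flank),
        ifelse(plus, e - tts_flank, e - tss_flank)),
    win("tts",
        ifelse(plus, e - tts_flank, s - tts_flank),
        ifelse(plus, e + tts_flank, s + tts_flank))
  )
  out$start <- pmax(out$start, 0)
  if (!is.null(chrom_sizes)) {
    len <- setNames(chrom_sizes$length, chrom_sizes$chrom)
    out$end <- pmin(out$end, len[out$chrom])
  }
  filter(out, .data$end > .data$start)
}

#' Build the priority-resolved genome partition
#'
#' Partitions every chromosome into the five feature categories by
#' sequential subtraction at the category level: the TSS territory is the
#' union of all TSS windows; the promoter territory is the union of
#' promoter windows minus the TSS territory; then TTS, then gene body, each
#' minus everything above it; whatever remains is intergenic. The
#' categories are therefore mutually disjoint, every windowed bp belongs to
#' the highest-priority category claiming it (across genes, not within
#' one), and the territories tile the genome exactly.
#'
#' @inheritParams gene_windows
#' @return a `feature_partition` object: `intervals` (tibble `chrom`,
#'   `category`, `start`, `end`), `territory` (tibble `category`,
#'   `territory_bp`), plus the `chrom_sizes` used.
#' @export
build_partition <- function(genes, chrom_sizes, tss_flank = 250,
                            promoter_flank = 1000, tts_flank = 250) {
  missing <- setdiff(genes$chrom, chrom_sizes$chrom)
  if (length(missing) > 0) {
    abort(sprintf("gene chromosome(s) absent from chrom_sizes: %s",
                  paste(missing, collapse = ", ")))
  }
  wins <- gene_windows(genes, chrom_sizes, tss_flank, promoter_flank, tts_flank)

  # 1-based closed IRanges per chromosome and category
  to_ir <- function(df) IRanges::reduce(IRanges::IRanges(df$start + 1, df$end))
  ir_by_chrom <- lapply(setNames(chrom_sizes$chrom, chrom_sizes$chrom), function(cr) {
    len <- chrom_sizes$length[chrom_sizes$chrom == cr]
    genome <- IRanges::IRanges(1, len)
    claimed <- IRanges::IRanges()
    out <- list()
    for (cat in c("tss", "promoter", "tts", "gene_body")) {
      w <- wins[wins$chrom == cr & wins$category == cat, , drop = FALSE]
      terr <- IRanges::setdiff(to_ir(w), claimed)
      out[[cat]] <- terr
      claimed <- IRanges::reduce(IRanges::union(claimed, terr))
    }
    out[["intergenic"]] <- IRanges::setdiff(genome, claimed)
    out
  })

  intervals <- purrr::imap_dfr(ir_by_chrom, function(cats, cr) {
    purrr::imap_dfr(cats, function(ir, cat) {
      tibble(chrom = cr, category = cat,
             start = IRanges::start(ir) - 1, end = IRanges::end(ir))
    })
  })
  territory <- intervals |>
    group_by(category = factor(.data$category, levels = FEATURE_LEVELS)) |>
    summarise(territory_bp = sum(.data$end - .data$start), .groups = "drop") |>
    tidyr::complete(category = factor(FEATURE_LEVELS, levels = FEATURE_LEVELS),
                    fill = list(territory_bp = 0))

  structure(list(intervals = intervals, territory = territory,
                 chrom_sizes = chrom_sizes, ir = ir_by_chrom),
            class = "feature_partition")
}

#' @export
print.feature_partition <- function(x, ...) {
  cat("<feature_partition>", nrow(x$chrom_sizes), "chromosome(s),",
      format(sum(x$chrom_sizes$length), big.mark = ","), "bp\n")
  print(x$territory)
  invisible(x)
}

#' Assign breaks to feature categories
#'
#' Looks each break up in the resolved partition; because the territories
#' are disjoint and tile the genome, every in-bounds break maps to exactly
#' one category.
#'
#' @param breaks break tibble (`chrom`, `pos`).
#' @param partition a `feature_partition`.
#' @return `breaks` with a `category` factor column added.
#' @export
assign_breaks <- function(breaks, partition) {
  len <- setNames(partition$chrom_sizes$length, partition$chrom_sizes$chrom)
  if (nrow(breaks) > 0) {
    bad <- !(breaks$chrom %in% names(len)) | breaks$pos < 0 |
      breaks$pos >= len[breaks$chrom]
    if (any(bad)) {
      abort(sprintf("%d break(s) out of chromosome bounds", sum(bad)))
    }
  }
  category <- rep(NA_character_, nrow(breaks))
  for (cr in unique(breaks$chrom)) {
    idx <- which(breaks$chrom == cr)
    pts <- IRanges::IRanges(breaks$pos[idx] + 1, width = 1)
    for (cat in FEATURE_LEVELS) {
      hit <- IRanges::overlapsAny(pts, partition$ir[[cr]][[cat]])
      category[idx[hit & is.na(category[idx])]] <- cat
    }
  }
  breaks$category <- factor(category, levels = FEATURE_LEVELS)
  breaks
}

#' Feature-category break counts and densities
#'
#' Tallies assigned breaks per category and normalizes each count to the
#' megabase size of the category's territory (breaks/Mb).
#'
#' @param breaks break tibble.
#' @param partition a `feature_partition`.
#' @return an `annotation_summary` tibble: `category`, `n_breaks`,
#'   `territory_bp`, `density_per_mb`, with the total break count as an
#'   attribute.
#' @export
annotate_breaks <- function(breaks, partition) {
  assigned <- assign_breaks(breaks, partition)
  out <- assigned |>
    count(.data$category, .drop = FALSE, name = "n_breaks") |>
    left_join(partition$territory, by = "category") |>
    mutate(density_per_mb = ifelse(.data$territory_bp > 0,
                                   .data$n_breaks / (.data$territory_bp / 1e6),
                                   0))
  attr(out, "total_breaks") <- nrow(breaks)
  class(out) <- c("annotation_summary", class(out))
  out
}
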
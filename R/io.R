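#' Read a chromosome sizes table
#'
#' Two-column tab-separated file of chromosome name and length in bp, the
#' `.chrom.sizes` convention used by the UCSC tools.
#'
#' @param path path to a TSV with columns chrom, length (no header).
#' @return a tibble with columns `chrom` (character) and `length` (double).
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = "cd", comment = "#", progress = FALSE)
  if (any(is.na(x$length)) || any(x$length <= 0)) {
    abort("chromosome lengths must be positive numbers")
  }
  if (anyDuplicated(x$chrom)) abort("duplicate chromosome name in sizes file")
  x
}

normalise_strand <- function(strand) {
  strand[strand == "−"] <- "-"
  strand
}

#' Read a gene annotation table
#'
#' Parses gene models from BED6, BED12 or refFlat-style tables into the
#' tibble the rest of the pipeline consumes. All coordinates are 0-based
#' half-open internally; BED is natively so, and refFlat txStart/txEnd are
#' treated the same way. The transcription start site (TSS) of a gene is
#' `tx_start` on the + strand and `tx_end - 1` on the - strand; the
#' termination site (TTS) is the opposite end.
#'
#' Annotation tables routinely carry several transcripts per gene symbol.
#' By default the longest transcript per `gene_id` is kept
#' (`collapse = "longest"`); `collapse = "all"` keeps every row, suffixing
#' repeated ids to keep them unique.
#'
#' @param path path to the annotation file.
#' @param dialect one of `"bed6"`, `"bed12"`, `"refflat"`.
#' @param collapse how to resolve duplicate gene ids: `"longest"` or `"all"`.
#' @return a tibble with columns `gene_id`, `chrom`, `strand`, `tx_start`,
#'   `tx_end`.
#' @export
read_gene_table <- function(path, dialect = c("bed6", "bed12", "refflat"),
                            collapse = c("longest", "all")) {
  dialect <- match.arg(dialect)
  collapse <- match.arg(collapse)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)

  parse_row <- function(f, ln) {
    need <- switch(dialect, bed6 = 6L, bed12 = 12L, refflat = 11L)
    if (length(f) < need) {
      abort(sprintf("line %d: expected >= %d fields for %s, got %d",
                    ln, need, dialect, length(f)))
    }
    if (dialect == "refflat") {
      out <- list(gene_id = f[[1]], chrom = f[[3]], strand = f[[4]],
                  tx_start = f[[5]], tx_end = f[[6]])
    } else {
      out <- list(gene_id = f[[4]], chrom = f[[1]], strand = f[[6]],
                  tx_start = f[[2]], tx_end = f[[3]])
    }
    out$strand <- normalise_strand(out$strand)
    s <- suppressWarnings(as.double(out$tx_start))
    e <- suppressWarnings(as.double(out$tx_end))
    if (is.na(s) || is.na(e)) abort(sprintf("line %d: non-numeric coordinates", ln))
    if (!out$strand %in% c("+", "-")) {
      abort(sprintf("line %d: unknown strand '%s'", ln, out$strand))
    }
    if (s >= e) abort(sprintf("line %d: tx_start >= tx_end (%s >= %s)", ln, s, e))
    tibble(gene_id = out$gene_id, chrom = out$chrom, strand = out$strand,
           tx_start = s, tx_end = e)
  }

  genes <- purrr::map2_dfr(fields, line_no, parse_row)
  if (nrow(genes) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  strand = character(), tx_start = double(), tx_end = double()))
  }

  dup <- sum(duplicated(genes$gene_id))
  if (dup > 0) {
    if (collapse == "longest") {
      genes <- genes |>
        mutate(.len = .data$tx_end - .data$tx_start) |>
        arrange(.data$gene_id, desc(.data$.len), .data$chrom, .data$tx_start) |>
        filter(!duplicated(.data$gene_id)) |>
        select(-".len")
      inform(sprintf("collapsed %d duplicate gene_id rows (kept longest transcript)", dup))
    } else {
      genes$gene_id <- make.unique(genes$gene_id, sep = "_tx")
    }
  }
  arrange(genes, .data$chrom, .data$tx_start)
}

#' Strand-aware TSS and TTS positions
#'
#' @param genes a gene tibble from [read_gene_table()].
#' @return the input with `tss`, `tts` (0-based single-bp positions) and
#'   `gene_length` columns added.
#' @export
add_gene_anchors <- function(genes) {
  genes |>
    mutate(
      tss = ifelse(.data$strand == "+", .data$tx_start, .data$tx_end - 1),
      tts = ifelse(.data$strand == "+", .data$tx_end - 1, .data$tx_start),
      gene_length = .data$tx_end - .data$tx_start
    )
}

# Reference-consuming CIGAR span (M/D/N/=/X advance the reference).
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0)
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    if (ops[1] == -1) abort(sprintf("unparsable CIGAR '%s'", cg))
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.double(substr(toks, 1, nchar(toks) - 1))
    op <- substr(toks, nchar(toks), nchar(toks))
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, double(1), USE.NAMES = FALSE)
}

#' Read alignment records from a SAM text file
#'
#' Parses the fields the break-extraction chain needs (query name, FLAG,
#' reference, position, MAPQ, CIGAR, mate fields, TLEN). SAM's 1-based POS
#' is converted to a 0-based `start` exactly once, here; `end` is the
#' 0-based exclusive end of the aligned reference span, from the CIGAR.
#'
#' @param path path to a SAM text file with `@SQ` header lines.
#' @return a tibble of alignment records with one row per line, carrying a
#'   `chrom_sizes` attribute built from the `@SQ` headers. Unmapped records
#'   have `chrom = NA`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]

  sq <- hdr[startsWith(hdr, "@SQ")]
  sq_fields <- strsplit(sq, "\t", fixed = TRUE)
  sq_name <- vapply(sq_fields, function(f) sub("^SN:", "", f[startsWith(f, "SN:")][1]), "")
  sq_len <- vapply(sq_fields, function(f) as.double(sub("^LN:", "", f[startsWith(f, "LN:")][1])), 0)
  sizes <- tibble(chrom = sq_name, length = sq_len)

  if (length(body) == 0) {
    rec <- tibble(query_name = character(), flags = integer(), chrom = character(),
                  start = double(), end = double(), mapq = integer(),
                  cigar = character(), mate_chrom = character(),
                  mate_start = double(), tlen = double(), is_duplicate = logical())
    attr(rec, "chrom_sizes") <- sizes
    return(rec)
  }

  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11)) {
    abort(sprintf("SAM line %d: fewer than 11 fields",
                  which(nf < 11)[1] + length(hdr)))
  }
  get <- function(i) vapply(f, `[[`, "", i)
  flags <- suppressWarnings(as.integer(get(2)))
  if (any(is.na(flags))) {
    abort(sprintf("SAM line %d: unparsable FLAG", which(is.na(flags))[1] + length(hdr)))
  }
  rname <- get(3)
  pos1 <- as.double(get(4))
  cigar <- get(6)
  rnext <- get(7)
  pnext <- as.double(get(8))

  mapped <- !flag_set(flags, SAM_FLAGS[["unmapped"]])
  bad <- mapped & !(rname %in% c(sizes$chrom))
  if (any(bad)) {
    abort(sprintf("SAM line %d: reference '%s' missing from @SQ header",
                  which(bad)[1] + length(hdr), rname[which(bad)[1]]))
  }

  start <- ifelse(mapped, pos1 - 1, NA_real_)
  span <- cigar_ref_span(cigar)
  mate_chrom <- ifelse(rnext == "=", rname, rnext)
  rec <- tibble(
    query_name = get(1),
    flags = flags,
    chrom = ifelse(mapped, rname, NA_character_),
    start = start,
    end = ifelse(mapped, start + pmax(span, 1), NA_real_),
    mapq = as.integer(get(5)),
    cigar = cigar,
    mate_chrom = ifelse(mate_chrom == "*", NA_character_, mate_chrom),
    mate_start = ifelse(pnext > 0, pnext - 1, NA_real_),
    tlen = as.double(get(9)),
    is_duplicate = flag_set(flags, SAM_FLAGS[["duplicate"]])
  )
  attr(rec, "chrom_sizes") <- sizes
  rec
}

#' Write and read single-nucleotide break calls as BED3
#'
#' Each break occupies one bp, so BED records are `start = pos`,
#' `end = pos + 1`. `read_breaks_bed()` rejects records wider than 1 bp.
#'
#' @param breaks tibble with columns `chrom`, `pos` (and optionally `sample`).
#' @param path output/input path.
#' @param sample sample label attached to breaks on read.
#' @return `write_breaks_bed()` returns `path` invisibly; `read_breaks_bed()`
#'   a break tibble with columns `chrom`, `pos`, `sample`.
#' @export
write_breaks_bed <- function(breaks, path) {
  stopifnot(all(c("chrom", "pos") %in% names(breaks)))
  lines <- sprintf("%s\t%d\t%d", breaks$chrom, as.integer(breaks$pos),
                   as.integer(breaks$pos) + 1L)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_breaks_bed
#' @export
read_breaks_bed <- function(path, sample = "sample") {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                       col_types = "cdd", comment = "#", progress = FALSE)
  if (nrow(x) > 0 && any(x$end != x$start + 1)) {
    abort("break BED records must span exactly 1 bp (end == start + 1)")
  }
  tibble(chrom = x$chrom, pos = x$start, sample = sample)
}

#' Read a per-gene expression table
#'
#' Two-column TSV of `gene_id` and FPKM. Negative FPKM is rejected;
#' duplicate gene ids are an error by default, or resolved by keeping the
#' maximum with `duplicates = "max"`.
#'
#' @param path path to the TSV.
#' @param header does the file carry a header line?
#' @param duplicates `"error"` or `"max"`.
#' @return tibble with columns `gene_id`, `fpkm`.
#' @export
read_expression <- function(path, header = FALSE, duplicates = c("error", "max")) {
  duplicates <- match.arg(duplicates)
  x <- readr::read_tsv(path,
                       col_names = if (header) TRUE else c("gene_id", "fpkm"),
                       col_types = "cd", comment = "#", progress = FALSE)
  names(x)[1:2] <- c("gene_id", "fpkm")
  if (nrow(x) == 0) {
    warn("empty expression table")
    return(tibble(gene_id = character(), fpkm = double()))
  }
  if (any(is.na(x$fpkm)) || any(x$fpkm < 0)) abort("FPKM must be a nonnegative number")
  if (anyDuplicated(x$gene_id)) {
    if (duplicates == "error") abort("duplicate gene_id in expression table")
    ndup <- sum(duplicated(x$gene_id))
    x <- x |>
      arrange(.data$gene_id, desc(.data$fpkm)) |>
      filter(!duplicated(.data$gene_id))
    inform(sprintf("kept max FPKM for %d duplicated gene_id rows", ndup))
  }
  as_tibble(x[, c("gene_id", "fpkm")])
}

#' Write a results table as TSV with a commented header
#'
#' All pipeline outputs are tab-separated with a `#` comment line stating
#' the column names and package version, and are written atomically
#' (temp-then-rename) so partial files never appear.
#'
#' @param x data frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  ver <- as.character(utils::packageVersion("breakscape"))
  header <- sprintf("# breakscape %s\t%s", ver, paste(names(x), collapse = "\t"))
  writeLines(header, tmp)
  readr::write_tsv(x, tmp, append = TRUE, col_names = TRUE, progress = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a results table written by [write_results_tsv()]
#'
#' @param path path to the TSV.
#' @return a tibble.
#' @export
read_results_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}
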
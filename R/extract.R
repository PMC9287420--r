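#' Primary alignment filter
#'
#' Drops unmapped, secondary (non-primary), QC-fail and supplementary
#' records — the union of flag bits 0x4, 0x100, 0x200 and 0x800, i.e. the
#' samtools filter value 2820. "Low quality" is read strictly as the QC-fail
#' flag; an optional MAPQ cutoff is applied separately in
#' [extract_breaks()] and defaults to off.
#'
#' @param flags integer vector of SAM FLAG values.
#' @return a tibble with columns `pass` (logical) and `reason` (the first
#'   failing bit, in the order unmapped, secondary, qcfail, supplementary;
#'   `NA` when passing).
#' @export
passes_primary_filter <- function(flags) {
  reason <- rep(NA_character_, length(flags))
  for (bit in c("supplementary", "qcfail", "secondary", "unmapped")) {
    reason[flag_set(flags, SAM_FLAGS[[bit]])] <- bit
  }
  tibble(pass = is.na(reason), reason = reason)
}

#' Fragment-length filter
#'
#' A read pair is kept when its absolute template length (TLEN) lies inside
#' `[min_len, max_len]`, both ends inclusive — the aligner-style convention
#' for an insert-size restriction of 100–2000 nt. A TLEN of 0 (mates on
#' different chromosomes, or unpaired) always fails.
#'
#' @param tlen numeric vector of signed template lengths.
#' @param min_len,max_len inclusive bounds in nt.
#' @return logical vector.
#' @export
passes_fragment_length <- function(tlen, min_len = 100, max_len = 2000) {
  !is.na(tlen) & tlen != 0 & abs(tlen) >= min_len & abs(tlen) <= max_len
}

# 5' position of a record in read orientation: leftmost base for a forward
# read, rightmost aligned base for a reverse read.
five_prime_pos <- function(records) {
  ifelse(flag_set(records$flags, SAM_FLAGS[["reverse"]]),
         records$end - 1, records$start)
}

#' Mark PCR duplicates
#'
#' Read pairs sharing both mates' 5' coordinates and orientation descend
#' from amplification of one fragment. Pairs are keyed on (chrom, forward
#' 5' end, reverse 5' end, strand of the first mate); records that are not
#' part of an evaluable pair fall back to (chrom, own 5' end, strand,
#' TLEN). Exactly one representative per duplicate class — the record(s)
#' with the lexicographically smallest query name — keeps
#' `is_duplicate = FALSE`; the choice is deterministic and independent of
#' input order.
#'
#' @param records an alignment tibble from [read_sam()].
#' @return `records` with `is_duplicate` set.
#' @export
mark_duplicates <- function(records) {
  if (nrow(records) == 0) return(records)
  rev_self <- flag_set(records$flags, SAM_FLAGS[["reverse"]])
  paired_ok <- flag_set(records$flags, SAM_FLAGS[["paired"]]) &
    !is.na(records$tlen) & records$tlen != 0 & !is.na(records$mate_start)

  frag_left <- pmin(records$start, records$mate_start)
  frag_right <- frag_left + abs(records$tlen)
  r1_rev <- ifelse(flag_set(records$flags, SAM_FLAGS[["first_in_pair"]]),
                   rev_self,
                   flag_set(records$flags, SAM_FLAGS[["mate_reverse"]]))
  key <- ifelse(
    paired_ok,
    paste(records$chrom, frag_left, frag_right - 1, r1_rev, sep = ":"),
    paste("se", records$chrom, five_prime_pos(records), rev_self,
          records$tlen, sep = ":")
  )
  rep_name <- tapply(records$query_name, key, min)
  records$is_duplicate <- as.vector(records$query_name != rep_name[key])
  records
}

#' Select the first mate of retained pairs
#'
#' Keeps records with the paired, proper-pair and first-in-pair bits all
#' set (flag filter value 67) and the duplicate state unset, leaving one
#' record per original DNA fragment.
#'
#' @param records a duplicate-marked alignment tibble.
#' @return the retained subset.
#' @export
select_first_mates <- function(records) {
  want <- SAM_FLAGS[["paired"]] + SAM_FLAGS[["proper_pair"]] +
    SAM_FLAGS[["first_in_pair"]]
  keep <- bitwAnd(records$flags, want) == want & !records$is_duplicate
  records[keep, , drop = FALSE]
}

#' Break position of a filtered first mate
#'
#' The DSB-capture chemistry ligates the sequencing adaptor to the broken
#' end, so the most 5' nucleotide of the first mate is the break position:
#' the leftmost aligned base of a forward read, the rightmost of a reverse
#' read.
#'
#' @param records retained first-mate records.
#' @param sample sample label to attach.
#' @return a break tibble with columns `chrom`, `pos`, `sample`.
#' @export
break_positions <- function(records, sample = "sample") {
  tibble(chrom = records$chrom, pos = five_prime_pos(records), sample = sample)
}

#' Extract single-nucleotide break calls from aligned read pairs
#'
#' Runs the full filter chain — primary-alignment flags, optional MAPQ,
#' proper-pair requirement, fragment-length restriction, duplicate marking,
#' first-mate selection — then maps each surviving record to the 5'
#' nucleotide of its first mate. Every input record is accounted for in the
#' report: `total = retained + sum(dropped_*)`, with each record counted
#' under the first filter it fails, in chain order.
#'
#' @param records an alignment tibble from [read_sam()], or a path to a
#'   SAM file.
#' @param min_frag,max_frag inclusive fragment-length bounds in nt.
#' @param min_mapq optional MAPQ cutoff (0 disables it).
#' @param sample sample label for the emitted breaks.
#' @return an object of class `break_extraction` with elements `breaks`
#'   (tibble `chrom`, `pos`, `sample`) and `report` (one-row tibble of
#'   counters). [tidy()] returns the breaks, [glance()] the report.
#' @export
extract_breaks <- function(records, min_frag = 100, max_frag = 2000,
                           min_mapq = 0, sample = "sample") {
  if (is.character(records)) records <- read_sam(records)
  n <- nrow(records)
  reason <- rep(NA_character_, n)

  prim <- passes_primary_filter(records$flags)
  reason[!prim$pass] <- prim$reason[!prim$pass]

  open <- is.na(reason)
  if (min_mapq > 0) {
    low <- open & records$mapq < min_mapq
    reason[low] <- "low_mapq"
    open <- is.na(reason)
  }

  pp <- SAM_FLAGS[["paired"]] + SAM_FLAGS[["proper_pair"]]
  not_pp <- open & bitwAnd(records$flags, pp) != pp
  reason[not_pp] <- "not_proper_pair"
  open <- is.na(reason)

  tlen0 <- open & (is.na(records$tlen) | records$tlen == 0)
  reason[tlen0] <- "tlen_zero"
  open <- is.na(reason)
  badlen <- open & !passes_fragment_length(records$tlen, min_frag, max_frag)
  reason[badlen] <- "fraglen"
  open <- is.na(reason)

  # duplicate classes are resolved among records that survive the pair and
  # fragment filters, then the first-mate requirement is applied
  surv <- records[open, , drop = FALSE]
  surv <- mark_duplicates(surv)
  first_bit <- flag_set(surv$flags, SAM_FLAGS[["first_in_pair"]])
  r2 <- rep(NA_character_, nrow(surv))
  r2[!first_bit] <- "not_first_mate"
  r2[first_bit & surv$is_duplicate] <- "duplicate"
  reason[open] <- r2

  retained <- surv[first_bit & !surv$is_duplicate, , drop = FALSE]
  breaks <- break_positions(retained, sample = sample)

  counter <- function(r) sum(reason == r, na.rm = TRUE)
  report <- tibble(
    total = n,
    dropped_unmapped = counter("unmapped"),
    dropped_secondary = counter("secondary"),
    dropped_qcfail = counter("qcfail"),
    dropped_supplementary = counter("supplementary"),
    dropped_low_mapq = counter("low_mapq"),
    dropped_not_proper_pair = counter("not_proper_pair"),
    dropped_tlen_zero = counter("tlen_zero"),
    dropped_fraglen = counter("fraglen"),
    dropped_not_first_mate = counter("not_first_mate"),
    dropped_duplicate = counter("duplicate"),
    retained = nrow(breaks)
  )
  structure(list(breaks = breaks, report = report, sample = sample),
            class = "break_extraction")
}

#' @export
print.break_extraction <- function(x, ...) {
  cat(sprintf("<break_extraction> %s: %d records in, %d breaks retained\n",
              x$sample, x$report$total, x$report$retained))
  drops <- x$report[startsWith(names(x$report), "dropped_")]
  drops <- drops[, unlist(drops) > 0, drop = FALSE]
  if (ncol(drops) > 0) {
    cat("dropped:", paste(sprintf("%s=%d", sub("dropped_", "", names(drops)),
                                  unlist(drops)), collapse = ", "), "\n")
  }
  invisible(x)
}
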
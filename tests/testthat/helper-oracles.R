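# Independent reference implementations used as oracles. These are written
# as plain per-element loops, deliberately avoiding the vectorized /
# interval-set code paths they check.

# Per-bp priority classifier: every bp of a toy genome is tested against
# every window in priority order (tss > promoter > tts > gene_body).
brute_force_partition <- function(genes, chrom_sizes, ...) {
  wins <- gene_windows(genes, chrom_sizes, ...)
  out <- list()
  for (i in seq_len(nrow(chrom_sizes))) {
    cr <- chrom_sizes$chrom[i]
    len <- chrom_sizes$length[i]
    cat_vec <- rep("intergenic", len)
    claimed <- rep(FALSE, len)
    for (cat in c("tss", "promoter", "tts", "gene_body")) {
      w <- wins[wins$chrom == cr & wins$category == cat, , drop = FALSE]
      for (j in seq_len(nrow(w))) {
        idx <- seq(w$start[j] + 1, w$end[j])  # bp p occupies index p + 1
        take <- idx[!claimed[idx]]
        cat_vec[take] <- cat
        claimed[take] <- TRUE
      }
    }
    out[[cr]] <- cat_vec
  }
  out
}

# Exhaustive 2^n sign-pattern enumeration of the signed-rank null.
enum_wilcoxon_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(seq_len(2^n) - 1L, function(mask) {
    sum(r[bitwAnd(bitwShiftR(mask, seq_len(n) - 1L), 1L) == 1L])
  }, double(1))
  min(1, 2 * min(mean(ws <= w_obs + 1e-9), mean(ws >= w_obs - 1e-9)))
}

# Naive per-record break extraction: straight-line per-record logic with
# brute-force duplicate grouping, independent of the streaming chain.
naive_extract_breaks <- function(records, min_frag = 100, max_frag = 2000) {
  n <- nrow(records)
  is_rev <- bitwAnd(records$flags, 0x10) != 0
  own5 <- ifelse(is_rev, records$end - 1, records$start)
  survives <- logical(n)
  for (i in seq_len(n)) {
    fl <- records$flags[i]
    if (bitwAnd(fl, 0x4 + 0x100 + 0x200 + 0x800) != 0) next
    if (bitwAnd(fl, 0x1 + 0x2) != 0x3) next
    tl <- records$tlen[i]
    if (is.na(tl) || tl == 0 || abs(tl) < min_frag || abs(tl) > max_frag) next
    survives[i] <- TRUE
  }
  key <- rep(NA_character_, n)
  for (i in which(survives)) {
    left <- min(records$start[i], records$mate_start[i])
    right <- left + abs(records$tlen[i]) - 1
    r1rev <- if (bitwAnd(records$flags[i], 0x40) != 0) {
      is_rev[i]
    } else {
      bitwAnd(records$flags[i], 0x20) != 0
    }
    key[i] <- paste(records$chrom[i], left, right, r1rev)
  }
  breaks <- list()
  for (i in which(survives)) {
    if (bitwAnd(records$flags[i], 0x40) == 0) next
    same <- which(survives & key == key[i])
    if (records$query_name[i] != min(records$query_name[same])) next
    breaks[[length(breaks) + 1]] <- data.frame(chrom = records$chrom[i],
                                               pos = own5[i])
  }
  if (length(breaks) == 0) {
    return(data.frame(chrom = character(), pos = double()))
  }
  do.call(rbind, breaks)
}

# Hand-rolled SAM fixture line (1-based pos in, like a real file).
sam_line <- function(qname, flag, chrom = "chr1", pos1 = 100, cigar = "50M",
                     rnext = "=", pnext1 = 300, tlen = 250, mapq = 60) {
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t*\t*",
          qname, flag, chrom, pos1, mapq, cigar, rnext, pnext1, tlen)
}

sam_fixture <- function(lines, chroms = c(chr1 = 100000)) {
  path <- tempfile(fileext = ".sam")
  header <- c("@HD\tVN:1.6",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), chroms))
  writeLines(c(header, lines), path)
  path
}

# A proper FR pair with the first mate's 5' end at `pos` (0-based).
pair_lines <- function(qname, pos, flen = 250, fwd = TRUE, chrom = "chr1",
                       rl = 50) {
  span <- min(rl, flen)
  cg <- sprintf("%dM", span)
  if (fwd) {
    r1 <- sam_line(qname, 99, chrom, pos + 1, cg, "=", pos + flen - span + 1, flen)
    r2 <- sam_line(qname, 147, chrom, pos + flen - span + 1, cg, "=", pos + 1, -flen)
  } else {
    r1 <- sam_line(qname, 83, chrom, pos - span + 2, cg, "=", pos - flen + 2, -flen)
    r2 <- sam_line(qname, 163, chrom, pos - flen + 2, cg, "=", pos - span + 2, flen)
  }
  c(r1, r2)
}

break_key <- function(breaks) sort(paste(breaks$chrom, breaks$pos))

# Small helper to materialize an alignment tibble without a file.
records_from_lines <- function(lines, chroms = c(chr1 = 100000)) {
  read_sam(sam_fixture(lines, chroms))
}
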
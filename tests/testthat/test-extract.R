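test_that("primary filter drops the 2820 flag union, naming the first bit", {
  res <- passes_primary_filter(c(99L, 0x100L, 0x4L, 0x4L + 0x100L,
                                 0x200L + 0x800L, 83L))
  expect_equal(res$pass, c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(res$reason,
               c(NA, "secondary", "unmapped", "unmapped", "qcfail", NA))
})

test_that("fragment-length bounds are inclusive and tlen 0 fails", {
  expect_equal(passes_fragment_length(c(100, 2000, -2000, 99, 2001, 0)),
               c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("duplicate marking groups by fragment coordinates and orientation", {
  rec <- records_from_lines(c(pair_lines("b", 500, flen = 300),
                              pair_lines("a", 500, flen = 300),
                              pair_lines("c", 500, flen = 301),
                              pair_lines("d", 500, flen = 300, fwd = FALSE)))
  marked <- mark_duplicates(rec)
  # 'a' wins its class lexicographically; 'c' and 'd' are distinct fragments
  expect_equal(marked$is_duplicate[marked$query_name == "a"], c(FALSE, FALSE))
  expect_equal(marked$is_duplicate[marked$query_name == "b"], c(TRUE, TRUE))
  expect_false(any(marked$is_duplicate[marked$query_name %in% c("c", "d")]))
})

test_that("n copies of one pair leave exactly one representative (oracle)", {
  for (n in c(2, 3, 7)) {
    lines <- unlist(lapply(seq_len(n), function(i) {
      pair_lines(sprintf("q%02d", i), 1000, flen = 400)
    }))
    marked <- mark_duplicates(records_from_lines(lines))
    expect_equal(sum(marked$is_duplicate), 2 * (n - 1))
    expect_equal(unique(marked$query_name[!marked$is_duplicate]), "q01")
  }

  # randomized: compare against brute-force grouping on generated pairs
  set.seed(11)
  for (rep in 1:5) {
    pos <- sample(500:520, 30, replace = TRUE)
    flen <- sample(c(200, 201), 30, replace = TRUE)
    fwd <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    lines <- unlist(lapply(1:30, function(i) {
      pair_lines(sprintf("r%03d", i), pos[i], flen[i], fwd[i])
    }))
    rec <- mark_duplicates(records_from_lines(lines))
    expected_dups <- sum(duplicated(paste(pos, flen, fwd))) * 2
    expect_equal(sum(rec$is_duplicate), expected_dups)
  }
})

test_that("first-mate selection keeps flags 67 minus duplicates", {
  rec <- records_from_lines(c(pair_lines("a", 500), pair_lines("b", 500)))
  rec <- mark_duplicates(rec)
  kept <- select_first_mates(rec)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$query_name, "a")
  expect_true(bitwAnd(kept$flags, 0x40) != 0)
})

test_that("break position is the 5' nucleotide of the first mate", {
  fwd <- records_from_lines(sam_line("f", 99, pos1 = 101, cigar = "75M",
                                     tlen = 200))
  expect_equal(break_positions(fwd)$pos, 100)
  rev <- records_from_lines(sam_line("r", 83, pos1 = 101, cigar = "75M",
                                     tlen = -200))
  expect_equal(break_positions(rev)$pos, 174)
  edge <- records_from_lines(sam_line("e", 99, pos1 = 1, cigar = "75M",
                                      tlen = 200))
  expect_equal(break_positions(edge)$pos, 0)
})

test_that("extract_breaks reproduces the hand-enumerated fixture", {
  clean <- unlist(lapply(1:10, function(i) {
    pair_lines(sprintf("c%02d", i), 1000 + 37 * i, flen = 300 + i)
  }))
  dups <- unlist(lapply(1:3, function(i) {
    pair_lines(sprintf("d%02d", i), 5000, flen = 500)
  }))
  contam <- c(sam_line("s1", 99 + 0x100, pos1 = 2001, tlen = 250),
              sam_line("s2", 99 + 0x100, pos1 = 2101, tlen = 250),
              "u1\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*")
  ex <- extract_breaks(sam_fixture(c(clean, dups, contam)))
  expect_equal(nrow(ex$breaks), 11)
  expect_equal(ex$report$dropped_duplicate, 2)
  expect_equal(ex$report$dropped_secondary, 2)
  expect_equal(ex$report$dropped_unmapped, 1)
  expect_equal(ex$report$retained, 11)
  expect_true(5000 %in% ex$breaks$pos)
})

test_that("degenerate streams are accounted for", {
  empty <- extract_breaks(sam_fixture(character(0)))
  expect_equal(nrow(empty$breaks), 0)
  expect_true(all(unlist(empty$report) == 0))

  seconds <- unlist(lapply(1:4, function(i) {
    pair_lines(sprintf("q%d", i), 900 + i)[2]
  }))
  ex2 <- extract_breaks(sam_fixture(seconds))
  expect_equal(nrow(ex2$breaks), 0)
  expect_equal(ex2$report$dropped_not_first_mate, 4)
})

test_that("record conservation holds on randomized contaminated inputs", {
  for (seed in 1:6) {
    cfg <- sim_config(seed = seed, n_genes = 20, chrom_length = 5e5,
                      library_size = 400, duplicate_rate = 0.1,
                      contaminant_rates = c(secondary = 0.07,
                                            supplementary = 0.05,
                                            unmapped = 0.04, qcfail = 0.03))
    g <- make_genome(cfg)
    e <- make_expression(g$genes, cfg)
    sim <- simulate_breaks(g$genes, e, "control", cfg)
    tf <- tempfile(fileext = ".sam")
    breaks_to_sam(sim$breaks, cfg, path = tf)
    ex <- extract_breaks(tf)
    r <- ex$report
    drops <- unlist(r[startsWith(names(r), "dropped_")])
    expect_equal(r$total, r$retained + sum(drops))
  }
})

test_that("break calls are invariant to record order", {
  cfg <- sim_config(seed = 3, n_genes = 15, chrom_length = 4e5,
                    library_size = 300, duplicate_rate = 0.15)
  g <- make_genome(cfg)
  e <- make_expression(g$genes, cfg)
  sim <- simulate_breaks(g$genes, e, "control", cfg)
  tf <- tempfile(fileext = ".sam")
  breaks_to_sam(sim$breaks, cfg, path = tf)
  rec <- read_sam(tf)
  shuffled <- rec[sample.int(nrow(rec)), ]
  attr(shuffled, "chrom_sizes") <- attr(rec, "chrom_sizes")
  expect_equal(break_key(extract_breaks(rec)$breaks),
               break_key(extract_breaks(shuffled)$breaks))
})

test_that("streaming extraction matches the naive per-record oracle", {
  for (seed in c(5, 9)) {
    cfg <- sim_config(seed = seed, n_genes = 25, chrom_length = 6e5,
                      gene_length_meanlog = log(8000), library_size = 350, duplicate_rate = 0.1,
                      contaminant_rates = c(secondary = 0.05,
                                            supplementary = 0.03,
                                            unmapped = 0.03, qcfail = 0.02))
    g <- make_genome(cfg)
    e <- make_expression(g$genes, cfg)
    sim <- simulate_breaks(g$genes, e, "control", cfg)
    tf <- tempfile(fileext = ".sam")
    breaks_to_sam(sim$breaks, cfg, path = tf)
    rec <- read_sam(tf)
    expect_equal(break_key(extract_breaks(rec)$breaks),
                 break_key(naive_extract_breaks(rec)))
  }
})

test_that("tidy and glance expose breaks and the QC report", {
  ex <- extract_breaks(sam_fixture(pair_lines("a", 500)))
  expect_equal(nrow(tidy(ex)), 1)
  expect_equal(glance(ex)$retained, 1)
  expect_equal(glance(ex)$total, 2)
})
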
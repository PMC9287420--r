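test_that("the simulator is fully deterministic under its seed", {
  cfg <- sim_config(seed = 31, n_genes = 40, chrom_length = 2e6,
                    library_size = 2000, duplicate_rate = 0.05,
                    contaminant_rates = c(secondary = 0.03, supplementary = 0,
                                          unmapped = 0.02, qcfail = 0))
  run <- function() {
    g <- make_genome(cfg)
    e <- make_expression(g$genes, cfg)
    sim <- simulate_breaks(g$genes, e, "p53kd", cfg)
    sam <- breaks_to_sam(sim$breaks, cfg)
    list(g = g$genes, e = e, b = sim$breaks, lines = sam$lines)
  }
  r1 <- run()
  r2 <- run()
  expect_identical(r1$g, r2$g)
  expect_identical(r1$e, r2$e)
  expect_identical(r1$b, r2$b)
  expect_identical(r1$lines, r2$lines)  # byte-identical SAM
})

test_that("genome generation respects gene count, bounds and spacing", {
  cfg <- sim_config(seed = 5, n_genes = 80, chrom_length = 3e6,
                    library_size = 10)
  g <- make_genome(cfg)
  expect_equal(nrow(g$genes), 80)
  expect_true(all(g$genes$tx_start >= 0))
  expect_true(all(g$genes$tx_end <= 3e6))
  expect_true(all(g$genes$tx_start < g$genes$tx_end))
  # overlap_fraction = 0: pairwise disjoint
  ord <- order(g$genes$tx_start)
  expect_true(all(diff(g$genes$tx_start[ord]) >=
                    (g$genes$tx_end - g$genes$tx_start)[ord][-80]))

  empty <- make_genome(sim_config(seed = 1, n_genes = 0, library_size = 10))
  expect_equal(nrow(empty$genes), 0)

  expect_error(make_genome(sim_config(seed = 1, n_genes = 50,
                                      chrom_length = 1e5,
                                      gene_length_meanlog = log(5e4),
                                      library_size = 10)),
               "cannot fit")
})

test_that("expression tables honour zero inflation and spread settings", {
  cfg <- sim_config(seed = 6, n_genes = 1000, chrom_length = 5e7,
                    zero_fraction = 0.1, library_size = 10)
  g <- make_genome(cfg)
  e <- make_expression(g$genes, cfg)
  n_zero <- sum(e$fpkm == 0)
  expect_true(abs(n_zero - 100) < 4 * sqrt(1000 * 0.1 * 0.9))
  expect_true(all(e$fpkm >= 0))

  flat <- make_expression(g$genes, sim_config(seed = 6, n_genes = 1000,
                                              chrom_length = 5e7,
                                              expression_sdlog = 0,
                                              zero_fraction = 0,
                                              library_size = 10))
  expect_equal(length(unique(flat$fpkm)), 1)
})

test_that("break mixtures follow the configured component weights", {
  cfg <- sim_config(seed = 13, n_genes = 100, chrom_length = 1e7,
                    library_size = 2e4)
  g <- make_genome(cfg)
  e <- make_expression(g$genes, cfg)
  sim <- simulate_breaks(g$genes, e, "control", cfg)
  expect_equal(nrow(sim$truth), 2e4)
  expect_equal(sum(table(sim$truth$component)), 2e4)

  # expected proportions from the weight definitions
  anch <- add_gene_anchors(g$genes)
  fpkm <- e$fpkm
  w_tss <- sum(0.5 * fpkm^0.5)
  w_body <- sum(ifelse(anch$gene_length > 500,
                       0.001 * (anch$gene_length / 1e3)^2, 0))
  w_bg <- 180 * 1e7 / 1e6
  w <- c(background = w_bg, tss = w_tss, body = w_body) /
    (w_bg + w_tss + w_body)
  obs <- table(factor(sim$truth$component,
                      c("background", "tss", "body"))) / 2e4
  for (comp in names(w)) {
    expect_true(abs(obs[[comp]] - w[[comp]]) <
                  4 * sqrt(w[[comp]] * (1 - w[[comp]]) / 2e4),
                info = comp)
  }

  # truth positions agree with emitted breaks
  expect_equal(sim$truth$pos, sim$breaks$pos)
  expect_error(simulate_breaks(g$genes, e, "nope", cfg), "unknown condition")
})

test_that("background-only breaks are uniform over the genome", {
  cfg <- sim_config(seed = 17, n_genes = 50, chrom_length = 2e6,
                    tss_beta = 0, body_rate_per_kb = 0, library_size = 2e4)
  g <- make_genome(cfg)
  e <- make_expression(g$genes, cfg)
  sim <- simulate_breaks(g$genes, e, "control", cfg)
  expect_true(all(sim$truth$component == "background"))
  bins <- cut(sim$breaks$pos, breaks = seq(0, 2e6, length.out = 21))
  gof <- suppressWarnings(stats::chisq.test(table(bins)))
  expect_true(gof$p.value > 0.01)
})

test_that("SAM round trip recovers the exact break multiset", {
  for (seed in 1:10) {
    cfg <- sim_config(seed = seed, n_genes = 20,
                      chrom_length = sample(c(5e5, 1e6, 2e6), 1),
                      gene_length_meanlog = log(8000),
                      library_size = sample(100:400, 1))
    g <- make_genome(cfg)
    e <- make_expression(g$genes, cfg)
    sim <- simulate_breaks(g$genes, e, "control", cfg)
    tf <- tempfile(fileext = ".sam")
    breaks_to_sam(sim$breaks, cfg, path = tf)
    ex <- extract_breaks(tf)
    expect_equal(break_key(ex$breaks), break_key(sim$breaks),
                 info = sprintf("seed %d", seed))
  }
})

test_that("injected duplicates and contaminants are reported exactly", {
  cfg <- sim_config(seed = 23, n_genes = 30, chrom_length = 1e6,
                    library_size = 1000, duplicate_rate = 0.06,
                    contaminant_rates = c(secondary = 0.05,
                                          supplementary = 0.04,
                                          unmapped = 0.03, qcfail = 0.02))
  g <- make_genome(cfg)
  e <- make_expression(g$genes, cfg)
  sim <- simulate_breaks(g$genes, e, "control", cfg)
  tf <- tempfile(fileext = ".sam")
  out <- breaks_to_sam(sim$breaks, cfg, path = tf)
  ex <- extract_breaks(tf)
  inj <- setNames(out$injected$n, out$injected$type)
  expect_equal(ex$report$dropped_duplicate, inj[["duplicate_pairs"]])
  expect_equal(ex$report$dropped_secondary, inj[["secondary"]])
  expect_equal(ex$report$dropped_supplementary, inj[["supplementary"]])
  expect_equal(ex$report$dropped_unmapped, inj[["unmapped"]])
  expect_equal(ex$report$dropped_qcfail, inj[["qcfail"]])
  expect_equal(break_key(ex$breaks), break_key(sim$breaks))
})

test_that("a contaminant-only SAM yields zero breaks", {
  cfg <- sim_config(seed = 2, n_genes = 10, chrom_length = 5e5,
                    library_size = 200,
                    contaminant_rates = c(secondary = 0.2, supplementary = 0.1,
                                          unmapped = 0.1, qcfail = 0.1))
  g <- make_genome(cfg)
  e <- make_expression(g$genes, cfg)
  sim <- simulate_breaks(g$genes, e, "control", cfg)
  sam <- breaks_to_sam(sim$breaks, cfg)
  keep <- startsWith(sam$lines, "@") | startsWith(sam$lines, "z")
  contam_only <- sam$lines[keep & !startsWith(sam$lines, "zdup")]
  tf <- tempfile(fileext = ".sam")
  writeLines(contam_only, tf)
  ex <- extract_breaks(tf)
  expect_equal(nrow(ex$breaks), 0)
})

test_that("condition multipliers shift the targeted component", {
  cfg <- sim_config(seed = 19, n_genes = 200, chrom_length = 2e7,
                    library_size = 3e4)
  g <- make_genome(cfg)
  e <- make_expression(g$genes, cfg)
  ctrl <- simulate_breaks(g$genes, e, "control", cfg)
  kd <- simulate_breaks(g$genes, e, "p53kd", cfg, seed = 99)
  aph <- simulate_breaks(g$genes, e, "aph", cfg, seed = 77)
  p_tss <- function(s) mean(s$truth$component == "tss")
  p_body <- function(s) mean(s$truth$component == "body")
  expect_true(p_tss(kd) > p_tss(ctrl))
  expect_true(p_body(aph) > 2 * p_body(ctrl))
})
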
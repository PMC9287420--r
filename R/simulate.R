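#' Simulation configuration for DSB-capture data
#'
#' Builds the validated configuration driving the toy-genome simulator.
#' The generative model mixes three break components: (i) uniform
#' background breakage over the genome; (ii) a TSS component in which a
#' gene is hit proportionally to `beta * FPKM^alpha` (times the condition's
#' TSS multiplier, the p53-knockdown-like axis) and the break lands
#' Normal(TSS, `tss_sd`) truncated to +/- `tss_truncation`; (iii) a
#' replication-stress body component in which a gene is hit proportionally
#' to `body_rate_per_kb * length_kb^body_length_power` (times the
#' condition's body multiplier, the aphidicolin-like axis) and the break
#' lands uniformly in the gene body. `body_length_power = 2` makes per-kb
#' fragility grow with gene length, the long-gene fragility signature of
#' replication stress; `1` gives a uniform per-kb rate (the no-association
#' null).
#'
#' @param seed integer master seed; every random stream derives from it.
#' @param n_genes number of genes.
#' @param chrom_length,chrom_name single toy chromosome size/name (supply
#'   vectors for a multi-chromosome genome).
#' @param gene_length_meanlog,gene_length_sdlog log-normal gene lengths (bp).
#' @param expression_meanlog,expression_sdlog log-normal FPKM.
#' @param zero_fraction fraction of genes with FPKM forced to 0.
#' @param overlap_fraction fraction of genes deliberately placed
#'   overlapping their neighbour, to exercise priority resolution.
#' @param background_rate background mixture weight per Mb of genome.
#' @param tss_alpha,tss_beta TSS coupling: per-gene weight `beta * fpkm^alpha`.
#' @param tss_sd,tss_truncation Gaussian spread (bp) and truncation of TSS
#'   break placement.
#' @param body_rate_per_kb,body_length_power body mixture weight per gene:
#'   `rate * length_kb^power`.
#' @param conditions named list of `c(tss = , body = )` multipliers.
#' @param library_size total breaks per simulated sample.
#' @param read_length,fragment_min,fragment_max read/fragment geometry (nt).
#' @param duplicate_rate fraction of extra duplicate pairs injected.
#' @param contaminant_rates named vector (secondary, supplementary,
#'   unmapped, qcfail) of contaminant record fractions.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 5000,
                       chrom_length = 2e8,
                       chrom_name = "chrS",
                       gene_length_meanlog = log(15000),
                       gene_length_sdlog = 0.6,
                       expression_meanlog = 1,
                       expression_sdlog = 1,
                       zero_fraction = 0.1,
                       overlap_fraction = 0,
                       background_rate = 180,
                       tss_alpha = 0.5,
                       tss_beta = 0.5,
                       tss_sd = 150,
                       tss_truncation = 2000,
                       body_rate_per_kb = 0.001,
                       body_length_power = 2,
                       conditions = list(control = c(tss = 1, body = 1),
                                         p53kd = c(tss = 2, body = 1),
                                         aph = c(tss = 1, body = 3)),
                       library_size = 2e6,
                       read_length = 75,
                       fragment_min = 100,
                       fragment_max = 2000,
                       duplicate_rate = 0,
                       contaminant_rates = c(secondary = 0, supplementary = 0,
                                             unmapped = 0, qcfail = 0)) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$chrom_length) == length(cfg$chrom_name))
  rates <- c(cfg$background_rate, cfg$tss_beta, cfg$body_rate_per_kb,
             cfg$duplicate_rate, cfg$contaminant_rates)
  if (any(rates < 0)) abort("all rates must be >= 0")
  if (cfg$fragment_min < 1 || cfg$fragment_max > min(cfg$chrom_length) ||
      cfg$fragment_min > cfg$fragment_max) {
    abort("fragment range must lie within [1, chrom_length]")
  }
  if (cfg$zero_fraction < 0 || cfg$zero_fraction >= 1) {
    abort("zero_fraction must be in [0, 1)")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a toy genome of gene models
#'
#' Places `n_genes` genes with log-normal lengths and random spacing on the
#' configured chromosome(s), non-overlapping by default; with
#' `overlap_fraction > 0` that fraction of genes is shifted onto its left
#' neighbour to create overlapping models. Strands are Bernoulli(0.5).
#' Fully deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return list with `genes` (tibble `gene_id`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`) and `chrom_sizes` (tibble `chrom`, `length`).
#' @export
make_genome <- function(config) {
  sizes <- tibble(chrom = config$chrom_name, length = config$chrom_length)
  if (config$n_genes == 0) {
    return(list(genes = tibble(gene_id = character(), chrom = character(),
                               strand = character(), tx_start = double(),
                               tx_end = double()),
                chrom_sizes = sizes))
  }
  genes <- local_seed(sub_seed(config$seed, 1), {
    chrom_idx <- sample.int(length(config$chrom_name), config$n_genes,
                            replace = TRUE, prob = config$chrom_length)
    len <- pmax(600, round(rlnorm(config$n_genes, config$gene_length_meanlog,
                                  config$gene_length_sdlog)))
    strand <- ifelse(runif(config$n_genes) < 0.5, "+", "-")
    parts <- lapply(seq_along(config$chrom_name), function(ci) {
      idx <- which(chrom_idx == ci)
      if (length(idx) == 0) return(NULL)
      L <- config$chrom_length[ci]
      lens <- len[idx]
      slack <- L - sum(lens)
      if (slack <= length(idx)) {
        abort("genes cannot fit on the chromosome; increase chrom_length")
      }
      gaps <- stats::rexp(length(idx) + 1)
      gaps <- floor(gaps / sum(gaps) * slack)
      starts <- cumsum(gaps[-length(gaps)] + c(0, lens[-length(lens)]))
      tibble(chrom = config$chrom_name[ci], strand = strand[idx],
             tx_start = starts, tx_end = starts + lens)
    })
    g <- bind_rows(parts)
    n_ov <- round(config$overlap_fraction * nrow(g))
    if (n_ov > 0 && nrow(g) > 1) {
      victims <- sample(2:nrow(g), min(n_ov, nrow(g) - 1))
      same <- g$chrom[victims] == g$chrom[victims - 1]
      victims <- victims[same]
      shift <- pmax(1, pmin(g$tx_start[victims] - g$tx_start[victims - 1] - 1,
                            g$tx_start[victims] - g$tx_end[victims - 1] + 400))
      g$tx_start[victims] <- g$tx_start[victims] - shift
      g$tx_end[victims] <- g$tx_end[victims] - shift
    }
    g
  })
  genes$gene_id <- sprintf("G%05d", seq_len(nrow(genes)))
  list(genes = select(genes, "gene_id", "chrom", "strand",
                      "tx_start", "tx_end"),
       chrom_sizes = sizes)
}

#' Generate a per-gene expression table
#'
#' FPKM ~ LogNormal(`expression_meanlog`, `expression_sdlog`), with a
#' `zero_fraction` of genes zero-inflated to FPKM 0. Deterministic under
#' the config seed.
#'
#' @param genes gene tibble from [make_genome()].
#' @param config a [sim_config()].
#' @return expression tibble (`gene_id`, `fpkm`).
#' @export
make_expression <- function(genes, config) {
  local_seed(sub_seed(config$seed, 2), {
    fpkm <- rlnorm(nrow(genes), config$expression_meanlog,
                   config$expression_sdlog)
    zero <- runif(nrow(genes)) < config$zero_fraction
    fpkm[zero] <- 0
    tibble(gene_id = genes$gene_id, fpkm = fpkm)
  })
}

# Per-gene mixture weights under a named condition. gene_tss_multiplier is
# an optional named vector of extra per-gene TSS weight factors (planted
# hotspot experiments).
component_weights <- function(genes, expr, condition, config,
                              gene_tss_multiplier = NULL) {
  mult <- config$conditions[[condition]]
  if (is.null(mult)) {
    abort(sprintf("unknown condition '%s' (have: %s)", condition,
                  paste(names(config$conditions), collapse = ", ")))
  }
  anchored <- add_gene_anchors(genes) |>
    left_join(expr, by = "gene_id") |>
    mutate(
      w_tss = config$tss_beta * .data$fpkm^config$tss_alpha *
        unname(mult[["tss"]]),
      body_start = .data$tx_start + 250,
      body_end = .data$tx_end - 250,
      w_body = ifelse(.data$body_end > .data$body_start,
                      config$body_rate_per_kb *
                        ((.data$tx_end - .data$tx_start) / 1e3) ^
                          config$body_length_power * unname(mult[["body"]]),
                      0)
    )
  anchored$w_tss[is.na(anchored$w_tss)] <- 0
  if (!is.null(gene_tss_multiplier)) {
    hit <- match(names(gene_tss_multiplier), anchored$gene_id)
    if (anyNA(hit)) abort("gene_tss_multiplier names must be gene ids")
    anchored$w_tss[hit] <- anchored$w_tss[hit] * gene_tss_multiplier
  }
  list(genes = anchored,
       w_background = config$background_rate * sum(config$chrom_length) / 1e6)
}

#' Simulate a truth-tracked break set
#'
#' Draws `library_size` breaks from the background / TSS / gene-body
#' mixture for one condition, recording for every break the generating
#' component and source gene, plus each gene's expected TSS break count.
#'
#' @param genes,expr toy genome and expression from [make_genome()] /
#'   [make_expression()].
#' @param condition name of a condition in `config$conditions`.
#' @param config a [sim_config()].
#' @param seed optional seed overriding the config seed (so several
#'   conditions or replicates can be drawn from one genome).
#' @param gene_tss_multiplier optional named numeric vector of extra
#'   per-gene TSS weight factors, for planting break hotspots in recovery
#'   experiments.
#' @return list with `breaks` (tibble `chrom`, `pos`, `sample`), `truth`
#'   (breaks plus `component`, `gene_id`) and `gene_expected` (tibble
#'   `gene_id`, `expected_tss`).
#' @export
simulate_breaks <- function(genes, expr, condition = "control", config,
                            seed = config$seed, gene_tss_multiplier = NULL) {
  cw <- component_weights(genes, expr, condition, config,
                          gene_tss_multiplier)
  g <- cw$genes
  weights <- c(background = cw$w_background,
               tss = sum(g$w_tss), body = sum(g$w_body))
  if (sum(weights) <= 0) abort("all mixture weights are zero")
  n <- config$library_size

  sizes <- tibble(chrom = config$chrom_name, length = config$chrom_length)
  draw <- local_seed(sub_seed(seed, 3), {
    comp <- sample(names(weights), n, replace = TRUE, prob = weights)
    out <- tibble(chrom = NA_character_, pos = NA_real_, component = comp,
                  gene_id = NA_character_)

    n_bg <- sum(comp == "background")
    if (n_bg > 0) {
      ci <- sample.int(nrow(sizes), n_bg, replace = TRUE, prob = sizes$length)
      out$chrom[comp == "background"] <- sizes$chrom[ci]
      out$pos[comp == "background"] <- floor(runif(n_bg) * sizes$length[ci])
    }

    n_tss <- sum(comp == "tss")
    if (n_tss > 0) {
      gi <- sample.int(nrow(g), n_tss, replace = TRUE, prob = g$w_tss)
      off <- rnorm(n_tss, 0, config$tss_sd)
      bad <- abs(off) > config$tss_truncation
      while (any(bad)) {
        off[bad] <- rnorm(sum(bad), 0, config$tss_sd)
        bad <- abs(off) > config$tss_truncation
      }
      len <- setNames(sizes$length, sizes$chrom)
      pos <- pmin(pmax(g$tss[gi] + round(off), 0), len[g$chrom[gi]] - 1)
      out$chrom[comp == "tss"] <- g$chrom[gi]
      out$pos[comp == "tss"] <- pos
      out$gene_id[comp == "tss"] <- g$gene_id[gi]
    }

    n_body <- sum(comp == "body")
    if (n_body > 0) {
      gi <- sample.int(nrow(g), n_body, replace = TRUE, prob = g$w_body)
      pos <- g$body_start[gi] +
        floor(runif(n_body) * (g$body_end[gi] - g$body_start[gi]))
      out$chrom[comp == "body"] <- g$chrom[gi]
      out$pos[comp == "body"] <- pos
      out$gene_id[comp == "body"] <- g$gene_id[gi]
    }
    out
  })

  gene_expected <- tibble(
    gene_id = g$gene_id,
    expected_tss = sum(draw$component == "tss") * g$w_tss / sum(g$w_tss)
  )
  breaks <- tibble(chrom = draw$chrom, pos = draw$pos, sample = condition)
  list(breaks = breaks, truth = mutate(draw, sample = condition),
       gene_expected = gene_expected)
}

#' Render breaks as a contaminated paired-end SAM file
#'
#' Each break becomes one proper read pair whose first mate's 5' nucleotide
#' sits exactly on the break position (first-mate orientation
#' Bernoulli(0.5), flipped where the chromosome edge forces it), with
#' fragment length uniform in the configured range. PCR-duplicate pairs and
#' contaminant records (secondary, supplementary, unmapped, QC-fail) are
#' then injected at the configured rates and the body lines shuffled.
#'
#' @param breaks break tibble (`chrom`, `pos`).
#' @param config a [sim_config()].
#' @param path optional output path; lines are written there when given.
#' @param seed optional seed overriding the config seed.
#' @return (invisibly when `path` is given) a list with `lines` (SAM text)
#'   and `injected` (tibble `type`, `n` of injected duplicate pairs and
#'   contaminant records).
#' @export
breaks_to_sam <- function(breaks, config, path = NULL, seed = config$seed) {
  sizes <- tibble(chrom = config$chrom_name, length = config$chrom_length)
  len <- setNames(sizes$length, sizes$chrom)
  n <- nrow(breaks)

  res <- local_seed(sub_seed(seed, 4), {
    flen <- sample(config$fragment_min:config$fragment_max, n, replace = TRUE)
    fwd <- runif(n) < 0.5
    L <- len[breaks$chrom]
    pos <- breaks$pos
    can_fwd <- pos + flen <= L
    can_rev <- flen <= pos + 1
    flen <- ifelse(!can_fwd & !can_rev,
                   pmax(config$fragment_min, pmin(L - pos, pos + 1)), flen)
    can_fwd <- pos + flen <= L
    can_rev <- flen <= pos + 1
    fwd <- ifelse(fwd & !can_fwd, FALSE, ifelse(!fwd & !can_rev, TRUE, fwd))

    span <- pmin(config$read_length, flen)
    qname <- sprintf("frag%07d", seq_len(n))
    r1_start <- ifelse(fwd, pos, pos - span + 1)
    r2_start <- ifelse(fwd, pos + flen - span, pos - flen + 1)
    r1_flag <- ifelse(fwd, 99L, 83L)
    r2_flag <- ifelse(fwd, 147L, 163L)
    r1_tlen <- ifelse(fwd, flen, -flen)

    sam_line <- function(qn, fl, cr, st, cg, p_mate, tl) {
      sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t*\t*",
              qn, fl, cr, as.integer(st) + 1L, cg, as.integer(p_mate) + 1L,
              as.integer(tl))
    }
    cg <- sprintf("%dM", span)
    l1 <- sam_line(qname, r1_flag, breaks$chrom, r1_start, cg, r2_start, r1_tlen)
    l2 <- sam_line(qname, r2_flag, breaks$chrom, r2_start, cg, r1_start, -r1_tlen)

    body <- c(l1, l2)
    injected <- tibble(type = c("duplicate_pairs", "secondary",
                                "supplementary", "unmapped", "qcfail"),
                      n = 0)

    k_dup <- round(config$duplicate_rate * n)
    if (k_dup > 0) {
      src <- sample.int(n, k_dup, replace = TRUE)
      dq <- sprintf("zdup%06d", seq_len(k_dup))
      body <- c(body,
                sam_line(dq, r1_flag[src], breaks$chrom[src], r1_start[src],
                         cg[src], r2_start[src], r1_tlen[src]),
                sam_line(dq, r2_flag[src], breaks$chrom[src], r2_start[src],
                         cg[src], r1_start[src], -r1_tlen[src]))
      injected$n[injected$type == "duplicate_pairs"] <- k_dup
    }

    rates <- config$contaminant_rates
    add_contam <- function(body, type, make) {
      k <- round((rates[[type]] %||% 0) * n)
      if (k > 0) {
        body <- c(body, make(k))
        injected$n[injected$type == type] <<- k
      }
      body
    }
    body <- add_contam(body, "secondary", function(k) {
      src <- sample.int(n, k, replace = TRUE)
      sam_line(sprintf("zsec%06d", seq_len(k)),
               bitwOr(r1_flag[src], 0x100L), breaks$chrom[src],
               r1_start[src], cg[src], r2_start[src], r1_tlen[src])
    })
    body <- add_contam(body, "supplementary", function(k) {
      src <- sample.int(n, k, replace = TRUE)
      sam_line(sprintf("zsup%06d", seq_len(k)),
               bitwOr(r1_flag[src], 0x800L), breaks$chrom[src],
               r1_start[src], cg[src], r2_start[src], r1_tlen[src])
    })
    body <- add_contam(body, "unmapped", function(k) {
      sprintf("zunm%06d\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*", seq_len(k))
    })
    body <- add_contam(body, "qcfail", function(k) {
      src <- sample.int(n, k, replace = TRUE)
      sam_line(sprintf("zqcf%06d", seq_len(k)),
               bitwOr(r1_flag[src], 0x200L), breaks$chrom[src],
               r1_start[src], cg[src], r2_start[src], r1_tlen[src])
    })

    list(body = body[sample.int(length(body))], injected = injected)
  })

  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", sizes$chrom,
                      as.integer(sizes$length)))
  out <- list(lines = c(header, res$body), injected = res$injected)
  if (!is.null(path)) {
    writeLines(out$lines, path)
    return(invisible(out))
  }
  out
}

#' Write a gene tibble as BED6
#'
#' @param genes gene tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genes_bed <- function(genes, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", genes$chrom,
                     as.integer(genes$tx_start), as.integer(genes$tx_end),
                     genes$gene_id, genes$strand), path)
  invisible(path)
}

#' Simulate a complete on-disk dataset
#'
#' Generates the toy genome, expression table and one SAM file per
#' configured condition (plus truth tables), writing everything a pipeline
#' run consumes into `dir`.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return (invisibly) a named list of written paths.
#' @export
simulate_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- make_genome(config)
  expr <- make_expression(genome$genes, config)
  paths <- list(
    genes = file.path(dir, "genes.bed"),
    chrom_sizes = file.path(dir, "sizes.tsv"),
    expression = file.path(dir, "expr.tsv")
  )
  write_genes_bed(genome$genes, paths$genes)
  writeLines(sprintf("%s\t%d", genome$chrom_sizes$chrom,
                     as.integer(genome$chrom_sizes$length)), paths$chrom_sizes)
  writeLines(sprintf("%s\t%g", expr$gene_id, expr$fpkm), paths$expression)
  for (i in seq_along(config$conditions)) {
    cond <- names(config$conditions)[i]
    sim <- simulate_breaks(genome$genes, expr, cond, config,
                           seed = sub_seed(config$seed, 10 + i))
    sam_path <- file.path(dir, paste0(cond, ".sam"))
    breaks_to_sam(sim$breaks, config, path = sam_path,
                  seed = sub_seed(config$seed, 20 + i))
    write_results_tsv(sim$truth, file.path(dir, paste0(cond, "_truth.tsv")))
    paths[[paste0("sam_", cond)]] <- sam_path
  }
  invisible(paths)
}
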
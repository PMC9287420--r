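#' Default pipeline parameters
#'
#' The tunable parameters of a pipeline run and their defaults: filter
#' bounds, annotation window sizes, coverage half-widths, decile count and
#' enrichment-calling settings.
#'
#' @return a named list of defaults.
#' @export
default_run_params <- function() {
  list(
    min_frag = 100, max_frag = 2000, min_mapq = 0,
    tss_flank = 250, promoter_flank = 1000, tts_flank = 250,
    coverage_halfwidth = 500, enrich_halfwidth = 250,
    flank = 2000, bin_width = 100, n_bins = 10,
    fc_threshold = 1.5, min_support = 5, pseudocount = 0.5,
    genes_dialect = "bed6"
  )
}

#' Validate a pipeline run configuration
#'
#' A run config is a list (or YAML file) with `inputs` (named `sam` paths
#' per sample, `genes`, `chrom_sizes`, `expression`), `case` / `control`
#' sample names, and optional `params` overriding [default_run_params()].
#' Unknown keys and non-positive window sizes are rejected before any
#' stage runs.
#'
#' @param config list or path to a YAML file.
#' @return the validated config with defaults filled in.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  allowed_top <- c("inputs", "params", "case", "control")
  unknown <- setdiff(names(config), allowed_top)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  needed_inputs <- c("sam", "genes", "chrom_sizes", "expression")
  missing <- setdiff(needed_inputs, names(config$inputs))
  if (length(missing) > 0) {
    abort(sprintf("missing inputs: %s", paste(missing, collapse = ", ")))
  }
  params <- default_run_params()
  unknown_p <- setdiff(names(config$params), names(params))
  if (length(unknown_p) > 0) {
    abort(sprintf("unknown param(s): %s", paste(unknown_p, collapse = ", ")))
  }
  params[names(config$params)] <- config$params
  for (k in c("min_frag", "max_frag", "tss_flank", "promoter_flank",
              "tts_flank", "coverage_halfwidth", "enrich_halfwidth",
              "flank", "bin_width", "n_bins")) {
    if (!is.numeric(params[[k]]) || params[[k]] <= 0) {
      abort(sprintf("param '%s' must be a positive number", k))
    }
  }
  config$params <- params
  samples <- names(config$inputs$sam)
  if (is.null(config$case)) config$case <- samples[1]
  if (is.null(config$control)) config$control <- samples[min(2, length(samples))]
  if (!all(c(config$case, config$control) %in% samples)) {
    abort("case/control must name entries of inputs$sam")
  }
  config
}

#' Run the full break-mapping pipeline
#'
#' Orchestrates extract, annotate, profile and enrich over one or more
#' samples: break extraction with QC report per SAM input, priority
#' feature annotation with breaks/Mb densities, expression-decile coverage
#' comparison (case vs control) with paired Wilcoxon tests and boxplot
#' summaries, TSS metaprofiles for top and bottom deciles, gene-length
#' association, and per-gene fold-change enrichment calls. All outputs are
#' TSVs under `out_dir` plus a `manifest.json` recording input checksums,
#' the resolved config, package version and per-stage row counts;
#' re-running on identical inputs reproduces identical files.
#'
#' @param config run configuration (list or YAML path), see
#'   [validate_run_config()].
#' @param out_dir output directory.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_run_config(config)
  p <- config$params
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  inputs <- c(unlist(config$inputs$sam),
              genes = config$inputs$genes,
              chrom_sizes = config$inputs$chrom_sizes,
              expression = config$inputs$expression)
  checksums <- tools::md5sum(inputs)

  genes <- stage("read_genes",
                 read_gene_table(config$inputs$genes, dialect = p$genes_dialect))
  sizes <- stage("read_chrom_sizes", read_chrom_sizes(config$inputs$chrom_sizes))
  expr <- stage("read_expression", read_expression(config$inputs$expression))

  samples <- names(config$inputs$sam)
  extractions <- list()
  for (s in samples) {
    extractions[[s]] <- stage(paste0("extract_", s), {
      ex <- extract_breaks(config$inputs$sam[[s]], min_frag = p$min_frag,
                           max_frag = p$max_frag, min_mapq = p$min_mapq,
                           sample = s)
      write_breaks_bed(ex$breaks, file.path(out_dir, paste0(s, "_breaks.bed")))
      write_results_tsv(ex$report, file.path(out_dir, paste0(s, "_report.tsv")))
      ex
    })
  }

  partition <- stage("build_partition",
                     build_partition(genes, sizes, tss_flank = p$tss_flank,
                                     promoter_flank = p$promoter_flank,
                                     tts_flank = p$tts_flank))
  ann_counts <- list()
  for (s in samples) {
    ann_counts[[s]] <- stage(paste0("annotate_", s), {
      summ <- annotate_breaks(extractions[[s]]$breaks, partition)
      write_results_tsv(as_tibble(summ),
                        file.path(out_dir, paste0(s, "_annotation.tsv")))
      summ
    })
  }

  bins <- stage("expression_bins", bin_genes_by_expression(expr, p$n_bins))
  case <- config$case
  control <- config$control
  lib <- vapply(extractions, function(e) nrow(e$breaks), double(1))

  cov <- lapply(extractions, function(e)
    tss_window_counts(e$breaks, genes, half_width = p$coverage_halfwidth))
  comparison <- stage("decile_comparison", {
    dc <- decile_comparison(cov[[case]], cov[[control]], bins,
                            labels = c(case, control),
                            lib_a = lib[[case]], lib_b = lib[[control]])
    write_results_tsv(dc$tests, file.path(out_dir, "decile_tests.tsv"))
    write_results_tsv(dc$box, file.path(out_dir, "decile_box.tsv"))
    dc
  })

  stage("metaprofiles", {
    top <- genes[genes$gene_id %in%
                   bins$gene_id[bins$expression_bin == p$n_bins], ]
    bottom <- genes[genes$gene_id %in%
                      bins$gene_id[bins$expression_bin == 1], ]
    profs <- purrr::imap_dfr(extractions, function(e, s) {
      bind_rows(
        mutate(tss_metaprofile(e$breaks, top, flank = p$flank,
                               bin_width = p$bin_width),
               sample = s, decile = "top"),
        mutate(tss_metaprofile(e$breaks, bottom, flank = p$flank,
                               bin_width = p$bin_width),
               sample = s, decile = "bottom"))
    })
    write_results_tsv(profs, file.path(out_dir, "metaprofiles.tsv"))
  })

  length_assoc <- list()
  for (s in samples) {
    length_assoc[[s]] <- stage(paste0("length_association_", s), {
      la <- length_association(extractions[[s]]$breaks, genes,
                               library_size = lib[[s]],
                               inner_flank = p$tss_flank)
      write_results_tsv(mutate(la$per_bin, sample = s),
                        file.path(out_dir, paste0(s, "_length_bins.tsv")))
      la
    })
  }

  enriched <- stage("enrichment", {
    cov250 <- lapply(extractions, function(e)
      tss_window_counts(e$breaks, genes, half_width = p$enrich_halfwidth))
    calls <- call_enriched(cov250[[case]], cov250[[control]], expr,
                           lib_case = lib[[case]], lib_control = lib[[control]],
                           fc_threshold = p$fc_threshold,
                           min_support = p$min_support,
                           pseudocount = p$pseudocount)
    write_results_tsv(as_tibble(calls), file.path(out_dir, "enriched_genes.tsv"))
    calls
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("breakscape")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config[c("case", "control", "params")],
    input_checksums = as.list(checksums),
    counts = list(
      n_genes = nrow(genes),
      n_expressed = nrow(bins),
      libraries = as.list(lib),
      extraction = lapply(extractions, function(e) as.list(e$report)),
      annotation_totals = lapply(ann_counts, function(a)
        sum(a$n_breaks)),
      territory_bp = as.list(setNames(partition$territory$territory_bp,
                                      as.character(partition$territory$category))),
      n_enriched = nrow(enriched),
      spearman = lapply(length_assoc, function(l) as.list(l$spearman))
    )
  )
  tmp <- file.path(out_dir, "manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
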
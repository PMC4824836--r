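# End-to-end orchestration: synthetic or file-based cohorts through QC,
# fitting, calling, enrichment and CYCLOPS reporting.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its working default: the
#' ploidy-relative loss factor 0.7, the recurrent-region thresholds (loss in
#' at least 20 % of tumors over more than 1 Mb), the correlation-filter
#' alpha, the fitting grids and the QC thresholds. Round-trips through YAML
#' unchanged via [write_config()] / [read_config()].
#'
#' @param mode input mode: generate a synthetic cohort, read SNP-track files,
#'   or read pre-segmented allele-specific profiles (skipping the fit).
#' @param snp_track_files,segment_file,genes_bed,gene_sets_gmt,expression_file
#'   input paths for the file-based modes.
#' @param n_tumors,n_genes,chrom_sizes,snp_spacing,stop_size,cyclops_size,rho_range,ploidy_choices,loss_rate_in_set,loss_rate_background,coupled_fraction,expr_slope,expr_noise_sd,het_fraction,lrr_sd,baf_sd
#'   synthetic-cohort controls (see the synth functions).
#' @param gamma,penalty,min_snps,rho_grid,psi_grid,max_homdel_mb fit controls.
#' @param loss_factor,min_freq,min_size_mb,gap_mb calling controls.
#' @param filter_alpha,n_perm,n_resample,ordering_seeds enrichment controls.
#' @param downreg_alpha,downreg_min_group CYCLOPS controls.
#' @param seed master seed.
#' @param qc QC thresholds, see [qc_thresholds()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "snp-tracks", "segment-profiles"),
                            snp_track_files = NULL, segment_file = NULL,
                            genes_bed = NULL, gene_sets_gmt = NULL,
                            expression_file = NULL,
                            n_tumors = 20, n_genes = 400,
                            chrom_sizes = c(60e6, 60e6, 60e6),
                            snp_spacing = 2e4,
                            stop_size = 60, cyclops_size = 20,
                            rho_range = c(0.3, 1), ploidy_choices = c(1.7, 2.0, 3.6),
                            loss_rate_in_set = 0.4, loss_rate_background = 0.1,
                            coupled_fraction = 0.6, expr_slope = 1,
                            expr_noise_sd = 0.5,
                            het_fraction = 0.3, lrr_sd = 0.25, baf_sd = 0.03,
                            gamma = 0.55, penalty = 4, min_snps = 5,
                            rho_grid = seq(0.10, 1.00, by = 0.01),
                            psi_grid = seq(1.0, 5.5, by = 0.05),
                            max_homdel_mb = 10,
                            loss_factor = 0.7, min_freq = 0.2,
                            min_size_mb = 1, gap_mb = 0.5,
                            filter_alpha = 0.05, n_perm = 200, n_resample = 200,
                            ordering_seeds = 1:3,
                            downreg_alpha = 0.05, downreg_min_group = 3,
                            seed = 1, qc = qc_thresholds()) {
  cfg <- as.list(environment())
  cfg$mode <- match.arg(mode)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  num <- c("chrom_sizes", "rho_range", "ploidy_choices", "rho_grid", "psi_grid",
           "ordering_seeds")
  for (k in num) if (!is.null(cfg[[k]])) cfg[[k]] <- as.numeric(cfg[[k]])
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read and validate pipeline inputs
#'
#' Loads the files named by the config for the file-based modes, checks the
#' coordinate system (0-based half-open; invalid rows are rejected with line
#' numbers) and verifies that expression samples are a subset of the
#' copy-number samples, listing offenders otherwise. In synthetic mode the
#' cohort is generated.
#'
#' @param config a `pipeline_config`.
#' @return list: `genome`/`genes`, `sets`, `truth` (synthetic only),
#'   `tracks` or `solutions`, `expression`.
#' @export
read_inputs <- function(config) {
  cfg <- config
  if (cfg$mode == "synthetic") {
    genome <- make_genome(cfg$seed, cfg$chrom_sizes, cfg$snp_spacing, cfg$n_genes)
    sets <- make_gene_sets(genome, cfg$stop_size, cfg$cyclops_size, seed = cfg$seed + 1)
    truth <- simulate_cohort_truth(genome, sets, cfg$n_tumors,
                                   rho_range = cfg$rho_range,
                                   ploidy_choices = cfg$ploidy_choices,
                                   loss_rate_in_set = cfg$loss_rate_in_set,
                                   loss_rate_background = cfg$loss_rate_background,
                                   seed = cfg$seed + 2)
    tracks <- lapply(seq_along(truth), function(i)
      render_snp_track(truth[[i]], genome, gamma = cfg$gamma,
                       lrr_sd = cfg$lrr_sd, baf_sd = cfg$baf_sd,
                       het_fraction = cfg$het_fraction, seed = cfg$seed + 10 + i))
    expression <- simulate_expression(truth, genome,
                                      coupled_fraction = cfg$coupled_fraction,
                                      slope = cfg$expr_slope,
                                      noise_sd = cfg$expr_noise_sd,
                                      seed = cfg$seed + 3)
    return(list(genome = genome, genes = genome$genes, sets = sets$sets,
                truth = truth, tracks = tracks, expression = expression))
  }
  genes <- read_bed_genes(cfg$genes_bed)
  sets <- if (!is.null(cfg$gene_sets_gmt)) read_gmt(cfg$gene_sets_gmt) else list()
  expression <- if (!is.null(cfg$expression_file)) read_expression(cfg$expression_file) else NULL
  out <- list(genes = genes, sets = sets, expression = expression)
  if (cfg$mode == "snp-tracks") {
    out$tracks <- lapply(cfg$snp_track_files, read_snp_track)
    cn_samples <- vapply(out$tracks, function(t) attr(t, "sample_id"), "")
  } else {
    out$solutions <- read_segments(cfg$segment_file)
    cn_samples <- vapply(out$solutions, `[[`, "", "sample_id")
  }
  if (!is.null(expression)) {
    extra <- setdiff(colnames(expression), cn_samples)
    if (length(extra))
      stopf("expression samples absent from copy-number input: %s",
            paste(extra, collapse = ", "))
  }
  out
}

#' Run the full analysis pipeline
#'
#' QC-failed samples are excluded before fitting and listed with their reason
#' (flat BAF / noisy LRR / low content); all downstream stages run on the
#' passing samples only, and the manifest records the sample funnel.
#'
#' @param config a `pipeline_config`.
#' @return a `report_bundle`: list with `funnel`, `qc`, `solutions`,
#'   `fractions`, `freq_track`, `regions`, `gene_calls`, `enrichment`,
#'   `cyclops`, `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  inputs <- read_inputs(cfg)
  genes <- inputs$genes

  if (!is.null(inputs$solutions)) {
    solutions <- inputs$solutions
    qc_tab <- data.frame(sample = vapply(solutions, `[[`, "", "sample_id"),
                         status = "pass", reason = "", stringsAsFactors = FALSE)
  } else {
    fits <- lapply(inputs$tracks, function(tr)
      fit_ascn(tr, gamma = cfg$gamma, qc = cfg$qc, penalty = cfg$penalty,
               min_snps = cfg$min_snps, rho_grid = cfg$rho_grid,
               psi_grid = cfg$psi_grid, max_homdel_mb = cfg$max_homdel_mb))
    status <- vapply(fits, `[[`, "", "status")
    reason <- vapply(fits, function(f) {
      if (f$status == "qc_failed")
        paste(c("flat_baf", "noisy_lrr", "low_content")[
          c(f$qc$flat_baf, f$qc$noisy_lrr, f$qc$low_content)], collapse = ",")
      else if (f$status == "unidentifiable") "unidentifiable"
      else ""
    }, "")
    qc_tab <- data.frame(sample = vapply(fits, `[[`, "", "sample_id"),
                         status = ifelse(status == "ok", "pass", "excluded"),
                         reason = reason, stringsAsFactors = FALSE)
    solutions <- lapply(fits[status == "ok"], `[[`, "solution")
  }
  if (!length(solutions))
    stopf("no samples passed QC and fitting: empty cohort")

  fractions <- t(vapply(solutions, genome_fractions, numeric(2),
                        factor = cfg$loss_factor))
  fractions <- data.frame(sample = vapply(solutions, sol_id, ""),
                          fractions, stringsAsFactors = FALSE)

  positions <- if (!is.null(inputs$genome)) {
    do.call(rbind, lapply(names(inputs$genome$snps), function(cn)
      data.frame(chrom = cn, pos = inputs$genome$snps[[cn]])))
  } else {
    # no SNP backbone in file mode: evaluate the track on a regular grid at
    # the synthetic default probe spacing over the segment-covered extent
    segs <- do.call(rbind, lapply(solutions, seg_df))
    do.call(rbind, lapply(split(segs, segs$chrom), function(s)
      data.frame(chrom = s$chrom[1],
                 pos = seq(min(s$start) + cfg$snp_spacing / 2, max(s$end) - 1,
                           by = cfg$snp_spacing))))
  }
  freq_track <- loss_frequency(solutions, positions, factor = cfg$loss_factor)
  regions <- recurrent_loss_regions(freq_track, min_freq = cfg$min_freq,
                                    min_size_mb = cfg$min_size_mb,
                                    gap_mb = cfg$gap_mb)
  regions <- annotate_regions(regions, genes, inputs$sets)

  gene_calls <- cohort_gene_calls(solutions, genes, factor = cfg$loss_factor)

  enrichment <- NULL
  cyclops <- NULL
  if (!is.null(inputs$expression)) {
    stop_set <- inputs$sets$stop_like %||% inputs$sets[["stop"]]
    if (!is.null(stop_set)) {
      enrichment <- tryCatch({
        mr <- mean_relative_cn(gene_calls)
        corr <- cn_expression_correlation(relative_cn_matrix(gene_calls),
                                          inputs$expression)
        max_p_over_orderings(mr, corr, stop_set, seeds = cfg$seed + cfg$ordering_seeds,
                             filter_alpha = cfg$filter_alpha,
                             n_resample = cfg$n_resample, n_perm = cfg$n_perm)
      }, error = function(e) structure(list(message = conditionMessage(e)),
                                       class = "enrichment_skipped"))
    }
    cyc_set <- inputs$sets$cyclops_like %||% inputs$sets[["cyclops"]]
    if (!is.null(cyc_set))
      cyclops <- cyclops_report(gene_calls, inputs$expression, cyc_set,
                                alpha = cfg$downreg_alpha,
                                min_group = cfg$downreg_min_group)
  }

  funnel <- c(n_input = nrow(qc_tab),
              n_pass = sum(qc_tab$status == "pass"),
              n_flat_baf = sum(grepl("flat_baf", qc_tab$reason)),
              n_noisy_lrr = sum(grepl("noisy_lrr", qc_tab$reason)),
              n_low_content = sum(grepl("low_content", qc_tab$reason)),
              n_unidentifiable = sum(qc_tab$reason == "unidentifiable"))

  structure(list(config = cfg, funnel = funnel, qc = qc_tab,
                 solutions = solutions, fractions = fractions,
                 freq_track = freq_track, regions = regions,
                 gene_calls = gene_calls, enrichment = enrichment,
                 cyclops = cyclops, sets = inputs$sets, genes = genes,
                 truth = inputs$truth),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  f <- x$funnel
  cat(sprintf("report_bundle: %d samples in, %d analyzed (flat_baf %d, noisy_lrr %d, low_content %d, unidentifiable %d)\n",
              f["n_input"], f["n_pass"], f["n_flat_baf"], f["n_noisy_lrr"],
              f["n_low_content"], f["n_unidentifiable"]))
  cat(sprintf("  mean fraction lost %.3f, mean fraction LOH %.3f; %d recurrent regions\n",
              mean(x$fractions$fraction_lost), mean(x$fractions$fraction_loh),
              nrow(x$regions)))
  if (!is.null(x$enrichment) && is.null(x$enrichment$message))
    cat(sprintf("  STOP-like enrichment: max empirical p = %.4g over %d orderings\n",
                x$enrichment$max_empirical_p, nrow(x$enrichment$per_seed)))
  if (!is.null(x$cyclops)) print(x$cyclops)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits tab-delimited tables (header-only when empty, never absent), the
#' gene sets as GMT, the configuration as YAML, and a manifest listing every
#' output with its md5 checksum and the sample funnel. Regenerating with the
#' same config and seeds yields byte-identical files.
#'
#' @param bundle a `report_bundle`.
#' @param outdir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
write_reports <- function(bundle, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create output directory %s", outdir)
  }
  wt <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- character(0)
  paths <- c(paths, wt(bundle$qc, "qc_summary.tsv"))
  paths <- c(paths, wt(bundle$fractions, "fractions.tsv"))
  paths <- c(paths, wt(bundle$freq_track, "loss_frequency.tsv"))
  paths <- c(paths, wt(bundle$regions, "regions.tsv"))
  paths <- c(paths, wt(as.data.frame(bundle$gene_calls), "gene_calls.tsv"))
  seg_path <- file.path(outdir, "solutions.tsv")
  write_segments(bundle$solutions, seg_path)
  paths <- c(paths, seg_path)
  if (length(bundle$sets)) {
    gmt_path <- file.path(outdir, "gene_sets.gmt")
    write_gmt(bundle$sets, gmt_path)
    paths <- c(paths, gmt_path)
  }
  if (!is.null(bundle$enrichment) && is.null(bundle$enrichment$message))
    paths <- c(paths, wt(bundle$enrichment$per_seed, "enrichment.tsv"))
  if (!is.null(bundle$cyclops)) {
    paths <- c(paths, wt(bundle$cyclops$genes, "cyclops_genes.tsv"))
    paths <- c(paths, wt(bundle$cyclops$per_tumor, "cyclops_per_tumor.tsv"))
  }
  cfg_path <- file.path(outdir, "config.yaml")
  write_config(bundle$config, cfg_path)
  paths <- c(paths, cfg_path)

  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  funnel_df <- data.frame(metric = names(bundle$funnel),
                          value = as.integer(bundle$funnel))
  wt(funnel_df, "funnel.tsv")
  wt(manifest, "manifest.tsv")
  invisible(manifest)
}
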
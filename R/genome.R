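#' Build a synthetic genome model
#'
#' Constructs the backbone for cohort simulation: chromosomes of the requested
#' sizes carrying a regular grid of SNP probes, plus non-overlapping genes each
#' guaranteed to cover at least one SNP. Coordinates are 0-based half-open
#' throughout the package.
#'
#' @param seed integer seed; the model is deterministic given the seed.
#' @param chrom_sizes numeric vector of chromosome lengths in bp.
#' @param snp_spacing distance between adjacent SNP probes in bp.
#' @param n_genes total number of genes to place across the genome
#'   (allocated to chromosomes proportionally to their length).
#' @param chrom_names optional chromosome names; defaults to `chr1`, `chr2`, ...
#'
#' @return An object of class `genome_model`: a list with `chromosomes`
#'   (data.frame: chrom, length), `snps` (named list of sorted positions) and
#'   `genes` (data.frame: gene_id, chrom, start, end).
#' @export
make_genome <- function(seed, chrom_sizes, snp_spacing = 10000, n_genes = 200,
                        chrom_names = NULL) {
  if (snp_spacing <= 0) stopf("`snp_spacing` must be > 0")
  if (n_genes < 1) stopf("`n_genes` must be >= 1")
  if (any(chrom_sizes < snp_spacing)) stopf("every chromosome must host >= 1 SNP")
  nc <- length(chrom_sizes)
  chrom_names <- chrom_names %||% paste0("chr", seq_len(nc))

  snps <- lapply(chrom_sizes, function(sz) {
    pos <- seq(from = floor(snp_spacing / 2), to = sz - 1, by = snp_spacing)
    as.numeric(pos)
  })
  names(snps) <- chrom_names

  # largest-remainder allocation of genes proportional to chromosome length
  share <- n_genes * chrom_sizes / sum(chrom_sizes)
  alloc <- floor(share)
  rem <- n_genes - sum(alloc)
  if (rem > 0) {
    ord <- order(share - alloc, decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1
  }

  genes <- with_seed(seed, {
    out <- vector("list", nc)
    for (ci in seq_len(nc)) {
      ng <- alloc[ci]
      if (ng == 0) next
      sz <- chrom_sizes[ci]
      slot <- floor(sz / ng)
      if (slot < snp_spacing)
        stopf("chromosome %s (%.0f bp) too small to host %d non-overlapping genes at %.0f bp SNP spacing",
              chrom_names[ci], sz, ng, snp_spacing)
      pos <- snps[[ci]]
      gs <- ge <- numeric(ng)
      for (gi in seq_len(ng)) {
        lo <- (gi - 1) * slot
        hi <- gi * slot
        idx <- which(pos >= lo & pos < hi)
        if (!length(idx))
          stopf("no SNP available in gene slot %d on %s", gi, chrom_names[ci])
        span <- sample.int(min(5L, length(idx)), 1L)
        a <- idx[sample.int(length(idx) - span + 1L, 1L)]
        b <- a + span - 1L
        pad <- floor(snp_spacing / 4)
        gs[gi] <- max(lo, pos[a] - pad)
        ge[gi] <- min(hi, pos[b] + pad + 1)
      }
      out[[ci]] <- data.frame(chrom = chrom_names[ci], start = gs, end = ge,
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  genes <- genes[order(match(genes$chrom, chrom_names), genes$start), , drop = FALSE]
  genes <- data.frame(gene_id = sprintf("g%04d", seq_len(nrow(genes))), genes,
                      stringsAsFactors = FALSE)
  rownames(genes) <- NULL

  structure(list(
    chromosomes = data.frame(chrom = chrom_names, length = as.numeric(chrom_sizes),
                             stringsAsFactors = FALSE),
    snps = snps,
    genes = genes
  ), class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chromosomes), "chromosomes,",
      sum(lengths(x$snps)), "SNPs,", nrow(x$genes), "genes\n")
  invisible(x)
}

#' Designate STOP-like, CYCLOPS-like and neutral gene sets
#'
#' Samples disjoint gene sets without replacement from a genome model. The
#' default sizes (878 and 55) match the curated STOP and CYCLOPS candidate
#' lists consumed by the real analysis. STOP-like genes are sampled in
#' spatial clusters (anchor genes plus their nearest neighbors), emulating
#' their concentration in recurrently deleted regions; this lets the cohort
#' simulator hit a whole cluster with one contiguous loss segment instead of
#' blanketing the genome with per-gene events. CYCLOPS-like genes are sampled
#' uniformly from the remainder: their deletion is incidental, so they carry
#' no spatial structure of their own.
#'
#' @param genome a `genome_model`.
#' @param stop_size,cyclops_size set sizes.
#' @param seed integer seed.
#' @param cluster_size target number of STOP-like genes per spatial cluster.
#' @return A `gene_set_collection`: list with `sets` (named list of gene_id
#'   vectors: `stop_like`, `cyclops_like`, `neutral`) and `stop_clusters`
#'   (list of gene_id vectors partitioning `stop_like`).
#' @export
make_gene_sets <- function(genome, stop_size = 878, cyclops_size = 55, seed = 1,
                           cluster_size = 15) {
  genes <- genome$genes
  ids <- genes$gene_id
  if (stop_size + cyclops_size > length(ids))
    stopf("stop_size + cyclops_size (%d) exceeds number of genes (%d)",
          stop_size + cyclops_size, length(ids))
  res <- with_seed(seed, {
    n_clusters <- max(1L, round(stop_size / cluster_size))
    anchors <- sample.int(nrow(genes), n_clusters)
    # genome-order index distance to the nearest anchor on the same chromosome
    taken <- logical(nrow(genes))
    clusters <- vector("list", n_clusters)
    quota <- rep(floor(stop_size / n_clusters), n_clusters)
    quota[seq_len(stop_size - sum(quota))] <- quota[seq_len(stop_size - sum(quota))] + 1
    for (k in seq_len(n_clusters)) {
      a <- anchors[k]
      same <- which(genes$chrom == genes$chrom[a] & !taken)
      ord <- same[order(abs(same - a))]
      pick <- utils::head(ord, quota[k])
      taken[pick] <- TRUE
      clusters[[k]] <- genes$gene_id[sort(pick)]
    }
    short <- stop_size - sum(lengths(clusters))
    if (short > 0) {  # chromosome exhausted near an anchor: top up anywhere
      extra <- sample(which(!taken), short)
      taken[extra] <- TRUE
      clusters[[length(clusters) + 1]] <- genes$gene_id[sort(extra)]
    }
    stop_like <- unlist(clusters)
    cyclops_like <- sample(setdiff(ids, stop_like), cyclops_size)
    list(sets = list(stop_like = sort(stop_like),
                     cyclops_like = sort(cyclops_like),
                     neutral = sort(setdiff(ids, c(stop_like, cyclops_like)))),
         stop_clusters = clusters)
  })
  structure(res, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:",
      paste(sprintf("%s=%d", names(x$sets), lengths(x$sets)), collapse = ", "), "\n")
  invisible(x)
}
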
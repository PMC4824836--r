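# Gene- and cohort-level loss/LOH calling from allele-specific copy-number
# profiles.

seg_df <- function(x) {
  if (inherits(x, "ascn_solution")) x$segments
  else if (inherits(x, "truth_profile")) x$segments
  else x
}

sol_psi <- function(x) {
  if (inherits(x, "ascn_solution")) x$psi
  else if (inherits(x, "truth_profile")) x$psi_true
  else stopf("cannot determine average ploidy from a bare segment table")
}

sol_id <- function(x, default = "sample") {
  if (inherits(x, "ascn_solution")) x$sample_id %||% default
  else if (inherits(x, "truth_profile")) x$sample_id
  else default
}

#' Project segment copy numbers onto genes
#'
#' Total copy number is the overlap-length-weighted mean of the overlapping
#' segments' totals (so a small intragenic sliver cannot dominate the call);
#' the minor copy number is the minimum minor allele over overlapping
#' segments (so any overlapping LOH segment confers LOH). Genes overlapping
#' no assessable segment get `NA` (unassessable).
#'
#' @param x an `ascn_solution`, `truth_profile`, or segment data.frame with
#'   columns chrom, start, end, nA, nB (0-based half-open).
#' @param genes data.frame: gene_id, chrom, start, end.
#' @return data.frame: gene_id, total_cn, minor_cn (NA when unassessable),
#'   rows aligned with `genes`.
#' @export
gene_copy_number <- function(x, genes) {
  segs <- seg_df(x)
  segs <- segs[!is.na(segs$nA) & !is.na(segs$nB), , drop = FALSE]
  out <- data.frame(gene_id = genes$gene_id,
                    total_cn = NA_real_, minor_cn = NA_real_,
                    stringsAsFactors = FALSE)
  if (!nrow(segs)) return(out)
  gr_g <- as_granges0(genes$chrom, genes$start, genes$end)
  gr_s <- as_granges0(segs$chrom, segs$start, segs$end)
  hits <- GenomicRanges::findOverlaps(gr_g, gr_s)
  if (!length(hits)) return(out)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ow <- GenomicRanges::width(GenomicRanges::pintersect(gr_g[qh], gr_s[sh]))
  tot <- segs$nA[sh] + segs$nB[sh]
  minor <- pmin(segs$nA[sh], segs$nB[sh])
  out$total_cn <- as.numeric(tapply(ow * tot, qh, sum)[as.character(seq_len(nrow(genes)))]) /
    as.numeric(tapply(ow, qh, sum)[as.character(seq_len(nrow(genes)))])
  out$minor_cn <- as.numeric(tapply(minor, qh, min)[as.character(seq_len(nrow(genes)))])
  out
}

#' Ploidy-relative loss threshold
#'
#' The working definition of copy-number loss: total copy number strictly
#' below `factor` times the sample's average ploidy. For example with an
#' average ploidy of 2.31 the threshold is 0.7 x 2.31 = 1.617.
#'
#' @param psi average ploidy.
#' @param factor loss factor in (0, 1].
#' @return the loss threshold `factor * psi`.
#' @export
loss_threshold <- function(psi, factor = 0.7) {
  if (!(factor > 0 && factor <= 1)) stopf("`factor` must lie in (0, 1]")
  factor * psi
}

#' Call ploidy-relative copy-number loss
#'
#' @param total_cn numeric vector of total copy numbers.
#' @param psi the sample's average ploidy (> 0).
#' @param factor loss factor; loss means `total_cn < factor * psi` (strict).
#' @return logical vector (NA propagates).
#' @export
call_losses <- function(total_cn, psi, factor = 0.7) {
  if (!(factor > 0 && factor <= 1)) stopf("`factor` must lie in (0, 1]")
  if (!is.finite(psi) || psi <= 0) stopf("`psi` must be > 0")
  total_cn < loss_threshold(psi, factor)
}

#' Call loss of heterozygosity
#'
#' LOH means minor-allele copy number zero; this includes copy-neutral LOH
#' and homozygous deletions.
#'
#' @param minor_cn numeric vector of minor-allele copy numbers.
#' @return logical vector (NA propagates).
#' @export
call_loh <- function(minor_cn) minor_cn == 0

#' Per-gene, per-sample calls across a cohort
#'
#' @param solutions list of `ascn_solution`s and/or `truth_profile`s.
#' @param genes gene table (gene_id, chrom, start, end).
#' @param factor loss factor.
#' @return `gene_calls` data.frame in long format: gene_id, sample, total_cn,
#'   minor_cn, relative_cn, is_loss, is_loh.
#' @export
cohort_gene_calls <- function(solutions, genes, factor = 0.7) {
  rows <- lapply(solutions, function(sol) {
    psi <- sol_psi(sol)
    cn <- gene_copy_number(sol, genes)
    data.frame(gene_id = cn$gene_id, sample = sol_id(sol),
               total_cn = cn$total_cn, minor_cn = cn$minor_cn,
               relative_cn = cn$total_cn / psi,
               is_loss = call_losses(cn$total_cn, psi, factor),
               is_loh = call_loh(cn$minor_cn),
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  class(calls) <- c("gene_calls", "data.frame")
  calls
}

#' Fractions of the genome subject to loss and LOH
#'
#' Base-pair-length-weighted fractions over the assessable autosomal extent
#' of one solution.
#'
#' @param solution an `ascn_solution` or `truth_profile`.
#' @param factor loss factor.
#' @return named numeric vector `c(fraction_lost, fraction_loh)`.
#' @export
genome_fractions <- function(solution, factor = 0.7) {
  segs <- seg_df(solution)
  psi <- sol_psi(solution)
  use <- !is.na(segs$nA) & drop_sex_chroms(segs$chrom)
  segs <- segs[use, , drop = FALSE]
  if (!nrow(segs)) stopf("zero assessable extent")
  w <- segs$end - segs$start
  tot <- segs$nA + segs$nB
  c(fraction_lost = sum(w[call_losses(tot, psi, factor)]) / sum(w),
    fraction_loh = sum(w[call_loh(pmin(segs$nA, segs$nB))]) / sum(w))
}

# loss state of one solution at given positions; NA where not assessable
state_at_positions <- function(solution, positions, factor = 0.7) {
  segs <- seg_df(solution)
  psi <- sol_psi(solution)
  loss <- rep(NA, nrow(positions))
  for (cn in unique(positions$chrom)) {
    pi <- which(positions$chrom == cn)
    sc <- which(segs$chrom == cn & !is.na(segs$nA))
    if (!length(sc)) next
    o <- sc[order(segs$start[sc])]
    idx <- findInterval(positions$pos[pi], segs$start[o])
    inside <- idx >= 1 & positions$pos[pi] < segs$end[o][pmax(idx, 1)]
    tot <- segs$nA[o][idx[inside]] + segs$nB[o][idx[inside]]
    loss[pi[inside]] <- call_losses(tot, psi, factor)
  }
  loss
}

#' Cohort loss-frequency track
#'
#' At each position, the fraction of assessable tumors with copy-number loss;
#' tumors unassessable at a position are excluded from that position's
#' denominator.
#'
#' @param solutions list of `ascn_solution`s / `truth_profile`s.
#' @param positions data.frame: chrom, pos (typically the SNP positions, the
#'   native resolution of the analysis).
#' @param factor loss factor.
#' @return data.frame: chrom, pos, frequency, n_assessable.
#' @export
loss_frequency <- function(solutions, positions, factor = 0.7) {
  if (!length(solutions)) stopf("need at least one solution")
  states <- vapply(solutions, state_at_positions, logical(nrow(positions)),
                   positions = positions, factor = factor)
  states <- matrix(states, nrow = nrow(positions))
  n_ok <- rowSums(!is.na(states))
  freq <- ifelse(n_ok > 0, rowSums(states, na.rm = TRUE) / n_ok, NA_real_)
  out <- data.frame(chrom = positions$chrom, pos = positions$pos,
                    frequency = freq, n_assessable = n_ok,
                    stringsAsFactors = FALSE)
  class(out) <- c("loss_freq_track", "data.frame")
  out
}

#' Recurrent loss regions
#'
#' Maximal runs of contiguous positions whose loss frequency reaches
#' `min_freq`, merged across gaps smaller than `gap_mb`, reported only when
#' strictly larger than `min_size_mb`.
#'
#' @param freq_track output of [loss_frequency()].
#' @param min_freq minimum loss frequency.
#' @param min_size_mb strict minimum region size in Mb.
#' @param gap_mb positions further apart than this break a run.
#' @return data.frame: chrom, start, end, size_mb, max_frequency.
#' @export
recurrent_loss_regions <- function(freq_track, min_freq = 0.2,
                                   min_size_mb = 1, gap_mb = 0.5) {
  if (!nrow(freq_track)) stopf("empty frequency track")
  empty <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      size_mb = numeric(0), max_frequency = numeric(0),
                      stringsAsFactors = FALSE)
  hit <- !is.na(freq_track$frequency) & freq_track$frequency >= min_freq
  ft <- freq_track[hit, , drop = FALSE]
  if (!nrow(ft)) return(empty)
  out <- list()
  for (cn in unique(ft$chrom)) {
    fc <- ft[ft$chrom == cn, , drop = FALSE]
    fc <- fc[order(fc$pos), , drop = FALSE]
    run <- cumsum(c(1, diff(fc$pos) >= gap_mb * 1e6))
    for (rid in unique(run)) {
      rr <- fc[run == rid, , drop = FALSE]
      size_mb <- (max(rr$pos) + 1 - min(rr$pos)) / 1e6
      if (size_mb > min_size_mb)
        out[[length(out) + 1]] <- data.frame(
          chrom = cn, start = min(rr$pos), end = max(rr$pos) + 1,
          size_mb = size_mb, max_frequency = max(rr$frequency),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate recurrent regions with gene-set members
#'
#' A gene belongs to a region iff its interval intersects it (genes straddling
#' a boundary are included).
#'
#' @param regions output of [recurrent_loss_regions()].
#' @param genes gene table (gene_id, chrom, start, end).
#' @param gene_sets a `gene_set_collection` or named list of gene_id vectors
#'   (uses `stop_like` and `cyclops_like` when present).
#' @param tsg optional character vector of tumor-suppressor gene ids.
#' @return `regions` with added columns `cyclops_genes`, `n_stop`,
#'   `stop_genes`, `tsg_genes` (comma-separated lists).
#' @export
annotate_regions <- function(regions, genes, gene_sets, tsg = character(0)) {
  sets <- if (inherits(gene_sets, "gene_set_collection")) gene_sets$sets else gene_sets
  regions$cyclops_genes <- character(nrow(regions))
  regions$n_stop <- integer(nrow(regions))
  regions$stop_genes <- character(nrow(regions))
  regions$tsg_genes <- character(nrow(regions))
  if (!nrow(regions)) return(regions)
  gr_r <- as_granges0(regions$chrom, regions$start, regions$end)
  gr_g <- as_granges0(genes$chrom, genes$start, genes$end)
  hits <- GenomicRanges::findOverlaps(gr_r, gr_g)
  for (i in seq_len(nrow(regions))) {
    members <- genes$gene_id[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]]
    sg <- intersect(members, sets$stop_like %||% character(0))
    cg <- intersect(members, sets$cyclops_like %||% character(0))
    tg <- intersect(members, tsg)
    regions$cyclops_genes[i] <- paste(cg, collapse = ",")
    regions$n_stop[i] <- length(sg)
    regions$stop_genes[i] <- paste(sg, collapse = ",")
    regions$tsg_genes[i] <- paste(tg, collapse = ",")
  }
  regions
}
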
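# Synthetic-cohort generator: ground-truth allele-specific copy-number
# profiles, rendered SNP tracks and coupled expression matrices.

# merge possibly overlapping [start, end) intervals into a disjoint union
merge_intervals <- function(start, end) {
  if (!length(start)) return(data.frame(start = numeric(0), end = numeric(0)))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i]) else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

# one loss-segment length, log-uniform between 1 Mb and half the chromosome
draw_loss_length <- function(chrom_len) {
  lo <- min(1e6, chrom_len / 2)
  hi <- max(lo + 1, chrom_len / 2)
  exp(stats::runif(1, log(lo), log(hi)))
}

#' Simulate ground-truth copy-number profiles for a cohort
#'
#' Each tumor gets an aberrant-cell fraction drawn from `rho_range`, a base
#' copy state derived from a draw from `ploidy_choices`, and contiguous
#' multi-megabase loss segments. Losses are planted so that genes in the
#' STOP-like set are hit with probability `loss_rate_in_set` and all other
#' genes with at least `loss_rate_background`, in expectation; targeted
#' events cover a whole spatial STOP-gene cluster at once (see
#' [make_gene_sets()]), keeping the genome-wide loss footprint near the
#' background rate. Loss segments
#' reduce the total copy number to `floor(0.7 * base)`, i.e. strictly below
#' the ploidy-relative loss threshold, removing copies from the minor allele
#' first (so single-copy losses of a diploid region also create LOH).
#'
#' When the drawn ploidy choice lies below the base state (e.g. 1.7 with a
#' diploid base), additional background losses are added until the lost
#' fraction of the genome reaches the deficit, so the realized average ploidy
#' approaches the choice. The authoritative truth is always `psi_true`,
#' recomputed from the realized segments.
#'
#' @param genome a `genome_model`.
#' @param sets a `gene_set_collection` (uses `sets$stop_like`).
#' @param n_tumors cohort size.
#' @param rho_range interval for the aberrant-cell fraction.
#' @param ploidy_choices vector of target average ploidies.
#' @param loss_rate_in_set,loss_rate_background per-gene loss probabilities.
#' @param seed integer seed.
#' @return list of `truth_profile` objects: `sample_id`, `rho`,
#'   `segments` (chrom, start, end, nA, nB tiling each chromosome) and
#'   `psi_true` (length-weighted mean total copy number).
#' @export
simulate_cohort_truth <- function(genome, sets, n_tumors,
                                  rho_range = c(0.3, 1),
                                  ploidy_choices = c(1.7, 2.0, 3.6),
                                  loss_rate_in_set = 0.4,
                                  loss_rate_background = 0.1,
                                  seed = 1) {
  if (!length(ploidy_choices)) stopf("`ploidy_choices` must be nonempty")
  if (!(loss_rate_background >= 0 && loss_rate_background <= loss_rate_in_set &&
        loss_rate_in_set <= 1))
    stopf("need 0 <= loss_rate_background <= loss_rate_in_set <= 1")
  chroms <- genome$chromosomes
  G <- sum(chroms$length)
  # spatial clusters of STOP-like genes; sets built from GMT input fall back
  # to one cluster per gene
  stop_clusters <- sets$stop_clusters %||%
    as.list(sets$sets$stop_like %||% character(0))

  with_seed(seed, lapply(seq_len(n_tumors), function(ti) {
    rho <- stats::runif(1, rho_range[1], rho_range[2])
    choice <- ploidy_choices[sample.int(length(ploidy_choices), 1L)]
    base <- max(1L, as.integer(round(choice)))
    nA_b <- ceiling(base / 2); nB_b <- floor(base / 2)
    loss_total <- max(0L, as.integer(floor(0.7 * base)))
    d <- base - loss_total
    nB_l <- max(nB_b - d, 0L); nA_l <- loss_total - nB_l

    # background coverage target: configured rate, raised to the ploidy deficit
    f_deficit <- if (base > choice && base > loss_total)
      (base - choice) / (base - loss_total) else 0
    c_bg <- min(0.95, max(loss_rate_background, f_deficit))
    raw_target <- -log(1 - c_bg) * G

    ls_chrom <- character(0); ls_s <- numeric(0); ls_e <- numeric(0)
    tot <- 0
    while (tot < raw_target) {
      ci <- sample.int(nrow(chroms), 1L, prob = chroms$length)
      L <- min(draw_loss_length(chroms$length[ci]), chroms$length[ci])
      s <- stats::runif(1, 0, chroms$length[ci] - L)
      ls_chrom <- c(ls_chrom, chroms$chrom[ci])
      ls_s <- c(ls_s, s); ls_e <- c(ls_e, s + L)
      tot <- tot + L
    }

    # targeted segments: each STOP-like cluster is covered by one contiguous
    # loss event with probability q, so every member gene's total loss rate is
    # q + c_bg (1 - q) = loss_rate_in_set
    q <- max(0, (loss_rate_in_set - c_bg) / (1 - c_bg))
    if (q > 0 && length(stop_clusters)) {
      hit <- stats::runif(length(stop_clusters)) < q
      for (k in which(hit)) {
        cg <- genome$genes[genome$genes$gene_id %in% stop_clusters[[k]], , drop = FALSE]
        for (cn in unique(cg$chrom)) {
          gg <- cg[cg$chrom == cn, ]
          clen <- chroms$length[match(cn, chroms$chrom)]
          span_lo <- min(gg$start); span_hi <- max(gg$end)
          L <- min(max(draw_loss_length(clen), (span_hi - span_lo) + 2), clen)
          s <- stats::runif(1, max(0, span_hi - L), min(span_lo, clen - L))
          ls_chrom <- c(ls_chrom, cn)
          ls_s <- c(ls_s, s); ls_e <- c(ls_e, s + L)
        }
      }
    }

    # shallow single-copy losses for high-ploidy bases: common in aneuploid
    # tumors, they stay above the loss threshold but give the genome odd copy
    # states that anchor the ploidy fit
    sh_chrom <- character(0); sh_s <- numeric(0); sh_e <- numeric(0)
    if (base >= 4) {
      sh_target <- 0.08 * G
      tot_sh <- 0
      while (tot_sh < sh_target) {
        ci <- sample.int(nrow(chroms), 1L, prob = chroms$length)
        L <- min(draw_loss_length(chroms$length[ci]), chroms$length[ci])
        s <- stats::runif(1, 0, chroms$length[ci] - L)
        sh_chrom <- c(sh_chrom, chroms$chrom[ci])
        sh_s <- c(sh_s, s); sh_e <- c(sh_e, s + L)
        tot_sh <- tot_sh + L
      }
    }

    segs <- lapply(seq_len(nrow(chroms)), function(ci) {
      cn <- chroms$chrom[ci]; clen <- chroms$length[ci]
      sel <- ls_chrom == cn
      iv <- merge_intervals(pmax(0, ls_s[sel]), pmin(clen, ls_e[sel]))
      ssel <- sh_chrom == cn
      sv <- merge_intervals(pmax(0, sh_s[ssel]), pmin(clen, sh_e[ssel]))
      bnd <- sort(unique(c(0, iv$start, iv$end, sv$start, sv$end, clen)))
      st <- bnd[-length(bnd)]; en <- bnd[-1]
      mid <- (st + en) / 2
      deep <- vapply(mid, function(m) any(iv$start <= m & m < iv$end), logical(1))
      shallow <- !deep &
        vapply(mid, function(m) any(sv$start <= m & m < sv$end), logical(1))
      data.frame(chrom = cn, start = st, end = en,
                 nA = ifelse(deep, nA_l, ifelse(shallow, nA_b, nA_b)),
                 nB = ifelse(deep, nB_l, ifelse(shallow, nB_b - 1, nB_b)),
                 stringsAsFactors = FALSE)
    })
    segments <- do.call(rbind, segs)
    rownames(segments) <- NULL
    w <- segments$end - segments$start
    psi_true <- sum(w * (segments$nA + segments$nB)) / sum(w)
    structure(list(sample_id = sprintf("T%03d", ti), rho = rho,
                   segments = segments, psi_true = psi_true),
              class = "truth_profile")
  }))
}

#' Recompute the length-weighted average ploidy of a truth profile
#' @param truth a `truth_profile`.
#' @return numeric average ploidy.
#' @export
truth_psi <- function(truth) {
  w <- truth$segments$end - truth$segments$start
  sum(w * (truth$segments$nA + truth$segments$nB)) / sum(w)
}

#' @export
print.truth_profile <- function(x, ...) {
  cat(sprintf("truth_profile %s: rho=%.3f psi=%.3f (%d segments)\n",
              x$sample_id, x$rho, x$psi_true, nrow(x$segments)))
  invisible(x)
}

#' Render LRR/BAF SNP signals from a truth profile
#'
#' Applies the mixture model that the allele-specific fit inverts: a tumor
#' sample is a mixture of aberrant cells (fraction rho, integer allele copy
#' numbers per segment) and diploid normal cells. For a SNP in a segment with
#' allele copies (nA, nB), total mixture copy number is
#' `2(1-rho) + rho(nA+nB)`; the expected LRR is
#' `gamma * log2(mix / psi_mix)` where `psi_mix` is the genome-wide mean
#' mixture copy number (median-centering against the mixture ploidy, matching
#' tumor-vs-matched-normal ratios) and `gamma` the platform compression
#' factor. Germline-heterozygous SNPs get expected BAF
#' `(1 - rho + rho * nB') / mix` with `nB'` equal to nB or nA with equal
#' probability per segment (phase symmetry about 0.5); homozygous SNPs sit at
#' 0 or 1. Gaussian noise is added and BAF clipped to [0, 1].
#'
#' @param truth a `truth_profile`.
#' @param genome the `genome_model` supplying SNP positions.
#' @param gamma platform compression factor in (0, 1].
#' @param lrr_sd,baf_sd Gaussian noise standard deviations.
#' @param het_fraction fraction of SNPs heterozygous in the matched normal.
#' @param seed integer seed.
#' @return `snp_track` data.frame: chrom, pos, lrr, baf, is_het (sorted), with
#'   attributes `sample_id` and `rho_true`.
#' @export
render_snp_track <- function(truth, genome, gamma = 0.55,
                             lrr_sd = 0.25, baf_sd = 0.03,
                             het_fraction = 0.3, seed = 1) {
  if (!(truth$rho >= 0 && truth$rho <= 1)) stopf("rho must lie in [0, 1]")
  if (!(gamma > 0 && gamma <= 1)) stopf("gamma must lie in (0, 1]")
  if (lrr_sd < 0 || baf_sd < 0) stopf("noise SDs must be >= 0")
  rho <- truth$rho
  segs <- truth$segments

  with_seed(seed, {
    # per-segment phase: is the B allele the major or the minor haplotype?
    nBp_seg <- ifelse(stats::runif(nrow(segs)) < 0.5, segs$nA, segs$nB)

    per_chrom <- lapply(names(genome$snps), function(cn) {
      pos <- genome$snps[[cn]]
      cs <- which(segs$chrom == cn)
      if (!length(cs)) return(NULL)
      idx <- cs[findInterval(pos, segs$start[cs])]
      data.frame(chrom = cn, pos = pos,
                 ntot = segs$nA[idx] + segs$nB[idx],
                 nBp = nBp_seg[idx], stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, per_chrom)
    n <- nrow(df)
    mix <- 2 * (1 - rho) + rho * df$ntot
    psi_mix <- mean(mix)
    lrr <- gamma * log2(mix / psi_mix) + stats::rnorm(n, 0, lrr_sd)

    is_het <- stats::runif(n) < het_fraction
    baf <- numeric(n)
    baf[is_het] <- (1 - rho + rho * df$nBp[is_het]) / mix[is_het]
    baf[!is_het] <- sample(c(0, 1), sum(!is_het), replace = TRUE)
    baf <- pmin(1, pmax(0, baf + stats::rnorm(n, 0, baf_sd)))

    track <- data.frame(chrom = df$chrom, pos = df$pos, lrr = lrr,
                        baf = baf, is_het = is_het, stringsAsFactors = FALSE)
    attr(track, "sample_id") <- truth$sample_id
    attr(track, "rho_true") <- rho
    class(track) <- c("snp_track", "data.frame")
    track
  })
}

#' Simulate a gene-by-sample expression matrix coupled to copy number
#'
#' A labeled `coupled_fraction` of genes have expression
#' `baseline + slope * (total copy number / psi) + noise`; the remainder are
#' copy-number independent. Coupling labels are attached for test oracles.
#'
#' @param truth_cohort list of `truth_profile`s.
#' @param genome the `genome_model`.
#' @param coupled_fraction probability that a gene is copy-number coupled.
#' @param slope expression units per unit of relative copy number.
#' @param noise_sd Gaussian noise SD.
#' @param seed integer seed.
#' @return numeric matrix (genes x samples) with attribute `coupled`, a named
#'   logical vector.
#' @export
simulate_expression <- function(truth_cohort, genome, coupled_fraction = 0.6,
                                slope = 1, noise_sd = 0.5, seed = 1) {
  if (coupled_fraction < 0 || coupled_fraction > 1)
    stopf("`coupled_fraction` must lie in [0, 1]")
  genes <- genome$genes
  samples <- vapply(truth_cohort, `[[`, "", "sample_id")
  rel <- vapply(truth_cohort, function(tp) {
    cn <- gene_copy_number(tp$segments, genes)
    cn$total_cn / tp$psi_true
  }, numeric(nrow(genes)))
  with_seed(seed, {
    coupled <- stats::runif(nrow(genes)) < coupled_fraction
    baseline <- stats::rnorm(nrow(genes), 5, 1)
    expr <- matrix(baseline, nrow(genes), length(samples)) +
      slope * rel * coupled +
      matrix(stats::rnorm(length(rel), 0, noise_sd), nrow(genes), length(samples))
    dimnames(expr) <- list(genes$gene_id, samples)
    names(coupled) <- genes$gene_id
    attr(expr, "coupled") <- coupled
    expr
  })
}
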
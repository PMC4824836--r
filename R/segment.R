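# Joint segmentation of the (LRR, mirrored BAF) signal at informative SNPs.

# Binary segmentation on a two-column signal matrix. Returns end indices of
# segments (the last one is nrow(X)). Gaussian SSE cost with a per-changepoint
# penalty; both dimensions share the split.
binseg2 <- function(X, penalty, min_snps) {
  n <- nrow(X)
  if (n < 2 * min_snps) return(n)
  cs <- apply(X, 2, cumsum)
  css <- apply(X^2, 2, cumsum)
  csum <- function(i) if (i >= 1) cs[i, ] else c(0, 0)
  cssum <- function(i) if (i >= 1) css[i, ] else c(0, 0)
  segcost <- function(l, r) {
    len <- r - l + 1
    s <- csum(r) - csum(l - 1)
    ss <- cssum(r) - cssum(l - 1)
    sum(ss - s^2 / len)
  }
  ends <- integer(0)
  queue <- list(c(1L, n))
  while (length(queue)) {
    lr <- queue[[1]]; queue <- queue[-1]
    l <- lr[1]; r <- lr[2]
    if (l + min_snps - 1L > r - min_snps) { ends <- c(ends, r); next }
    ks <- seq.int(l + min_snps - 1L, r - min_snps)
    lenL <- ks - l + 1; lenR <- r - ks
    sL1 <- cs[ks, 1] - (if (l > 1) cs[l - 1, 1] else 0)
    sL2 <- cs[ks, 2] - (if (l > 1) cs[l - 1, 2] else 0)
    ssL1 <- css[ks, 1] - (if (l > 1) css[l - 1, 1] else 0)
    ssL2 <- css[ks, 2] - (if (l > 1) css[l - 1, 2] else 0)
    sR1 <- cs[r, 1] - cs[ks, 1]; sR2 <- cs[r, 2] - cs[ks, 2]
    ssR1 <- css[r, 1] - css[ks, 1]; ssR2 <- css[r, 2] - css[ks, 2]
    cost_split <- (ssL1 - sL1^2 / lenL) + (ssL2 - sL2^2 / lenL) +
      (ssR1 - sR1^2 / lenR) + (ssR2 - sR2^2 / lenR)
    gain <- segcost(l, r) - cost_split
    k <- ks[which.max(gain)]
    if (max(gain) > penalty) {
      queue <- c(queue, list(c(l, k)), list(c(k + 1L, r)))
    } else ends <- c(ends, r)
  }
  sort(ends)
}

#' Segment a SNP track into regions of constant copy-number signal
#'
#' Joint changepoint detection on the two-dimensional signal formed by the LRR
#' and the mirrored BAF (`0.5 + |baf - 0.5|`) of germline-heterozygous SNPs,
#' smoothing random SNP-to-SNP variation before model fitting. Chromosome
#' boundaries are always changepoints. Both signals are standardized by a
#' robust noise estimate (median absolute successive difference) so the
#' penalty is in units of noise variance.
#'
#' @param track an `snp_track`.
#' @param penalty changepoint penalty multiplier; a split is accepted when the
#'   cost reduction exceeds `penalty * log(n_het)` on the standardized scale.
#' @param min_snps minimum informative SNPs per segment.
#' Per-segment mirrored BAF is estimated with a noise-bias-corrected second
#' moment (the plain mean of `|baf - 0.5|` is inflated by `sd * sqrt(2/pi)`
#' for balanced segments, which would masquerade as allelic imbalance).
#'
#' @return `segmented_track` data.frame: chrom, start, end, mean_lrr,
#'   mean_mbaf, n_informative. Chromosomes without enough heterozygous SNPs
#'   are kept as rows with `NA` means (marked unassessable, not dropped);
#'   their names are in `attr(, "unassessable")`.
#' @export
segment_track <- function(track, penalty = 4, min_snps = 5) {
  if (!nrow(track)) stopf("empty SNP track")
  track <- track[order(match(track$chrom, unique(track$chrom)), track$pos), ]
  unassessable <- character(0)
  out <- list()
  for (cn in unique(track$chrom)) {
    tc <- track[track$chrom == cn, ]
    het <- tc[tc$is_het, ]
    ext_lo <- min(tc$pos); ext_hi <- max(tc$pos) + 1
    if (nrow(het) < max(2L, min_snps)) {
      unassessable <- c(unassessable, cn)
      out[[cn]] <- data.frame(chrom = cn, start = ext_lo, end = ext_hi,
                              mean_lrr = NA_real_, mean_mbaf = NA_real_,
                              n_informative = nrow(het), stringsAsFactors = FALSE)
      next
    }
    mbaf <- 0.5 + abs(het$baf - 0.5)
    scl <- function(x) max(stats::median(abs(diff(x))) / (sqrt(2) * 0.6745), 1e-6)
    X <- cbind(het$lrr / scl(het$lrr), mbaf / scl(mbaf))
    ends <- binseg2(X, penalty * log(nrow(het)), min_snps)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    bnd_lo <- c(ext_lo, floor((het$pos[utils::head(ends, -1L)] +
                                 het$pos[utils::head(ends, -1L) + 1L]) / 2))
    bnd_hi <- c(bnd_lo[-1], ext_hi)
    # folding |baf - 0.5| inflates the mean of balanced segments by about
    # sd * sqrt(2/pi); the second-moment estimator removes the bias:
    # E[(baf-0.5)^2] = divergence^2 + noise^2
    sd_b <- scl(het$baf)
    out[[cn]] <- data.frame(
      chrom = cn, start = bnd_lo, end = bnd_hi,
      mean_lrr = vapply(seq_along(ends), function(i)
        mean(het$lrr[starts[i]:ends[i]]), 0),
      mean_mbaf = vapply(seq_along(ends), function(i)
        0.5 + sqrt(max(0, mean((het$baf[starts[i]:ends[i]] - 0.5)^2) - sd_b^2)), 0),
      n_informative = ends - starts + 1L, stringsAsFactors = FALSE)
  }
  seg <- do.call(rbind, out)
  rownames(seg) <- NULL
  attr(seg, "unassessable") <- unassessable
  attr(seg, "sample_id") <- attr(track, "sample_id")
  class(seg) <- c("segmented_track", "data.frame")
  seg
}
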
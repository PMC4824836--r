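#' QC thresholds for sample-level exclusion
#'
#' Defaults reproduce the exclusion taxonomy used for tumor/normal SNP-array
#' pairs: flat BAFs (very low tumor content genome-wide), excessively variable
#' LRRs (experimental artifacts), and low-content samples whose segmented LRR
#' and BAF signals both carry almost no aberration signal.
#'
#' @param flat_baf_div absolute BAF divergence from 0.5 that counts a het SNP
#'   as "diverged".
#' @param flat_baf_frac flag `flat_baf` when the diverged fraction of het SNPs
#'   falls below this.
#' @param noisy_lrr_mad flag `noisy_lrr` when the median absolute successive
#'   LRR difference exceeds this.
#' @param low_lrr_var minimal variance of binned LRR means for a sample to
#'   count as carrying copy-number signal.
#' @param low_baf_frac minimal diverged-het fraction for a sample to count as
#'   carrying allelic-imbalance signal.
#' @param lrr_bin number of SNPs per bin for the smoothed-LRR variance metric.
#' @return list of thresholds.
#' @export
qc_thresholds <- function(flat_baf_div = 0.1, flat_baf_frac = 0.005,
                          noisy_lrr_mad = 0.5, low_lrr_var = 0.002,
                          low_baf_frac = 0.02, lrr_bin = 200) {
  list(flat_baf_div = flat_baf_div, flat_baf_frac = flat_baf_frac,
       noisy_lrr_mad = noisy_lrr_mad, low_lrr_var = low_lrr_var,
       low_baf_frac = low_baf_frac, lrr_bin = lrr_bin)
}

#' Sample-level quality control of a SNP track
#'
#' Reproduces the three exclusion reasons applied before fitting:
#' `flat_baf` (het BAFs essentially uniformly 0.5, i.e. apparently no aberrant
#' DNA), `noisy_lrr` (excessively variable LRRs as measured by the median
#' absolute successive difference), and `low_content` (neither of the above,
#' but both the binned-LRR variance and the BAF divergence are below minimal
#' signal thresholds).
#'
#' @param track an `snp_track` data.frame (chrom, pos, lrr, baf, is_het).
#' @param thresholds see [qc_thresholds()].
#' @return `qc_flags`: list with logicals `flat_baf`, `noisy_lrr`,
#'   `low_content`, `pass`, and the backing `metrics`.
#' @export
qc_sample <- function(track, thresholds = qc_thresholds()) {
  if (!nrow(track)) stopf("empty SNP track")
  th <- thresholds
  het <- track$baf[track$is_het]
  if (!length(het)) stopf("track has no heterozygous SNPs")
  div_frac <- mean(abs(het - 0.5) > th$flat_baf_div)
  lrr_mad <- stats::median(abs(diff(track$lrr)))

  flat_baf <- div_frac < th$flat_baf_frac
  noisy_lrr <- !flat_baf && lrr_mad > th$noisy_lrr_mad

  # binned LRR means stand in for a segmentation when probing residual signal
  nb <- max(1L, floor(nrow(track) / th$lrr_bin))
  bins <- rep(seq_len(nb), each = ceiling(nrow(track) / nb))[seq_len(nrow(track))]
  bin_var <- if (nb > 1) stats::var(tapply(track$lrr, bins, mean)) else 0
  low_content <- !flat_baf && !noisy_lrr &&
    bin_var < th$low_lrr_var && div_frac < th$low_baf_frac

  structure(list(flat_baf = flat_baf, noisy_lrr = noisy_lrr,
                 low_content = low_content,
                 pass = !(flat_baf || noisy_lrr || low_content),
                 metrics = list(baf_diverged_fraction = div_frac,
                                lrr_successive_mad = lrr_mad,
                                binned_lrr_variance = bin_var)),
            class = "qc_flags")
}

#' @export
print.qc_flags <- function(x, ...) {
  status <- if (x$pass) "PASS" else
    paste("FAIL:", paste(c("flat_baf", "noisy_lrr", "low_content")[
      c(x$flat_baf, x$noisy_lrr, x$low_content)], collapse = ","))
  cat(sprintf("qc_flags [%s] diverged-het=%.4f lrr-mad=%.3f bin-var=%.5f\n",
              status, x$metrics$baf_diverged_fraction,
              x$metrics$lrr_successive_mad, x$metrics$binned_lrr_variance))
  invisible(x)
}
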
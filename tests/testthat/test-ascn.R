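test_that("QC reproduces the three exclusion reasons", {
  g <- fix_genome()
  tp <- fix_truth()[[1]]

  flat <- tp; flat$rho <- 0
  qc_flat <- qc_sample(render_snp_track(flat, g, seed = 1))
  expect_true(qc_flat$flat_baf)
  expect_false(qc_flat$noisy_lrr)

  noisy <- qc_sample(render_snp_track(tp, g, lrr_sd = 1.5, seed = 2))
  expect_true(noisy$noisy_lrr)
  expect_gt(noisy$metrics$lrr_successive_mad, 0.5)

  high <- tp; high$rho <- 0.8
  clean <- qc_sample(render_snp_track(high, g, seed = 3))
  expect_false(clean$flat_baf)
  expect_false(clean$noisy_lrr)
  expect_false(clean$low_content)
  expect_true(clean$pass)

  expect_error(qc_sample(data.frame()), "empty")
})

test_that("segmentation recovers noise-free changepoints exactly", {
  g <- fix_genome()
  truth3 <- manual_truth(
    rbind(data.frame(chrom = "chr1", start = 0, end = 20e6, nA = 1, nB = 1),
          data.frame(chrom = "chr1", start = 20e6, end = 40e6, nA = 1, nB = 0),
          data.frame(chrom = "chr1", start = 40e6, end = 60e6, nA = 2, nB = 1),
          data.frame(chrom = "chr2", start = 0, end = 60e6, nA = 1, nB = 1),
          data.frame(chrom = "chr3", start = 0, end = 60e6, nA = 1, nB = 1)),
    rho = 0.6)
  tr <- render_snp_track(truth3, g, lrr_sd = 0, baf_sd = 0, seed = 4)
  seg <- segment_track(tr)
  s1 <- seg[seg$chrom == "chr1", ]
  expect_equal(nrow(s1), 3)
  # each boundary lies between the informative SNPs straddling the true
  # changepoint (exact to +-1 informative SNP)
  hets <- tr$pos[tr$chrom == "chr1" & tr$is_het]
  for (bk in c(20e6, 40e6)) {
    lo <- max(hets[hets < bk]); hi <- min(hets[hets >= bk])
    fitted_bk <- s1$end[which.min(abs(s1$end - bk))]
    expect_gte(fitted_bk, lo)
    expect_lte(fitted_bk, hi)
  }
  expect_equal(nrow(seg[seg$chrom == "chr2", ]), 1)
  expect_equal(nrow(seg[seg$chrom == "chr3", ]), 1)
})

test_that("noisy segmentation localizes most true breakpoints", {
  g <- fix_genome()
  hits <- 0; total <- 0
  for (sd in 1:10) {
    tp <- simulate_cohort_truth(g, fix_sets(), 1, seed = 40 + sd)[[1]]
    tr <- render_snp_track(tp, g, seed = 60 + sd)
    seg <- segment_track(tr)
    for (cn in unique(tp$segments$chrom)) {
      ts <- tp$segments[tp$segments$chrom == cn, ]
      true_bks <- ts$start[-1]
      # drop breakpoints between segments of identical state (invisible)
      st <- paste(ts$nA, ts$nB)
      true_bks <- true_bks[st[-1] != st[-length(st)]]
      if (!length(true_bks)) next
      fit_bks <- seg$start[seg$chrom == cn][-1]
      total <- total + length(true_bks)
      for (b in true_bks)
        if (length(fit_bks) && min(abs(fit_bks - b)) <= 5 * 2e4) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("chromosomes without informative SNPs are marked, not dropped", {
  g <- fix_genome()
  tp <- fix_truth()[[1]]
  tr <- render_snp_track(tp, g, seed = 5)
  tr$is_het[tr$chrom == "chr2"] <- FALSE
  seg <- segment_track(tr)
  expect_true("chr2" %in% seg$chrom)
  expect_true("chr2" %in% attr(seg, "unassessable"))
  expect_true(all(is.na(seg$mean_lrr[seg$chrom == "chr2"])))
})

test_that("noise-free fits land on the truth and invert consistently", {
  g <- fix_genome()
  gamma <- 0.55
  for (i in c(1, 2, 3)) {
    tp <- fix_truth()[[i]]
    tr <- render_snp_track(tp, g, lrr_sd = 0, baf_sd = 0, seed = 100 + i)
    fit <- fit_ascn(tr)
    expect_equal(fit$status, "ok")
    expect_lt(abs(fit$rho - tp$rho), 0.011)          # one rho grid step
    expect_lt(abs(fit$psi - tp$psi_true), 0.05)
    # every fitted segment matches the truth state at its midpoint
    fs <- fit$solution$segments
    fs <- fs[!is.na(fs$nA), ]
    for (j in seq_len(nrow(fs))) {
      st <- truth_state_at(tp, fs$chrom[j], (fs$start[j] + fs$end[j]) / 2)
      expect_equal(unname(fs$nA[j]), unname(st["nA"]))
      expect_equal(unname(fs$nB[j]), unname(st["nB"]))
    }
    # inversion consistency: generative equations applied to the fitted
    # integers reproduce the observed segment means
    rho <- tp$rho
    seg <- fit$segmented
    use <- !is.na(seg$mean_lrr)
    psi_mix <- 2 * (1 - rho) + rho *
      sum(seg$n_informative[use] * (fs$nA + fs$nB)) / sum(seg$n_informative[use])
    mix <- 2 * (1 - rho) + rho * (fs$nA + fs$nB)
    r_hat <- gamma * log2(mix / psi_mix)
    b_hat <- (1 - rho + rho * fs$nA) / mix
    expect_lt(max(abs(r_hat - seg$mean_lrr[use])), 0.02)
    expect_lt(max(abs(b_hat - seg$mean_mbaf[use])), 0.02)
  }
})

test_that("an all-balanced flat genome is reported unidentifiable", {
  g <- fix_genome()
  diploid <- manual_truth(
    do.call(rbind, lapply(g$chromosomes$chrom, function(cn)
      data.frame(chrom = cn, start = 0, end = 60e6, nA = 1, nB = 1))),
    rho = 1)
  tr <- render_snp_track(diploid, g, lrr_sd = 0, baf_sd = 0, seed = 6)
  seg <- segment_track(tr)
  cands <- fit_purity_ploidy(seg)
  expect_length(cands, 0)
  expect_match(attr(cands, "diagnostic"), "unidentifiable")
  fit <- fit_ascn(tr, qc = NULL)  # QC itself would flag the flat BAF first
  expect_equal(fit$status, "unidentifiable")
})

test_that("solution selection applies the homozygous-deletion adjustment", {
  seg_ok <- data.frame(chrom = "chr1", start = 0, end = 60e6, nA = 1, nB = 1)
  seg_hd <- rbind(
    data.frame(chrom = "chr1", start = 0, end = 15e6, nA = 0, nB = 0),
    data.frame(chrom = "chr1", start = 15e6, end = 60e6, nA = 1, nB = 1))
  best_clean <- manual_solution(seg_ok, 0.8, goodness = 0.01)
  expect_identical(select_solution(list(best_clean)), best_clean)

  best_hd <- manual_solution(seg_hd, 0.8, goodness = 0.01)       # psi ~ 1.5
  second <- manual_solution(data.frame(chrom = "chr1", start = 0, end = 60e6,
                                       nA = 2, nB = 1), 0.5, goodness = 0.02)
  expect_gt(best_hd$homdel_mb, 10)
  chosen <- select_solution(list(best_hd, second))
  expect_equal(chosen$psi, second$psi)
  expect_true(isTRUE(chosen$adjusted_homdel))

  # next-best at LOWER ploidy must not be chosen
  lower <- manual_solution(data.frame(chrom = "chr1", start = 0, end = 60e6,
                                      nA = 1, nB = 0), 0.5, goodness = 0.02)
  expect_warning(chosen2 <- select_solution(list(best_hd, lower)), "tolerance")
  expect_true(chosen2$warning_homdel)

  # every candidate over the tolerance: best returned with a warning flag
  expect_warning(chosen3 <- select_solution(list(best_hd)), "tolerance")
  expect_true(chosen3$warning_homdel)
  expect_error(select_solution(list()), "unassessable")
})

test_that("average ploidy is the informative-SNP-weighted mean", {
  all_dip <- manual_solution(data.frame(chrom = "chr1", start = 0, end = 60e6,
                                        nA = 1, nB = 1, n_informative = 100L),
                             0.9, goodness = 0)
  expect_equal(average_ploidy(all_dip), 2.0)

  two_eq <- manual_solution(
    data.frame(chrom = "chr1", start = c(0, 30e6), end = c(30e6, 60e6),
               nA = c(1, 2), nB = c(1, 2), n_informative = c(50L, 50L)),
    0.9, goodness = 0)
  expect_equal(average_ploidy(two_eq), 3.0)

  weighted <- manual_solution(
    data.frame(chrom = "chr1", start = c(0, 30e6), end = c(30e6, 60e6),
               nA = c(1, 3), nB = c(1, 3), n_informative = c(75L, 25L)),
    0.9, goodness = 0)
  expect_equal(average_ploidy(weighted), 3.0)
})

test_that("the fitted model object exposes the standard accessors", {
  g <- fix_genome()
  tp <- fix_truth()[[2]]
  fit <- fit_ascn(render_snp_track(tp, g, seed = 7))
  expect_s3_class(fit, "ascn_fit")
  co <- coef(fit)
  expect_named(co, c("rho", "psi"))
  expect_equal(unname(co["psi"]), average_ploidy(fit$solution), tolerance = 1e-9)
  res <- residuals(fit)
  expect_true(all(abs(res$resid_nA) <= 0.5 + 1e-9, na.rm = TRUE))
  s <- summary(fit)
  expect_output(print(s), "aberrant-cell fraction")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
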
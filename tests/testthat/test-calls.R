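test_that("gene copy number projects segments correctly", {
  genes <- data.frame(gene_id = c("inside", "straddle", "gap"),
                      chrom = "chr1",
                      start = c(1e6, 9e6, 30e6),
                      end = c(2e6, 11e6, 31e6))
  segs <- rbind(
    data.frame(chrom = "chr1", start = 0, end = 10e6, nA = 2, nB = 2),
    data.frame(chrom = "chr1", start = 10e6, end = 12e6, nA = 1, nB = 0))
  cn <- gene_copy_number(segs, genes)
  expect_equal(cn$total_cn[cn$gene_id == "inside"], 4)
  expect_equal(cn$minor_cn[cn$gene_id == "inside"], 2)
  # half in (2,2), half in (1,0): length-weighted mean total, min minor
  expect_equal(cn$total_cn[cn$gene_id == "straddle"], 0.5 * 4 + 0.5 * 1)
  expect_equal(cn$minor_cn[cn$gene_id == "straddle"], 0)
  expect_true(is.na(cn$total_cn[cn$gene_id == "gap"]))

  simple <- gene_copy_number(
    data.frame(chrom = "chr1", start = 0, end = 10e6, nA = 2, nB = 1),
    data.frame(gene_id = "g", chrom = "chr1", start = 1e6, end = 2e6))
  expect_equal(simple$total_cn, 3)
  expect_equal(simple$minor_cn, 1)
})

test_that("the ploidy-relative loss call uses a strict threshold", {
  expect_equal(loss_threshold(2.31), 0.7 * 2.31)
  expect_equal(round(loss_threshold(2.31), 1), 1.6)
  expect_true(call_losses(1, psi = 2.31))
  expect_false(call_losses(2, psi = 2.31))
  expect_false(call_losses(0.7 * 2.31, psi = 2.31))  # boundary: strict
  expect_error(call_losses(1, psi = 2.31, factor = 1.5), "factor")
  expect_error(call_losses(1, psi = 0), "psi")
})

test_that("LOH means zero minor copies, including homozygous deletion", {
  expect_true(call_loh(0))     # (2,0) copy-neutral LOH
  expect_false(call_loh(1))    # (1,1)
  # (0,0): both loss and LOH under the conventions used here
  expect_true(call_loh(0) && call_losses(0, psi = 2))
})

test_that("genome fractions are length-weighted over assessable autosomes", {
  dip <- manual_solution(do.call(rbind, lapply(paste0("chr", 1:10), function(cn)
    data.frame(chrom = cn, start = 0, end = 10e6, nA = 1, nB = 1))),
    0.9, goodness = 0)
  expect_equal(unname(genome_fractions(dip)), c(0, 0))

  # one of ten equal chromosomes at (1,0): psi ~ 1.95, threshold 1.365
  segs <- do.call(rbind, lapply(paste0("chr", 1:10), function(cn)
    data.frame(chrom = cn, start = 0, end = 10e6,
               nA = 1, nB = if (cn == "chr1") 0 else 1)))
  one_loss <- manual_solution(segs, 0.9, goodness = 0)
  fr <- genome_fractions(one_loss)
  expect_equal(unname(fr["fraction_lost"]), 0.1)
  expect_equal(unname(fr["fraction_loh"]), 0.1)

  cn_loh <- manual_solution(data.frame(chrom = "chr1", start = 0, end = 10e6,
                                       nA = 2, nB = 0), 0.9, goodness = 0)
  expect_equal(unname(genome_fractions(cn_loh)), c(0, 1))

  sexless <- manual_solution(data.frame(chrom = "chrX", start = 0, end = 10e6,
                                        nA = 1, nB = 0), 0.9, goodness = 0)
  expect_error(genome_fractions(sexless), "assessable")
})

test_that("loss frequency counts assessable tumors per position", {
  positions <- data.frame(chrom = "chr1", pos = seq(5e5, 9.5e6, by = 1e6))
  loss_seg <- data.frame(chrom = "chr1", start = 0, end = 10e6, nA = 1, nB = 0)
  dip_seg <- data.frame(chrom = "chr1", start = 0, end = 10e6, nA = 1, nB = 1)
  # psi anchors: give each solution a second chromosome to set psi near 2
  anchor <- data.frame(chrom = "chr2", start = 0, end = 90e6, nA = 1, nB = 1)
  lost <- manual_solution(rbind(loss_seg, anchor), 0.9, goodness = 0)
  diploid <- manual_solution(rbind(dip_seg, anchor), 0.9, goodness = 0)

  none <- loss_frequency(rep(list(diploid), 5), positions)
  expect_true(all(none$frequency == 0))

  cohort <- c(rep(list(lost), 3), rep(list(diploid), 7))
  ft <- loss_frequency(cohort, positions)
  expect_true(all(ft$frequency == 0.3))
  expect_true(all(ft$n_assessable == 10))

  # a tumor with no segments on chr1 leaves the denominator
  absent <- manual_solution(anchor, 0.9, goodness = 0)
  cohort2 <- c(rep(list(lost), 3), rep(list(diploid), 6), list(absent))
  ft2 <- loss_frequency(cohort2, positions)
  expect_true(all(ft2$frequency == 3 / 9))
  expect_true(all(ft2$n_assessable == 9))
})

test_that("recurrent regions respect frequency, size and gap rules", {
  mk_track <- function(pos, freq, chrom = "chr1")
    structure(data.frame(chrom = chrom, pos = pos, frequency = freq,
                         n_assessable = 10L),
              class = c("loss_freq_track", "data.frame"))
  pos <- seq(0, 20e6, by = 1e5)

  expect_equal(nrow(recurrent_loss_regions(mk_track(pos, 0.1))), 0)

  # 2 Mb run at 0.25
  f <- ifelse(pos >= 5e6 & pos <= 7e6, 0.25, 0)
  r <- recurrent_loss_regions(mk_track(pos, f))
  expect_equal(nrow(r), 1)
  expect_equal(r$max_frequency, 0.25)
  expect_gt(r$size_mb, 1)

  # exactly 1.0 Mb run: excluded by the strict size rule
  pos1 <- seq(0, 1e6, by = 1e5)          # spans exactly 1.0 Mb + one base
  f1 <- rep(0.3, length(pos1))
  r1 <- recurrent_loss_regions(mk_track(pos1, f1), min_size_mb = 1.000001)
  expect_equal(nrow(r1), 0)

  # gaps below 0.5 Mb are bridged; larger gaps split the region
  f2 <- ifelse((pos >= 2e6 & pos <= 4e6) | (pos >= 4.3e6 & pos <= 6e6), 0.3, 0)
  r2 <- recurrent_loss_regions(mk_track(pos, f2))
  expect_equal(nrow(r2), 1)
  f3 <- ifelse((pos >= 2e6 & pos <= 4e6) | (pos >= 5.5e6 & pos <= 8e6), 0.3, 0)
  r3 <- recurrent_loss_regions(mk_track(pos, f3))
  expect_equal(nrow(r3), 2)
})

test_that("region annotation assigns genes by interval intersection", {
  regions <- data.frame(chrom = "chr1", start = 10e6, end = 20e6,
                        size_mb = 10, max_frequency = 0.3)
  genes <- data.frame(gene_id = c("s1", "s2", "s3", "c1", "edge", "out"),
                      chrom = "chr1",
                      start = c(11e6, 12e6, 13e6, 14e6, 19.9e6, 25e6),
                      end = c(11.1e6, 12.1e6, 13.1e6, 14.1e6, 20.5e6, 25.1e6))
  sets <- list(stop_like = c("s1", "s2", "s3", "out"), cyclops_like = "c1")
  ann <- annotate_regions(regions, genes, sets, tsg = "edge")
  expect_equal(ann$n_stop, 3)
  expect_equal(ann$cyclops_genes, "c1")
  expect_equal(ann$tsg_genes, "edge")   # straddling the boundary counts

  none <- annotate_regions(regions, genes[genes$gene_id == "out", ], sets)
  expect_equal(none$n_stop, 0)
  expect_equal(none$cyclops_genes, "")
})

test_that("loss calls are monotone in the factor and regions in min_freq", {
  truth <- fix_truth()
  genes <- fix_genome()$genes
  n_loss <- vapply(c(0.5, 0.7, 0.9), function(f)
    sum(cohort_gene_calls(truth, genes, factor = f)$is_loss, na.rm = TRUE), 0)
  expect_true(all(diff(n_loss) >= 0))

  positions <- do.call(rbind, lapply(names(fix_genome()$snps), function(cn)
    data.frame(chrom = cn, pos = fix_genome()$snps[[cn]])))
  ft <- loss_frequency(truth, positions)
  # raising min_freq can split one run in two, so the count itself is not
  # monotone; the total reported extent is
  tot_mb <- vapply(c(0.1, 0.2, 0.4), function(mf)
    sum(recurrent_loss_regions(ft, min_freq = mf)$size_mb), 0)
  expect_true(all(diff(tot_mb) <= 0))
})

test_that("gene-based and segment-based lost fractions agree on a gene tiling", {
  # genes tiling one chromosome exactly reproduce the segment fraction
  g <- fix_genome()
  tp <- fix_truth()[[2]]
  tile <- data.frame(gene_id = sprintf("t%03d", 1:60), chrom = "chr1",
                     start = seq(0, 59e6, by = 1e6), end = seq(1e6, 60e6, by = 1e6))
  calls <- cohort_gene_calls(list(tp), tile)
  segs1 <- tp$segments[tp$segments$chrom == "chr1", ]
  w <- segs1$end - segs1$start
  frac_seg <- sum(w[call_losses(segs1$nA + segs1$nB, tp$psi_true)]) / sum(w)
  frac_gene <- mean(calls$is_loss, na.rm = TRUE)
  expect_lt(abs(frac_gene - frac_seg), 2 / 60)  # tiling resolution
})
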
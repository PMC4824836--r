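test_that("make_genome produces the forced counts and is deterministic", {
  g <- make_genome(1, 10e6, snp_spacing = 1e4, n_genes = 100)
  expect_equal(length(g$snps[[1]]), 1000)
  expect_equal(nrow(g$genes), 100)
  g2 <- make_genome(1, 10e6, snp_spacing = 1e4, n_genes = 100)
  expect_identical(g, g2)
  expect_false(identical(g, make_genome(2, 10e6, snp_spacing = 1e4, n_genes = 100)))
})

test_that("genes never overlap and each covers at least one SNP", {
  g <- make_genome(2, c(1e6, 2e6), snp_spacing = 1e3, n_genes = 50)
  for (cn in unique(g$genes$chrom)) {
    gg <- g$genes[g$genes$chrom == cn, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1) expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
    pos <- g$snps[[cn]]
    # brute-force interval check
    covered <- vapply(seq_len(nrow(gg)), function(i)
      any(pos >= gg$start[i] & pos < gg$end[i]), NA)
    expect_true(all(covered))
    expect_true(all(gg$start >= 0 & gg$end <= g$chromosomes$length[
      g$chromosomes$chrom == cn]))
  }
})

test_that("make_genome rejects chromosomes too small for the request", {
  expect_error(make_genome(1, 1e5, snp_spacing = 1e4, n_genes = 50), "small")
})

test_that("gene sets are disjoint, sized, and seed-deterministic", {
  g <- make_genome(3, c(40e6, 40e6, 40e6), 1e4, 2000)
  s <- make_gene_sets(g, seed = 1)  # defaults
  expect_length(s$sets$stop_like, 878)
  expect_length(s$sets$cyclops_like, 55)
  expect_length(intersect(s$sets$stop_like, s$sets$cyclops_like), 0)
  expect_setequal(unlist(s$sets), g$genes$gene_id)
  s2 <- make_gene_sets(g, seed = 1)
  expect_identical(s$sets, s2$sets)
  small <- make_gene_sets(fix_genome(), 10, 5, seed = 1)
  expect_length(intersect(small$sets$stop_like, small$sets$cyclops_like), 0)
  expect_error(make_gene_sets(fix_genome(), 290, 20, seed = 1), "exceeds")
})

test_that("cohort truth respects the configured loss rates", {
  g <- fix_genome(); s <- fix_sets()
  truth <- simulate_cohort_truth(g, s, 20, loss_rate_in_set = 0.4,
                                 loss_rate_background = 0.1, seed = 7,
                                 ploidy_choices = 2)
  calls <- cohort_gene_calls(truth, g$genes)
  rate <- tapply(calls$is_loss, calls$gene_id, mean)
  stop_rate <- mean(rate[s$sets$stop_like])
  bg_rate <- mean(rate[!names(rate) %in% s$sets$stop_like])
  expect_lt(abs(stop_rate - 0.4), 3 * sqrt(0.4 * 0.6 / 20))
  expect_lt(abs(bg_rate - 0.1), 3 * sqrt(0.1 * 0.9 / 20))

  # null configuration: equal rates abolish the STOP/background separation
  null <- simulate_cohort_truth(g, s, 50, loss_rate_in_set = 0.1,
                                loss_rate_background = 0.1, seed = 8,
                                ploidy_choices = 2)
  ncalls <- cohort_gene_calls(null, g$genes)
  nrate <- tapply(ncalls$is_loss, ncalls$gene_id, mean)
  d <- mean(nrate[s$sets$stop_like]) - mean(nrate[!names(nrate) %in% s$sets$stop_like])
  expect_lt(abs(d), 3 * sqrt(2 * 0.1 * 0.9 / 50))
})

test_that("degenerate configuration gives pure diploid profiles", {
  truth <- simulate_cohort_truth(fix_genome(), fix_sets(), 3,
                                 rho_range = c(1, 1), ploidy_choices = 2,
                                 loss_rate_in_set = 0, loss_rate_background = 0,
                                 seed = 1)
  for (tp in truth) {
    expect_true(all(tp$segments$nA == 1 & tp$segments$nB == 1))
    expect_equal(tp$rho, 1)
    expect_equal(tp$psi_true, 2)
  }
})

test_that("psi_true is recomputable from segments", {
  for (tp in fix_truth())
    expect_equal(truth_psi(tp), tp$psi_true, tolerance = 1e-9)
})

test_that("segments tile each chromosome without overlap", {
  g <- fix_genome()
  for (tp in fix_truth()) {
    for (cn in g$chromosomes$chrom) {
      s <- tp$segments[tp$segments$chrom == cn, ]
      s <- s[order(s$start), ]
      expect_equal(s$start[1], 0)
      expect_equal(s$end[nrow(s)], g$chromosomes$length[g$chromosomes$chrom == cn])
      if (nrow(s) > 1) expect_equal(s$start[-1], s$end[-nrow(s)])
      expect_true(all(s$nA >= s$nB & s$nB >= 0))
    }
  }
})

test_that("rendered signals follow the mixture model in the noise-free limit", {
  g <- fix_genome()
  diploid <- manual_truth(
    do.call(rbind, lapply(g$chromosomes$chrom, function(cn)
      data.frame(chrom = cn, start = 0, end = 60e6, nA = 1, nB = 1))),
    rho = 1)
  tr <- render_snp_track(diploid, g, lrr_sd = 0, baf_sd = 0, seed = 1)
  expect_equal(max(abs(tr$lrr)), 0)
  expect_equal(unique(tr$baf[tr$is_het]), 0.5)
  expect_true(all(tr$baf[!tr$is_het] %in% c(0, 1)))

  # zero tumor content: flat BAF regardless of the aberrant genome
  lost <- fix_truth()[[1]]
  lost0 <- lost; lost0$rho <- 0
  tr0 <- render_snp_track(lost0, g, lrr_sd = 0, baf_sd = 0, seed = 2)
  expect_equal(unique(tr0$baf[tr0$is_het]), 0.5)
  expect_equal(max(abs(tr0$lrr)), 0)

  # rho = 0.5, copy-neutral LOH: het BAF 0.25 or 0.75 by phase
  cnloh <- manual_truth(
    rbind(data.frame(chrom = "chr1", start = 0, end = 30e6, nA = 2, nB = 0),
          data.frame(chrom = "chr1", start = 30e6, end = 60e6, nA = 1, nB = 1),
          data.frame(chrom = "chr2", start = 0, end = 60e6, nA = 1, nB = 1),
          data.frame(chrom = "chr3", start = 0, end = 60e6, nA = 1, nB = 1)),
    rho = 0.5)
  trc <- render_snp_track(cnloh, g, lrr_sd = 0, baf_sd = 0, seed = 3)
  in_loh <- trc$chrom == "chr1" & trc$pos < 30e6 & trc$is_het
  expect_true(all(trc$baf[in_loh] %in% c(0.25, 0.75)))
  expect_lt(max(abs(trc$lrr)), 1e-12)  # psi_mix = 2 everywhere
  expect_error(render_snp_track(cnloh, g, gamma = 0), "gamma")
})

test_that("rendering validates rho and is seed-deterministic", {
  tp <- fix_truth()[[1]]
  bad <- tp; bad$rho <- 1.2
  expect_error(render_snp_track(bad, fix_genome()), "rho")
  t1 <- render_snp_track(tp, fix_genome(), seed = 5)
  t2 <- render_snp_track(tp, fix_genome(), seed = 5)
  expect_identical(t1, t2)
  expect_true(all(t1$baf >= 0 & t1$baf <= 1))
})

test_that("expression coupling behaves at the slope extremes", {
  g <- fix_genome(); truth <- fix_truth()
  e0 <- simulate_expression(truth, g, coupled_fraction = 1, slope = 0,
                            noise_sd = 0.3, seed = 1)
  calls <- cohort_gene_calls(truth, g$genes)
  rel <- relative_cn_matrix(calls)
  rel <- rel[rownames(e0), colnames(e0)]
  rng <- apply(rel, 1, function(x) diff(range(x)))
  varying <- which(rng > 0.2)[1:25]
  rho0 <- vapply(varying, function(i)
    suppressWarnings(cor(rel[i, ], e0[i, ], method = "spearman")), 0)
  # unbiased about zero (individual correlations are noisy at 10 samples)
  expect_lt(abs(mean(rho0)), 0.25)

  e1 <- simulate_expression(truth, g, coupled_fraction = 1, slope = 1,
                            noise_sd = 0, seed = 1)
  rho1 <- vapply(varying, function(i)
    suppressWarnings(cor(rel[i, ], e1[i, ], method = "spearman")), 0)
  expect_true(all(rho1 > 0.999))
  expect_named(attr(e1, "coupled"))
})

test_that("tracks, segments, gene sets and expression round-trip through files", {
  dir <- withr::local_tempdir()
  g <- fix_genome(); tp <- fix_truth()[[1]]
  tr <- render_snp_track(tp, g, seed = 9)
  p <- write_snp_track(tr, file.path(dir, "t.tsv"))
  tr2 <- read_snp_track(p)
  expect_equal(as.data.frame(tr), as.data.frame(tr2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(tr2, "sample_id"), tp$sample_id)

  fit <- fit_ascn(tr)
  sp <- write_segments(list(fit$solution), file.path(dir, "s.tsv"))
  sols <- read_segments(sp)
  expect_length(sols, 1)
  expect_equal(sols[[1]]$rho, fit$rho, tolerance = 1e-6)
  expect_equal(sols[[1]]$psi, fit$psi, tolerance = 1e-6)
  orig <- fit$solution$segments
  orig <- orig[!is.na(orig$nA), c("chrom", "start", "end", "nA", "nB")]
  rownames(orig) <- NULL
  expect_equal(as.data.frame(sols[[1]]$segments[, colnames(orig)]),
               as.data.frame(orig), ignore_attr = TRUE)

  sets <- fix_sets()
  gp <- write_gmt(sets, file.path(dir, "sets.gmt"))
  sets2 <- read_gmt(gp)
  expect_identical(sets2$stop_like, sets$sets$stop_like)

  bp <- write_bed_genes(g$genes, file.path(dir, "genes.bed"))
  genes2 <- read_bed_genes(bp)
  expect_equal(genes2, g$genes[, colnames(genes2)])

  ex <- simulate_expression(fix_truth(), g, seed = 1)
  ep <- write_expression(ex, file.path(dir, "expr.tsv"))
  ex2 <- read_expression(ep)
  expect_equal(unname(ex2), unname(ex), tolerance = 1e-10, ignore_attr = TRUE)
})
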
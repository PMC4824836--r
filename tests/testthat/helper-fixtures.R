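# Shared fixtures, built once per test run. Sizes are kept small: three
# 60 Mb chromosomes at 20 kb SNP spacing are enough for megabase-scale loss
# segments while keeping segmentation and grid fits fast.

fix_genome <- function() {
  if (is.null(.fix$genome))
    .fix$genome <- make_genome(1, c(60e6, 60e6, 60e6), 2e4, 300)
  .fix$genome
}

fix_sets <- function() {
  if (is.null(.fix$sets))
    .fix$sets <- make_gene_sets(fix_genome(), 60, 20, seed = 2)
  .fix$sets
}

fix_truth <- function() {
  if (is.null(.fix$truth))
    .fix$truth <- simulate_cohort_truth(fix_genome(), fix_sets(), 10, seed = 3)
  .fix$truth
}

.fix <- new.env(parent = emptyenv())

# a single-sample truth profile with explicit segments, for worked examples
manual_truth <- function(segments, rho, sample_id = "M1") {
  w <- segments$end - segments$start
  structure(list(sample_id = sample_id, rho = rho, segments = segments,
                 psi_true = sum(w * (segments$nA + segments$nB)) / sum(w)),
            class = "truth_profile")
}

# truth state lookup at a position
truth_state_at <- function(truth, chrom, pos) {
  s <- truth$segments[truth$segments$chrom == chrom, ]
  s <- s[order(s$start), ]
  i <- findInterval(pos, s$start)
  c(nA = s$nA[i], nB = s$nB[i])
}

# manual ascn_solution for select_solution / calls tests
manual_solution <- function(segments, rho, goodness, sample_id = "S1") {
  segments$n_informative <- segments$n_informative %||%
    as.integer((segments$end - segments$start) / 1e5)
  w <- segments$n_informative
  structure(list(
    rho = rho,
    psi = sum(w * (segments$nA + segments$nB)) / sum(w),
    segments = segments, goodness = goodness,
    homdel_mb = sum((segments$end - segments$start)[segments$nA == 0 &
                                                      segments$nB == 0]) / 1e6,
    warning_homdel = FALSE, sample_id = sample_id),
    class = "ascn_solution")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a small long-format calls table by hand: `lost` is a list mapping
# gene -> samples in which that gene is lost.
mk_calls <- function(genes, samples, lost = list(), unassessable = list()) {
  df <- expand.grid(gene_id = genes, sample = samples,
                    stringsAsFactors = FALSE)
  df$total_cn <- 2; df$minor_cn <- 1
  df$relative_cn <- 1; df$is_loss <- FALSE; df$is_loh <- FALSE
  for (g in names(lost)) {
    i <- df$gene_id == g & df$sample %in% lost[[g]]
    df$is_loss[i] <- TRUE; df$total_cn[i] <- 1; df$relative_cn[i] <- 0.5
  }
  for (g in names(unassessable)) {
    i <- df$gene_id == g & df$sample %in% unassessable[[g]]
    df$is_loss[i] <- NA; df$total_cn[i] <- NA; df$relative_cn[i] <- NA
  }
  class(df) <- c("gene_calls", "data.frame")
  df
}


# Independent oracle: walk the full ranking step by step, tracking the
# maximum absolute deviation of the running sum (positive extreme wins ties).
es_oracle <- function(ids, set) {
  k <- sum(ids %in% set); N <- length(ids)
  run <- 0; best <- 0
  for (g in ids) {
    run <- run + if (g %in% set) 1 / k else -1 / (N - k)
    if (abs(run) > abs(best) + 1e-12 ||
        (abs(run) >= abs(best) - 1e-12 && run > best)) best <- run
  }
  best
}

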
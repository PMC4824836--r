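# Rank-based gene-set enrichment against a copy-number ranking: the classic
# (unweighted) running-sum statistic with a permutation NES and a
# random-gene-set empirical p value.

#' Per-gene mean relative copy number across a cohort
#'
#' Relative copy number is the gene's total copy number divided by its
#' sample's average ploidy; the mean is taken over the samples in which the
#' gene is assessable. Genes assessable in no sample are dropped.
#'
#' @param gene_calls a `gene_calls` table from [cohort_gene_calls()].
#' @return data.frame: gene_id, mean_relative_cn, n_samples.
#' @export
mean_relative_cn <- function(gene_calls) {
  m <- tapply(gene_calls$relative_cn, gene_calls$gene_id,
              function(x) mean(x, na.rm = TRUE))
  n <- tapply(gene_calls$relative_cn, gene_calls$gene_id,
              function(x) sum(!is.na(x)))
  out <- data.frame(gene_id = names(m), mean_relative_cn = as.numeric(m),
                    n_samples = as.integer(n), stringsAsFactors = FALSE)
  out <- out[out$n_samples > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene x sample matrix of relative copy numbers from long-format calls
#' @param gene_calls a `gene_calls` table.
#' @return numeric matrix (genes x samples) with `NA` where unassessable.
#' @export
relative_cn_matrix <- function(gene_calls) {
  genes <- unique(gene_calls$gene_id)
  samples <- unique(gene_calls$sample)
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(gene_calls$gene_id, genes), match(gene_calls$sample, samples))] <-
    gene_calls$relative_cn
  m
}

#' Spearman correlation between relative copy number and expression
#'
#' Per gene, the Spearman correlation (and its two-sided p value) between the
#' per-sample relative copy numbers and expression levels. Genes with fewer
#' than `min_pairs` complete pairs, or with a constant vector on either side,
#' get `NA` and thus fail the positive-correlation filter downstream.
#'
#' @param rel_cn gene x sample matrix of relative copy numbers.
#' @param expression gene x sample expression matrix.
#' @param min_pairs minimum complete pairs per gene.
#' @return data.frame: gene_id, rho, p, n.
#' @export
cn_expression_correlation <- function(rel_cn, expression, min_pairs = 8) {
  common_s <- intersect(colnames(rel_cn), colnames(expression))
  missing_s <- setdiff(colnames(rel_cn), colnames(expression))
  if (length(missing_s))
    stopf("samples present in copy-number but not expression data: %s",
          paste(utils::head(missing_s, 5), collapse = ", "))
  if (length(common_s) < min_pairs) stopf("fewer than %d shared samples", min_pairs)
  genes <- intersect(rownames(rel_cn), rownames(expression))
  res <- data.frame(gene_id = genes, rho = NA_real_, p = NA_real_, n = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    x <- rel_cn[genes[i], common_s]
    y <- expression[genes[i], common_s]
    ok <- !is.na(x) & !is.na(y)
    res$n[i] <- sum(ok)
    if (sum(ok) < min_pairs) next
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                           exact = FALSE))
    res$rho[i] <- unname(ct$estimate)
    res$p[i] <- ct$p.value
  }
  rownames(res) <- NULL
  res
}

#' Build the correlation-filtered copy-number ranking
#'
#' Keeps genes with a significant positive copy-number/expression correlation
#' (`rho > 0` and `p < filter_alpha`), then orders them by increasing mean
#' relative copy number, breaking ties by decreasing correlation coefficient,
#' and residual ties by a seeded random ordering.
#'
#' @param mean_rel output of [mean_relative_cn()].
#' @param correlations output of [cn_expression_correlation()].
#' @param filter_alpha two-sided Spearman p threshold for the filter.
#' @param seed seed for the residual-tie ordering.
#' @return `ranked_gene_list` data.frame: gene_id, mean_relative_cn,
#'   spearman_rho, spearman_p, in ranking order (most-lost genes first).
#' @export
build_ranked_list <- function(mean_rel, correlations, filter_alpha = 0.05,
                              seed = 1) {
  df <- merge(mean_rel, correlations, by = "gene_id")
  df <- df[!is.na(df$rho) & !is.na(df$p) & df$rho > 0 & df$p < filter_alpha, ,
           drop = FALSE]
  if (!nrow(df)) stopf("no genes pass the positive-correlation filter")
  u <- with_seed(seed, sample.int(nrow(df)))
  df <- df[order(df$mean_relative_cn, -df$rho, u), , drop = FALSE]
  out <- data.frame(gene_id = df$gene_id,
                    mean_relative_cn = df$mean_relative_cn,
                    spearman_rho = df$rho, spearman_p = df$p,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "ordering_seed") <- seed
  class(out) <- c("ranked_gene_list", "data.frame")
  out
}

ranked_ids <- function(ranked) {
  if (is.data.frame(ranked)) ranked$gene_id else as.character(ranked)
}

# Signed extreme of the unweighted running sum, from sorted hit positions.
# Maximum-absolute-deviation convention; on an exact tie the positive extreme
# wins.
es_from_positions <- function(p_sorted, N, k) {
  i <- seq_len(k)
  after <- i / k - (p_sorted - i) / (N - k)
  before <- after - 1 / k
  mx <- max(after, 0)
  mn <- min(before, 0)
  if (mx >= -mn - 1e-12) mx else mn
}

#' Classic (unweighted) enrichment score
#'
#' Walks the ranking: members of the set add `1/n_hit`, non-members subtract
#' `1/(N - n_hit)`; the enrichment score is the running-sum value of maximum
#' absolute deviation from zero (signed). Positive scores mean enrichment at
#' the top of the ranking.
#'
#' @param ranked a `ranked_gene_list` or character vector of gene ids.
#' @param gene_set character vector of member gene ids.
#' @return list: `es`, `running_sum` (length N), `hit_positions`.
#' @export
enrichment_score_classic <- function(ranked, gene_set) {
  ids <- ranked_ids(ranked)
  N <- length(ids)
  hit <- ids %in% gene_set
  k <- sum(hit)
  if (k == 0 || k == N)
    stopf("gene set intersects the ranking in %d of %d genes: enrichment undefined", k, N)
  inc <- ifelse(hit, 1 / k, -1 / (N - k))
  cs <- cumsum(inc)
  mx <- max(cs); mn <- min(cs)
  es <- if (max(mx, 0) >= -min(mn, 0) - 1e-12) max(mx, 0) else mn
  list(es = es, running_sum = cs, hit_positions = which(hit))
}

#' Permutation-normalized enrichment score
#'
#' The null distribution is the classic enrichment score of `n_perm` random
#' gene sets of the same size drawn from the ranking. The NES is the observed
#' score divided by the mean absolute null score of matching sign, and
#' `perm_p` is the fraction of matching-sign null scores at least as extreme.
#'
#' @param ranked a `ranked_gene_list` or character vector of gene ids.
#' @param gene_set character vector of member gene ids.
#' @param n_perm number of random sets (values below 100 warn).
#' @param seed integer seed.
#' @return list: `es`, `nes`, `perm_p`, `n_perm`, `running_sum`.
#' @export
permutation_nes <- function(ranked, gene_set, n_perm = 1000, seed = 1) {
  if (n_perm < 100)
    warning("n_perm < 100 gives a coarse permutation null", call. = FALSE)
  ids <- ranked_ids(ranked)
  N <- length(ids)
  obs <- enrichment_score_classic(ids, gene_set)
  k <- length(obs$hit_positions)
  null_es <- with_seed(seed, vapply(seq_len(n_perm), function(j)
    es_from_positions(sort.int(sample.int(N, k)), N, k), 0))
  s <- sign(obs$es)
  if (s == 0) {
    return(list(es = 0, nes = 0, perm_p = 1, n_perm = n_perm,
                running_sum = obs$running_sum))
  }
  same <- sign(null_es) == s
  denom <- if (any(same)) mean(abs(null_es[same])) else mean(abs(null_es))
  nes <- obs$es / denom
  perm_p <- if (any(same)) mean(abs(null_es[same]) >= abs(obs$es)) else 0
  list(es = obs$es, nes = nes, perm_p = perm_p, n_perm = n_perm,
       running_sum = obs$running_sum)
}

#' Random-gene-set empirical p value
#'
#' Draws `n_resample` uniform same-size gene sets from the ranking universe,
#' computes each one's NES the same way as the observed set's, and returns
#' the fraction whose NES strictly exceeds the observed NES (`k/n`;
#' `conservative = TRUE` gives `(k+1)/(n+1)`).
#'
#' @param ranked a `ranked_gene_list` or character vector of gene ids.
#' @param gene_set character vector of member gene ids.
#' @param n_resample number of random sets.
#' @param n_perm permutations per NES.
#' @param seed integer seed.
#' @param conservative use the `(k+1)/(n+1)` estimator.
#' @return `enrichment_result`: list with `es`, `nes`, `perm_p`,
#'   `empirical_p`, `n_perm`, `n_resample`, `running_sum`.
#' @export
random_set_empirical_p <- function(ranked, gene_set, n_resample = 1000,
                                   n_perm = 1000, seed = 1,
                                   conservative = FALSE) {
  ids <- ranked_ids(ranked)
  set_in <- intersect(gene_set, ids)
  if (length(set_in) > length(ids)) stopf("gene set larger than the ranking")
  obs <- permutation_nes(ids, set_in, n_perm = n_perm, seed = seed)
  k_set <- length(set_in)
  nes_rand <- with_seed(seed + 1, vapply(seq_len(n_resample), function(j) {
    rs <- sample(ids, k_set)
    suppressWarnings(permutation_nes(ids, rs, n_perm = n_perm,
                                     seed = sample.int(.Machine$integer.max, 1))$nes)
  }, 0))
  k <- sum(nes_rand > obs$nes)
  empirical_p <- if (conservative) (k + 1) / (n_resample + 1) else k / n_resample
  structure(list(es = obs$es, nes = obs$nes, perm_p = obs$perm_p,
                 empirical_p = empirical_p, n_perm = n_perm,
                 n_resample = n_resample, running_sum = obs$running_sum),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: es=%.3f nes=%.3f perm_p=%.4g empirical_p=%.4g (n_perm=%d, n_resample=%d)\n",
              x$es, x$nes, x$perm_p, x$empirical_p, x$n_perm, x$n_resample))
  invisible(x)
}

#' Maximum p value over residual-tie orderings
#'
#' Rebuilds the ranking under several residual-tie seeds, reruns the
#' enrichment analysis for each, and reports the maximum (most conservative)
#' p values with their spread.
#'
#' @param mean_rel,correlations inputs to [build_ranked_list()].
#' @param gene_set character vector of member gene ids.
#' @param seeds seeds for the residual-tie orderings (at least 2).
#' @param filter_alpha correlation-filter alpha.
#' @param n_resample,n_perm resampling controls.
#' @return list: `per_seed` data.frame (seed, es, nes, perm_p, empirical_p),
#'   `max_perm_p`, `max_empirical_p`.
#' @export
max_p_over_orderings <- function(mean_rel, correlations, gene_set,
                                 seeds = 1:5, filter_alpha = 0.05,
                                 n_resample = 1000, n_perm = 1000) {
  if (length(seeds) < 2) stopf("need at least 2 ordering seeds")
  rows <- lapply(seeds, function(s) {
    ranked <- build_ranked_list(mean_rel, correlations,
                                filter_alpha = filter_alpha, seed = s)
    res <- random_set_empirical_p(ranked, gene_set, n_resample = n_resample,
                                  n_perm = n_perm, seed = s)
    data.frame(seed = s, es = res$es, nes = res$nes, perm_p = res$perm_p,
               empirical_p = res$empirical_p)
  })
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       max_perm_p = max(per_seed$perm_p),
       max_empirical_p = max(per_seed$empirical_p))
}
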
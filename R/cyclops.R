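# CYCLOPS-gene accounting: per-tumor deleted counts, deletion-associated
# downregulation, qualifying-gene tumor coverage and cross-cohort
# deletion-frequency comparison.

#' Per-tumor counts of lost genes from a set
#'
#' @param gene_calls a `gene_calls` table.
#' @param set character vector of gene ids.
#' @return list: `counts` data.frame (sample, n_lost, n_unassessable) and
#'   summary statistics `mean`, `median`, `range` over tumors.
#' @export
per_tumor_set_loss_counts <- function(gene_calls, set) {
  gc <- gene_calls[gene_calls$gene_id %in% set, , drop = FALSE]
  if (!nrow(gc)) stopf("gene set is disjoint from the call universe")
  samples <- unique(gene_calls$sample)
  n_lost <- vapply(samples, function(s)
    sum(gc$is_loss[gc$sample == s], na.rm = TRUE), 0L)
  n_un <- vapply(samples, function(s)
    sum(is.na(gc$is_loss[gc$sample == s])), 0L)
  counts <- data.frame(sample = samples, n_lost = n_lost,
                       n_unassessable = n_un, stringsAsFactors = FALSE,
                       row.names = NULL)
  list(counts = counts, mean = mean(n_lost), median = stats::median(n_lost),
       range = range(n_lost))
}

#' Test whether deletion of a gene is associated with lower expression
#'
#' One-sided Wilcoxon rank-sum comparison of expression in tumors where the
#' gene is lost versus intact (`deleted < intact`). Requires at least
#' `min_group` tumors on each side; otherwise the verdict is "untestable"
#' (`testable = FALSE`), never a silent negative.
#'
#' @param gene a gene id.
#' @param gene_calls a `gene_calls` table.
#' @param expression gene x sample expression matrix.
#' @param alpha significance level for the downregulation verdict.
#' @param min_group minimum group size on each side.
#' @return list: `testable`, `downregulated`, `statistic`, `p`,
#'   `n_deleted`, `n_intact`.
#' @export
deletion_downregulation_test <- function(gene, gene_calls, expression,
                                         alpha = 0.05, min_group = 3) {
  gc <- gene_calls[gene_calls$gene_id == gene & !is.na(gene_calls$is_loss), ,
                   drop = FALSE]
  if (!nrow(gc) || !(gene %in% rownames(expression)))
    return(list(testable = FALSE, downregulated = NA, statistic = NA_real_,
                p = NA_real_, n_deleted = 0L, n_intact = 0L))
  ex <- expression[gene, ]
  gc <- gc[gc$sample %in% names(ex), , drop = FALSE]
  del <- ex[gc$sample[gc$is_loss]]
  intact <- ex[gc$sample[!gc$is_loss]]
  if (length(del) < min_group || length(intact) < min_group)
    return(list(testable = FALSE, downregulated = NA, statistic = NA_real_,
                p = NA_real_, n_deleted = length(del), n_intact = length(intact)))
  wt <- suppressWarnings(stats::wilcox.test(del, intact, alternative = "less",
                                            exact = FALSE))
  list(testable = TRUE, downregulated = wt$p.value < alpha,
       statistic = unname(wt$statistic), p = wt$p.value,
       n_deleted = length(del), n_intact = length(intact))
}

#' Qualifying genes: deleted in at least one tumor and downregulated
#'
#' @param cyclops_set character vector of candidate gene ids.
#' @param gene_calls a `gene_calls` table.
#' @param expression gene x sample expression matrix.
#' @param alpha,min_group see [deletion_downregulation_test()].
#' @return list: `genes` (the qualifying subset), `percentage` (rounded to
#'   the nearest integer, of the candidate set) and the per-gene test table.
#' @export
qualifying_genes <- function(cyclops_set, gene_calls, expression,
                             alpha = 0.05, min_group = 3) {
  rows <- lapply(cyclops_set, function(g) {
    gc <- gene_calls[gene_calls$gene_id == g, , drop = FALSE]
    n_del <- sum(gc$is_loss, na.rm = TRUE)
    tst <- deletion_downregulation_test(g, gene_calls, expression,
                                        alpha = alpha, min_group = min_group)
    data.frame(gene_id = g, n_tumors_deleted = n_del,
               deletion_frequency = if (nrow(gc)) n_del / sum(!is.na(gc$is_loss)) else NA_real_,
               testable = tst$testable,
               downregulated = isTRUE(tst$downregulated),
               statistic = tst$statistic, p = tst$p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  qual <- tab$gene_id[tab$n_tumors_deleted >= 1 & tab$downregulated]
  list(genes = qual,
       percentage = round(100 * length(qual) / length(cyclops_set)),
       table = tab)
}

#' Tumors with at least one qualifying gene lost
#'
#' @param gene_calls a `gene_calls` table.
#' @param qualifying nonempty character vector of qualifying gene ids.
#' @return list: `count`, `n_tumors`, `percentage` (one decimal).
#' @export
tumors_with_any <- function(gene_calls, qualifying) {
  if (!length(qualifying)) stopf("`qualifying` must be nonempty")
  gc <- gene_calls[gene_calls$gene_id %in% qualifying, , drop = FALSE]
  samples <- unique(gene_calls$sample)
  has <- vapply(samples, function(s)
    any(gc$is_loss[gc$sample == s], na.rm = TRUE), NA)
  count <- sum(has)
  list(count = count, n_tumors = length(samples),
       percentage = round(100 * count / length(samples), 1))
}

#' Fisher's exact test of deletion frequencies between two cohorts
#'
#' Exact two-sided test on the 2x2 table `[[k1, n1-k1], [k2, n2-k2]]`,
#' computed by summation of all conditional (hypergeometric) table
#' probabilities not exceeding the observed table's probability.
#'
#' @param k1,n1 deletions and cohort size in cohort 1.
#' @param k2,n2 deletions and cohort size in cohort 2.
#' @return list: `odds_ratio` (sample odds ratio), `p` (two-sided).
#' @export
deletion_frequency_fisher <- function(k1, n1, k2, n2) {
  if (k1 > n1 || k2 > n2 || any(c(k1, n1, k2, n2) < 0))
    stopf("need 0 <= k <= n for both cohorts")
  m <- k1 + k2
  xs <- max(0, m - n2):min(n1, m)
  probs <- stats::dhyper(xs, m, n1 + n2 - m, n1)
  p_obs <- stats::dhyper(k1, m, n1 + n2 - m, n1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- (k1 * (n2 - k2)) / ((n1 - k1) * k2)
  list(odds_ratio = or, p = min(1, p))
}

#' Full CYCLOPS-gene report for a cohort
#'
#' Per-gene deletion counts and deletion-associated downregulation tests,
#' per-tumor deleted and qualifying-deleted counts, and cohort-level
#' summaries including the percentage of tumors carrying at least one
#' qualifying gene loss.
#'
#' @param gene_calls a `gene_calls` table.
#' @param expression gene x sample expression matrix.
#' @param cyclops_set character vector of candidate gene ids.
#' @param alpha,min_group see [deletion_downregulation_test()].
#' @return `cyclops_report`: list with `genes` (per-gene table),
#'   `qualifying`, `pct_qualifying`, `per_tumor` (sample, n_cyclops_deleted,
#'   n_qualifying_deleted), `summary` (mean/median/range of counts,
#'   `n_tumors_with_any_qualifying`, `pct_tumors_with_any_qualifying`).
#' @export
cyclops_report <- function(gene_calls, expression, cyclops_set,
                           alpha = 0.05, min_group = 3) {
  qg <- qualifying_genes(cyclops_set, gene_calls, expression,
                         alpha = alpha, min_group = min_group)
  counts_all <- per_tumor_set_loss_counts(gene_calls, cyclops_set)
  per_tumor <- counts_all$counts
  names(per_tumor)[names(per_tumor) == "n_lost"] <- "n_cyclops_deleted"
  if (length(qg$genes)) {
    counts_q <- per_tumor_set_loss_counts(gene_calls, qg$genes)
    per_tumor$n_qualifying_deleted <-
      counts_q$counts$n_lost[match(per_tumor$sample, counts_q$counts$sample)]
    twa <- tumors_with_any(gene_calls, qg$genes)
  } else {
    per_tumor$n_qualifying_deleted <- 0L
    twa <- list(count = 0L, n_tumors = length(unique(gene_calls$sample)),
                percentage = 0)
  }
  structure(list(
    genes = qg$table, qualifying = qg$genes, pct_qualifying = qg$percentage,
    per_tumor = per_tumor,
    summary = list(mean_deleted = counts_all$mean,
                   median_deleted = counts_all$median,
                   range_deleted = counts_all$range,
                   n_tumors_with_any_qualifying = twa$count,
                   pct_tumors_with_any_qualifying = twa$percentage)
  ), class = "cyclops_report")
}

#' @export
print.cyclops_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("cyclops_report: %d candidates, %d qualifying (%d%%)\n",
              nrow(x$genes), length(x$qualifying), x$pct_qualifying))
  cat(sprintf("  deleted per tumor: mean %.2f, median %g, range %g-%g\n",
              s$mean_deleted, s$median_deleted, s$range_deleted[1], s$range_deleted[2]))
  cat(sprintf("  tumors with >=1 qualifying loss: %d (%.1f%%)\n",
              s$n_tumors_with_any_qualifying, s$pct_tumors_with_any_qualifying))
  invisible(x)
}
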
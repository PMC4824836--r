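# Grid estimation of aberrant-cell fraction and ploidy, and the ascn_fit
# model object.

# Invert the mixture model for one (rho, psi_t) pair: continuous allele copy
# numbers per segment from segment-mean LRR r and mirrored BAF b.
invert_mixture <- function(r, b, rho, psi_t, gamma) {
  psi_mix <- 2 * (1 - rho) + rho * psi_t
  mix <- psi_mix * 2^(r / gamma)
  ntot <- (mix - 2 * (1 - rho)) / rho
  nmaj <- (b * mix - (1 - rho)) / rho
  list(nmaj = nmaj, nmin = ntot - nmaj)
}

#' Fit aberrant-cell fraction and ploidy over a grid
#'
#' For every grid point (rho, psi) the generative mixture model is inverted to
#' continuous allele-specific copy numbers per segment; the goodness of fit is
#' the informative-SNP-weighted mean squared distance of the continuous values
#' to the nearest nonnegative integers. Candidate solutions are the local
#' minima of the goodness surface (at or below their 8 grid neighbors;
#' plateau ties broken by lower ploidy then higher aberrant-cell fraction),
#' returned sorted by their observation-space residual plus the
#' ploidy-parsimony penalty; each candidate also reports its
#' copy-number-space goodness.
#'
#' @param seg a `segmented_track`.
#' @param rho_grid,psi_grid grids for the aberrant-cell fraction and the
#'   tumor average ploidy.
#' @param gamma platform compression factor used by the generative model.
#' @param min_snps segments with fewer informative SNPs are ignored in the fit.
#' @param max_candidates cap on the number of candidates returned.
#' @param psi_penalty ploidy-parsimony weight: candidates are ordered by
#'   their observation-space residual plus `psi_penalty * psi`. The mixture
#'   model admits exact aliases at higher ploidy (one extra copy on every
#'   allele), so among near-equal fits the lowest-ploidy solution is
#'   preferred.
#' @return list of `ascn_solution` candidates (possibly empty, with
#'   `attr(, "diagnostic")` set when the genome is all-balanced and the fit is
#'   unidentifiable). Each solution carries rho, psi (recomputed from the
#'   rounded integers), integer segments, goodness, per-segment reliability
#'   and the total megabases of homozygous deletion. The goodness surface is
#'   attached as `attr(, "grid")`.
#' @export
fit_purity_ploidy <- function(seg, rho_grid = seq(0.10, 1.00, by = 0.01),
                              psi_grid = seq(1.0, 5.5, by = 0.05),
                              gamma = 0.55, min_snps = 3,
                              max_candidates = 10, psi_penalty = 2e-4) {
  use <- !is.na(seg$mean_lrr) & !is.na(seg$mean_mbaf) &
    seg$n_informative >= min_snps & drop_sex_chroms(seg$chrom)
  fs <- seg[use, , drop = FALSE]
  if (!nrow(fs)) stopf("no informative segments to fit")
  r <- fs$mean_lrr; b <- pmin(1, pmax(0.5, fs$mean_mbaf))
  w <- fs$n_informative

  wsd <- function(x) sqrt(sum(w * (x - sum(w * x) / sum(w))^2) / sum(w))
  if (all(abs(b - 0.5) < 1e-3) && wsd(r) < 1e-3) {
    out <- list()
    attr(out, "diagnostic") <-
      "all segments balanced with flat LRR: aberrant-cell fraction unidentifiable"
    return(out)
  }

  R <- length(rho_grid); P <- length(psi_grid)
  G <- matrix(NA_real_, R, P)   # copy-number-space goodness
  D <- matrix(NA_real_, R, P)   # observation-space distance
  pow <- 2^(r / gamma)
  rm_ <- matrix(r, 1, length(r))
  for (ri in seq_len(R)) {
    rho <- rho_grid[ri]
    psi_mix <- 2 * (1 - rho) + rho * psi_grid
    mix <- outer(psi_mix, pow)                       # P x S
    bm <- matrix(b, P, length(b), byrow = TRUE)
    nmaj <- (bm * mix - (1 - rho)) / rho
    nmin <- (mix - 2 * (1 - rho)) / rho - nmaj
    iA <- pmax(round(nmaj), 0)
    iB <- pmax(round(nmin), 0)
    G[ri, ] <- as.numeric(((nmaj - iA)^2 + (nmin - iB)^2) %*% w) / sum(w)
    # predict the segment means back from the rounded integers; this
    # distance is invariant along the exact alias ladder and free of the
    # low-ploidy noise-shrinkage bias of the copy-number-space goodness
    mix_hat <- 2 * (1 - rho) + rho * (iA + iB)
    r_hat <- gamma * log2(pmax(mix_hat, 0.05) / psi_mix)
    b_hat <- ifelse(mix_hat > 0, (1 - rho + rho * pmax(iA, iB)) / mix_hat, 0.5)
    D[ri, ] <- as.numeric(((r_hat - rm_[rep(1, P), ])^2 + (b_hat - bm)^2) %*% w) /
      sum(w)
  }

  # local minima of the observation-space distance surface
  pad <- matrix(Inf, R + 2, P + 2)
  pad[2:(R + 1), 2:(P + 1)] <- D
  nb <- array(Inf, c(R, P, 8))
  k <- 0
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    k <- k + 1
    nb[, , k] <- pad[(2:(R + 1)) + di, (2:(P + 1)) + dj]
  }
  nbmin <- apply(nb, c(1, 2), min)
  cand <- which(D <= nbmin + 1e-12, arr.ind = TRUE)
  if (!nrow(cand)) cand <- which(D == min(D), arr.ind = TRUE)
  ord <- order(D[cand], psi_grid[cand[, 2]], -rho_grid[cand[, 1]])
  cand <- cand[ord, , drop = FALSE]
  # prune near-duplicates: drop a candidate grid-adjacent to a better one kept
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    adj <- keep & abs(cand[, 1] - cand[i, 1]) <= 1 & abs(cand[, 2] - cand[i, 2]) <= 1
    keep[i] <- !any(adj)
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[seq_len(min(nrow(cand), 3 * max_candidates)), , drop = FALSE]

  sols <- lapply(seq_len(nrow(cand)), function(i) {
    rho <- rho_grid[cand[i, 1]]; psi_t <- psi_grid[cand[i, 2]]
    inv <- invert_mixture(r, b, rho, psi_t, gamma)
    iA <- pmax(round(inv$nmaj), 0); iB <- pmax(round(inv$nmin), 0)
    swap <- iA < iB
    tmp <- iA[swap]; iA[swap] <- iB[swap]; iB[swap] <- tmp
    resid <- sqrt((inv$nmaj - iA)^2 + (inv$nmin - iB)^2)
    obs_dist <- D[cand[i, 1], cand[i, 2]]
    segs <- seg[, c("chrom", "start", "end", "n_informative")]
    segs$nA <- NA_real_; segs$nB <- NA_real_
    segs$nA_cont <- NA_real_; segs$nB_cont <- NA_real_
    segs$reliability <- NA_real_
    segs$nA[use] <- iA; segs$nB[use] <- iB
    segs$nA_cont[use] <- inv$nmaj; segs$nB_cont[use] <- inv$nmin
    segs$reliability[use] <- 1 - pmin(1, resid / 0.5)
    psi_hat <- sum(w * (iA + iB)) / sum(w)
    homdel_mb <- sum((segs$end - segs$start)[use][iA == 0 & iB == 0]) / 1e6
    structure(list(rho = rho, psi = psi_hat, grid_psi = psi_t,
                   segments = segs, goodness = G[cand[i, 1], cand[i, 2]],
                   obs_dist = obs_dist,
                   homdel_mb = homdel_mb, warning_homdel = FALSE,
                   sample_id = attr(seg, "sample_id")),
              class = "ascn_solution")
  })
  # final order: observation-space distance with a ploidy-parsimony penalty
  # that resolves the exact alias ladder toward the lowest-ploidy member
  score <- vapply(sols, function(s) s$obs_dist + psi_penalty * s$psi, 0)
  psis <- vapply(sols, `[[`, 0, "psi")
  rhos <- vapply(sols, `[[`, 0, "rho")
  sols <- sols[order(score, psis, -rhos)]
  sols <- sols[seq_len(min(length(sols), max_candidates))]
  attr(sols, "grid") <- list(rho = rho_grid, psi = psi_grid, goodness = G)
  sols
}

#' Select the reported solution, adjusting for large homozygous deletions
#'
#' Returns the best-goodness candidate unless it carries more than
#' `max_homdel_mb` megabases of homozygous deletion (biologically implausible
#' and symptomatic of an underestimated ploidy), in which case the next-best
#' candidate with strictly higher average ploidy and an acceptable
#' homozygous-deletion load is chosen. If none exists the best candidate is
#' returned with `warning_homdel = TRUE`.
#'
#' @param candidates list of `ascn_solution`s sorted by goodness.
#' @param max_homdel_mb homozygous-deletion tolerance in Mb.
#' @return one `ascn_solution`.
#' @export
select_solution <- function(candidates, max_homdel_mb = 10) {
  if (!length(candidates))
    stopf("no candidate solutions: sample unassessable%s",
          if (!is.null(attr(candidates, "diagnostic")))
            paste0(" (", attr(candidates, "diagnostic"), ")") else "")
  best <- candidates[[1]]
  if (best$homdel_mb <= max_homdel_mb) return(best)
  for (cand in candidates[-1]) {
    if (cand$psi > best$psi + 1e-9 && cand$homdel_mb <= max_homdel_mb) {
      cand$adjusted_homdel <- TRUE
      return(cand)
    }
  }
  warning("all candidate solutions exceed the homozygous-deletion tolerance; ",
          "returning the best-goodness solution flagged", call. = FALSE)
  best$warning_homdel <- TRUE
  best
}

#' Average ploidy of a fitted solution
#'
#' The informative-SNP-count-weighted mean of the segment total copy numbers,
#' i.e. the average copy number over informative SNPs across the genome.
#'
#' @param solution an `ascn_solution`.
#' @return numeric average ploidy.
#' @export
average_ploidy <- function(solution) {
  s <- solution$segments
  use <- !is.na(s$nA) & s$n_informative > 0
  if (!any(use)) stopf("solution has no informative segments")
  w <- s$n_informative[use]
  sum(w * (s$nA + s$nB)[use]) / sum(w)
}

#' Fit allele-specific copy numbers to a SNP track
#'
#' The package's central model fit: quality control, joint segmentation of the
#' (LRR, mirrored BAF) signal, grid search for aberrant-cell fraction and
#' average ploidy, and homozygous-deletion-aware solution selection, returning
#' a classed model object.
#'
#' @param track an `snp_track` (chrom, pos, lrr, baf, is_het).
#' @param gamma platform compression factor of the array.
#' @param qc thresholds from [qc_thresholds()], or `NULL` to skip QC.
#' @param penalty,min_snps segmentation controls, see [segment_track()].
#' @param rho_grid,psi_grid search grids, see [fit_purity_ploidy()].
#' @param max_homdel_mb see [select_solution()].
#' @return An object of class `ascn_fit` with components `status`
#'   (`"ok"`, `"qc_failed"` or `"unidentifiable"`), `qc`, `segmented`,
#'   `candidates`, `solution`, `rho`, `psi`. Methods: `print`, `summary`,
#'   `coef` (rho and psi), `residuals` (continuous minus integer copy numbers
#'   per segment), `plot` (goodness surface and copy-number profile).
#' @export
fit_ascn <- function(track, gamma = 0.55, qc = qc_thresholds(),
                     penalty = 4, min_snps = 5,
                     rho_grid = seq(0.10, 1.00, by = 0.01),
                     psi_grid = seq(1.0, 5.5, by = 0.05),
                     max_homdel_mb = 10) {
  track <- track[drop_sex_chroms(track$chrom), , drop = FALSE]
  obj <- list(sample_id = attr(track, "sample_id") %||% "sample",
              n_snps = nrow(track), gamma = gamma, call = match.call())
  if (!is.null(qc)) {
    flags <- qc_sample(track, qc)
    obj$qc <- flags
    if (!flags$pass) {
      obj$status <- "qc_failed"
      class(obj) <- "ascn_fit"
      return(obj)
    }
  }
  seg <- segment_track(track, penalty = penalty, min_snps = min_snps)
  obj$segmented <- seg
  cands <- fit_purity_ploidy(seg, rho_grid = rho_grid, psi_grid = psi_grid,
                             gamma = gamma)
  obj$candidates <- cands
  obj$grid <- attr(cands, "grid")
  if (!length(cands)) {
    obj$status <- "unidentifiable"
    obj$diagnostic <- attr(cands, "diagnostic")
    class(obj) <- "ascn_fit"
    return(obj)
  }
  sol <- select_solution(cands, max_homdel_mb = max_homdel_mb)
  obj$solution <- sol
  obj$rho <- sol$rho
  obj$psi <- sol$psi
  obj$status <- "ok"
  class(obj) <- "ascn_fit"
  obj
}

#' @export
print.ascn_fit <- function(x, ...) {
  cat(sprintf("ascn_fit '%s' [%s]", x$sample_id, x$status))
  if (x$status == "ok")
    cat(sprintf(": rho=%.2f psi=%.3f goodness=%.4g homdel=%.1f Mb",
                x$rho, x$psi, x$solution$goodness, x$solution$homdel_mb))
  cat("\n")
  invisible(x)
}

#' @export
coef.ascn_fit <- function(object, ...) {
  if (object$status != "ok") return(c(rho = NA_real_, psi = NA_real_))
  c(rho = object$rho, psi = object$psi)
}

#' @export
residuals.ascn_fit <- function(object, ...) {
  if (object$status != "ok") stopf("no fitted solution (status: %s)", object$status)
  s <- object$solution$segments
  data.frame(chrom = s$chrom, start = s$start, end = s$end,
             resid_nA = s$nA_cont - s$nA, resid_nB = s$nB_cont - s$nB)
}

#' @export
summary.ascn_fit <- function(object, ...) {
  out <- list(sample_id = object$sample_id, status = object$status,
              n_snps = object$n_snps)
  if (object$status == "ok") {
    s <- object$solution$segments
    use <- !is.na(s$nA)
    out$rho <- object$rho
    out$psi <- object$psi
    out$goodness <- object$solution$goodness
    out$homdel_mb <- object$solution$homdel_mb
    out$n_segments <- sum(use)
    out$mean_reliability <- mean(s$reliability[use])
    out$n_candidates <- length(object$candidates)
  }
  if (!is.null(object$qc)) out$qc <- object$qc
  class(out) <- "summary.ascn_fit"
  out
}

#' @export
print.summary.ascn_fit <- function(x, ...) {
  cat(sprintf("Allele-specific copy-number fit: sample '%s' (%d SNPs)\n",
              x$sample_id, x$n_snps))
  cat("Status:", x$status, "\n")
  if (x$status == "ok") {
    cat(sprintf("  aberrant-cell fraction rho = %.2f\n", x$rho))
    cat(sprintf("  average ploidy psi         = %.3f\n", x$psi))
    cat(sprintf("  goodness (lower = better)  = %.4g over %d segments\n",
                x$goodness, x$n_segments))
    cat(sprintf("  mean reliability           = %.3f\n", x$mean_reliability))
    cat(sprintf("  homozygous deletion        = %.1f Mb (%d candidate solutions)\n",
                x$homdel_mb, x$n_candidates))
  }
  if (!is.null(x$qc)) print(x$qc)
  invisible(x)
}

#' @export
plot.ascn_fit <- function(x, ...) {
  if (x$status != "ok") stopf("no fitted solution (status: %s)", x$status)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  g <- x$grid
  graphics::image(g$rho, g$psi, log10(g$goodness + 1e-12),
                  xlab = "aberrant-cell fraction", ylab = "average ploidy",
                  main = "log10 goodness surface",
                  col = grDevices::hcl.colors(64, "viridis"))
  graphics::points(x$rho, x$solution$grid_psi, pch = 4, cex = 2, col = "red")
  s <- x$solution$segments
  use <- !is.na(s$nA)
  s <- s[use, ]
  off <- cumsum(c(0, tapply(s$end, s$chrom, max)[unique(s$chrom)]))
  names(off) <- c(unique(s$chrom), "end")
  xs <- s$start + off[s$chrom]; xe <- s$end + off[s$chrom]
  graphics::plot(NULL, xlim = c(0, max(xe)), ylim = c(-0.2, max(s$nA) + 0.5),
                 xlab = "genome position", ylab = "allele copy number",
                 main = sprintf("rho=%.2f psi=%.2f", x$rho, x$psi))
  graphics::segments(xs, s$nA + 0.05, xe, s$nA + 0.05, col = "red", lwd = 2)
  graphics::segments(xs, s$nB - 0.05, xe, s$nB - 0.05, col = "darkgreen", lwd = 2)
  invisible(x)
}

#' @export
print.ascn_solution <- function(x, ...) {
  cat(sprintf("ascn_solution: rho=%.2f psi=%.3f goodness=%.4g homdel=%.1f Mb (%d segments)\n",
              x$rho, x$psi, x$goodness, x$homdel_mb, nrow(x$segments)))
  invisible(x)
}
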
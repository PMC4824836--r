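# Internal helpers shared across modules.

# Run expr with a temporary RNG state seeded at `seed`, restoring the caller's
# stream afterwards. All user-facing randomness funnels through this so that
# fixed seeds give bit-identical results.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Autosome filter used by the ascn and calls modules; sex chromosomes are
# excluded from fractions, frequency tracks and fitting by default.
SEX_CHROMS <- c("chrX", "chrY", "X", "Y")

drop_sex_chroms <- function(chrom) !(chrom %in% SEX_CHROMS)

# 0-based half-open intervals -> GRanges (1-based closed internally).
as_granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = start + 1L, end = end))
}

check_intervals0 <- function(start, end, what = "interval") {
  bad <- which(!(is.finite(start) & is.finite(end) & start >= 0 & end > start))
  if (length(bad))
    stopf("%s rows %s are not valid 0-based half-open intervals (need 0 <= start < end)",
          what, paste(utils::head(bad, 5L), collapse = ", "))
  invisible(TRUE)
}
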
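# Readers and writers for the plain-text interchange formats: SNP tracks,
# segment profiles, BED genes, GMT gene sets, expression and call tables.
# All coordinates are 0-based half-open; 1-based input is rejected, not
# guessed.

#' Write / read a SNP track (tab-delimited: chrom, pos, lrr, baf, is_het)
#' @param track an `snp_track`.
#' @param path file path.
#' @export
write_snp_track <- function(track, path) {
  df <- as.data.frame(track)
  df$is_het <- as.integer(df$is_het)
  hdr <- sprintf("# snp_track\tsample=%s", attr(track, "sample_id") %||% "sample")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_track
#' @export
read_snp_track <- function(path) {
  first <- readLines(path, n = 1)
  sample_id <- sub(".*sample=", "", first)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "lrr", "baf", "is_het")
  if (!all(need %in% names(df)))
    stopf("%s: SNP track must have columns %s", path, paste(need, collapse = ", "))
  if (any(df$baf < 0 | df$baf > 1))
    stopf("%s: BAF values outside [0, 1]", path)
  df$is_het <- as.logical(df$is_het)
  df <- df[order(match(df$chrom, unique(df$chrom)), df$pos), ]
  rownames(df) <- NULL
  attr(df, "sample_id") <- if (startsWith(first, "#")) sample_id else "sample"
  class(df) <- c("snp_track", "data.frame")
  df
}

#' Write / read allele-specific segment profiles
#'
#' Tab-delimited with one `# sample=<id> rho=<r> psi=<p> goodness=<g>` header
#' line per sample followed by rows `sample, chrom, start, end, nA, nB`.
#' Multiple samples may share one file. This is the input format of the
#' calling stage, and the output format of the fitting stage.
#'
#' @param solutions list of `ascn_solution`s (or `truth_profile`s, whose
#'   `psi_true` is written as psi and goodness as NA).
#' @param path file path.
#' @export
write_segments <- function(solutions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("sample\tchrom\tstart\tend\tnA\tnB", con)
  for (sol in solutions) {
    id <- sol_id(sol)
    rho <- if (inherits(sol, "truth_profile")) sol$rho else sol$rho
    psi <- sol_psi(sol)
    good <- if (inherits(sol, "ascn_solution")) sol$goodness else NA
    writeLines(sprintf("# sample=%s\trho=%.6g\tpsi=%.8g\tgoodness=%.6g",
                       id, rho, psi, good), con)
    segs <- seg_df(sol)
    segs <- segs[!is.na(segs$nA), c("chrom", "start", "end", "nA", "nB")]
    utils::write.table(cbind(sample = id, segs), con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^# sample=", lines)
  meta <- lines[hdr]
  body <- lines[!hdr & !grepl("^sample\t", lines) & nzchar(lines)]
  if (!length(meta)) stopf("%s: no per-sample header lines found", path)
  parse_kv <- function(line, key) {
    m <- regmatches(line, regexpr(paste0(key, "=[^\t ]+"), line))
    if (!length(m)) return(NA)
    sub(paste0(key, "="), "", m)
  }
  df <- utils::read.table(text = body, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("sample", "chrom", "start", "end", "nA", "nB"))
  check_intervals0(df$start, df$end, sprintf("%s segment", path))
  lapply(meta, function(m) {
    id <- parse_kv(m, "sample")
    segs <- df[df$sample == id, c("chrom", "start", "end", "nA", "nB")]
    segs <- segs[order(match(segs$chrom, unique(segs$chrom)), segs$start), ]
    rownames(segs) <- NULL
    segs$n_informative <- NA_integer_
    good <- suppressWarnings(as.numeric(parse_kv(m, "goodness")))
    structure(list(rho = as.numeric(parse_kv(m, "rho")),
                   psi = as.numeric(parse_kv(m, "psi")),
                   segments = segs, goodness = good,
                   homdel_mb = sum((segs$end - segs$start)[segs$nA == 0 & segs$nB == 0]) / 1e6,
                   warning_homdel = FALSE, sample_id = id),
              class = "ascn_solution")
  })
}

#' Read / write a BED gene annotation (0-based half-open)
#'
#' Only the first four columns (chrom, start, end, name) are used. Rows with
#' `end <= start` or negative coordinates are rejected with their line
#' numbers; 1-based input must be converted by the caller, never guessed at.
#'
#' @param path file path.
#' @return data.frame: gene_id, chrom, start, end.
#' @export
read_bed_genes <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 4) stopf("%s: BED needs at least 4 columns (chrom, start, end, name)", path)
  bad <- which(!(df[[2]] >= 0 & df[[3]] > df[[2]]))
  if (length(bad))
    stopf("%s: invalid BED intervals (end <= start or negative start) at data line(s) %s",
          path, paste(utils::head(bad, 5), collapse = ", "))
  out <- data.frame(gene_id = as.character(df[[4]]), chrom = as.character(df[[1]]),
                    start = as.numeric(df[[2]]), end = as.numeric(df[[3]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene_id))
    stopf("%s: duplicated gene ids", path)
  out
}

#' @rdname read_bed_genes
#' @param genes gene table (gene_id, chrom, start, end).
#' @export
write_bed_genes <- function(genes, path) {
  utils::write.table(genes[, c("chrom", "start", "end", "gene_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("%s: GMT lines need name, description and >= 1 gene", path)
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors (or a `gene_set_collection`).
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a gene x sample expression matrix (TSV, genes in rows)
#' @param path file path.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

#' @rdname read_expression
#' @param expression numeric matrix, gene ids as rownames.
#' @export
write_expression <- function(expression, path) {
  df <- data.frame(gene_id = rownames(expression), expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write long-format gene calls
#' @param path file path.
#' @export
write_gene_calls <- function(gene_calls, path) {
  utils::write.table(as.data.frame(gene_calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_calls
#' @param gene_calls a `gene_calls` table.
#' @export
read_gene_calls <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$is_loss <- as.logical(df$is_loss)
  df$is_loh <- as.logical(df$is_loh)
  class(df) <- c("gene_calls", "data.frame")
  df
}
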
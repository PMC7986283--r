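#' Write an omics matrix as gzipped TSV
#'
#' Matrices are stored features x samples with a header row of sample ids
#' and feature ids in the first column, the layout used throughout the
#' package's on-disk interface.
#'
#' @param x omics matrix (samples x features).
#' @param path output path, conventionally ending in `.tsv.gz`.
#' @export
write_omics_matrix <- function(x, path) {
  con <- gzfile(path, "w")
  on.exit(close(con))
  df <- data.frame(feature = colnames(x), t(x), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an omics matrix written by [write_omics_matrix()]
#' @param path path to the gzipped TSV.
#' @return omics matrix (samples x features).
#' @export
read_omics_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- t(as.matrix(df[, -1L, drop = FALSE]))
  colnames(m) <- df[[1L]]
  omics_matrix(m)
}

#' Write a BED-like annotation table
#'
#' CpG annotations use columns (chrom, start, end, id, context); transcript
#' annotations use (chrom, start, end, id, strand). Coordinates in the
#' in-memory tables are 1-based; BED start is written 0-based per the format.
#'
#' @param ann annotation data.frame with 1-based `pos` (CpGs) or `tss`/`tes`
#'   (transcripts) columns.
#' @param path output TSV path.
#' @export
write_annotation_bed <- function(ann, path) {
  if ("pos" %in% names(ann)) {
    bed <- data.frame(chrom = ann$chrom, start = ann$pos - 1L, end = ann$pos,
                      id = ann$cpg_id,
                      context = if ("island_context" %in% names(ann))
                        ann$island_context else ".")
  } else {
    bed <- data.frame(chrom = ann$chrom, start = ann$tss - 1L, end = ann$tes,
                      id = ann$transcript_id, strand = ann$strand)
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a GWAS-style summary statistics table as TSV
#' @param ss summary statistics data.frame (see [emit_summary_stats()]).
#' @param path output path.
#' @export
write_summary_stats <- function(ss, path) {
  utils::write.table(ss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a summary statistics TSV
#' @param path path written by [write_summary_stats()].
#' @export
read_summary_stats <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
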
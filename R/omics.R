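#' Construct an omics matrix
#'
#' An omics matrix is a plain numeric matrix with samples in rows and
#' features (CpGs, transcripts or SNPs) in columns, carrying sample ids as
#' rownames and feature ids as colnames. This is the common currency of the
#' package: methylation beta values in \[0,1\], expression on an arbitrary
#' continuous scale, or genotype dosages in \[0,2\].
#'
#' @param x numeric matrix, samples x features.
#' @param sample_ids optional character vector of sample identifiers.
#' @param feature_ids optional character vector of feature identifiers.
#' @return a validated numeric matrix with dimnames set.
#' @export
omics_matrix <- function(x, sample_ids = rownames(x), feature_ids = colnames(x)) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("omics matrix must be a numeric matrix (samples x features)")
  if (is.null(sample_ids) || is.null(feature_ids))
    stop("sample and feature identifiers are required")
  if (length(sample_ids) != nrow(x) || length(feature_ids) != ncol(x))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(sample_ids) || anyDuplicated(feature_ids))
    stop("sample and feature identifiers must be unique")
  dimnames(x) <- list(sample_ids, feature_ids)
  x
}

#' Check that matrices share an identical sample axis
#' @param ... omics matrices.
#' @return invisibly TRUE; errors if sample ids differ.
#' @keywords internal
check_shared_samples <- function(...) {
  mats <- list(...)
  ids <- rownames(mats[[1L]])
  for (m in mats[-1L]) {
    if (!identical(rownames(m), ids))
      stop("matrices do not share an identical sample axis")
  }
  invisible(TRUE)
}

# stable log(sum(exp(x))) over a vector
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
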
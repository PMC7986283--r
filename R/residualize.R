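#' Residualize an omics matrix against measured covariates
#'
#' Per feature, returns ordinary least squares residuals against the design
#' `[intercept | covariates]`. Character or factor covariate columns (e.g.
#' technical batch) enter as categorical fixed effects. The output is
#' orthogonal to every design column.
#'
#' @param matrix omics matrix (samples x features).
#' @param covariates data.frame of covariates aligned with the sample axis;
#'   a `sample_id` column, if present, is used to check alignment and then
#'   dropped from the design.
#' @return residual omics matrix of the same shape.
#' @export
residualize <- function(matrix, covariates) {
  X <- build_design(matrix, covariates)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  res <- matrix - X %*% qr.coef(q, matrix)
  omics_matrix(res, rownames(matrix), colnames(matrix))
}

# assemble the [intercept | covariates] design with factors expanded
build_design <- function(matrix, covariates) {
  if (nrow(covariates) != nrow(matrix))
    stop("covariates incomplete: row count does not match sample axis")
  if ("sample_id" %in% names(covariates)) {
    if (!identical(as.character(covariates$sample_id), rownames(matrix)))
      stop("covariates incomplete: sample ids do not match the matrix")
    covariates <- covariates[, setdiff(names(covariates), "sample_id"),
                             drop = FALSE]
  }
  if (anyNA(covariates))
    stop("covariates incomplete: missing values present")
  if (ncol(covariates) == 0)
    return(stats::model.matrix(~1, data.frame(row.names = rownames(matrix))))
  stats::model.matrix(~ ., data = covariates)
}

#' Estimate surrogate variables from a residual matrix
#'
#' Surrogate variables are taken as the top-k left singular vectors (sample
#' space) of the feature-centered residual matrix: deterministic latent
#' factors capturing unmodeled structure such as hidden batch. Columns are
#' orthonormal, ordered by singular value; each is signed so its
#' largest-magnitude loading is positive.
#'
#' @param residuals omics matrix of covariate residuals.
#' @param k number of surrogate variables (>= 1).
#' @return samples x k matrix of surrogate variables.
#' @export
compute_surrogate_variables <- function(residuals, k) {
  if (k < 1) stop("k must be >= 1")
  if (k >= min(dim(residuals)))
    stop("k must be smaller than min(n_samples, n_features)")
  centered <- sweep(residuals, 2, colMeans(residuals))
  sv <- svd(centered, nu = k, nv = 0)
  u <- sv$u
  for (j in seq_len(k)) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) u[, j] <- -u[, j]
  }
  rownames(u) <- rownames(residuals)
  colnames(u) <- paste0("SV", seq_len(k))
  u
}

#' Two-stage residualization: covariates, then surrogate variables
#'
#' Implements the residuals-of-residuals clean-up protocol: the matrix is
#' first residualized on the measured covariates, k surrogate variables are
#' estimated from those residuals, and the residuals are residualized again
#' on the surrogate variables. The output is orthogonal to both the
#' covariates and the SVs. For small cohorts k is capped at
#' `floor(n_samples / 10)` (with a message) so the SV design stays well
#' conditioned.
#'
#' @inheritParams residualize
#' @param k requested number of surrogate variables; `k = 0` reduces to
#'   plain covariate residualization.
#' @param cap_k if TRUE (default), cap k at n/10.
#' @return doubly residualized omics matrix with attribute `svs` (the
#'   surrogate variable matrix, or NULL when k = 0).
#' @export
double_residualize <- function(matrix, covariates, k = 25L, cap_k = TRUE) {
  r1 <- residualize(matrix, covariates)
  if (k == 0) {
    attr(r1, "svs") <- NULL
    return(r1)
  }
  if (cap_k) {
    kmax <- max(1L, floor(nrow(matrix) / 10))
    if (k > kmax) {
      message("capping surrogate variable count at n/10 = ", kmax)
      k <- kmax
    }
  }
  svs <- compute_surrogate_variables(r1, k)
  r2 <- residualize(r1, as.data.frame(svs))
  attr(r2, "svs") <- svs
  r2
}
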
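#' Define cis/trans CpG-transcript pairs by genomic distance
#'
#' A pair is cis when the CpG lies on the transcript's chromosome within a
#' closed window around the transcript unit, `[tss - window, tes + window]`;
#' every other pair (including all cross-chromosome pairs) is trans.
#' Distance is 0 for CpGs inside the gene body, otherwise the base-pair
#' distance to the nearer of the transcription start/end site; it is NA for
#' cross-chromosome pairs. Strand is collapsed to plus-strand coordinates
#' (tss/tes swapped if needed) before windowing.
#'
#' @param cpgs CpG annotation data.frame (`cpg_id`, `chrom`, `pos`, and
#'   optionally `island_context`).
#' @param transcripts transcript annotation data.frame (`transcript_id`,
#'   `chrom`, `tss`, `tes`, `strand`).
#' @param cis_window window size in bp on each side of the transcript unit.
#' @param known_chroms optional vector of valid chromosome names; unknown
#'   names raise an error listing the offenders.
#' @return data.frame with columns cpg_id, transcript_id, cis, distance_bp.
#' @export
define_pairs <- function(cpgs, transcripts, cis_window = 500000,
                         known_chroms = NULL) {
  chroms <- c(cpgs$chrom, transcripts$chrom)
  bad <- is.na(chroms) | chroms == ""
  if (!is.null(known_chroms)) bad <- bad | !chroms %in% known_chroms
  if (any(bad))
    stop("unknown chromosome names: ",
         paste(unique(chroms[bad]), collapse = ", "))
  start <- pmin(transcripts$tss, transcripts$tes)
  end <- pmax(transcripts$tss, transcripts$tes)
  nc <- nrow(cpgs); nt <- nrow(transcripts)
  ci <- rep(seq_len(nc), times = nt)
  ti <- rep(seq_len(nt), each = nc)
  pos <- cpgs$pos[ci]
  same_chrom <- cpgs$chrom[ci] == transcripts$chrom[ti]
  s <- start[ti]; e <- end[ti]
  dist <- ifelse(pos >= s & pos <= e, 0L,
                 pmin(abs(pos - transcripts$tss[ti]),
                      abs(pos - transcripts$tes[ti])))
  dist[!same_chrom] <- NA_integer_
  cis <- same_chrom & pos >= (s - cis_window) & pos <= (e + cis_window)
  data.frame(cpg_id = cpgs$cpg_id[ci],
             transcript_id = transcripts$transcript_id[ti],
             cis = cis, distance_bp = as.integer(dist),
             stringsAsFactors = FALSE)
}

# simple-OLS association of y on x with intercept; closed form
pair_ols <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop("fewer than 10 pairwise-complete observations")
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2); syy <- sum(yc^2)
  if (sxx == 0 || syy == 0)
    stop("degenerate input: zero variance in methylation or expression")
  beta <- sum(xc * yc) / sxx
  rss <- max(syy - beta^2 * sxx, 0)
  se <- sqrt(rss / ((n - 2) * sxx))
  tval <- beta / se # Inf on an exact fit; p clamps below
  p <- 2 * stats::pt(-abs(tval), n - 2)
  list(beta = beta, se = se, t = tval,
       p = max(p, .Machine$double.xmin),
       n = n, r_squared = 1 - rss / syy)
}

#' Test a single CpG-transcript pair
#'
#' Simple OLS of the expression residual on the methylation residual with
#' intercept, on pairwise-complete samples; two-sided p from the t
#' distribution with n - 2 df. `r_squared` is the proportion of expression
#' variance explained by the CpG.
#'
#' @param methylation_residuals,expression_residuals residual omics
#'   matrices sharing the sample axis.
#' @param pair list or one-row data.frame with `cpg_id` and `transcript_id`.
#' @return one-row data.frame (cpg_id, transcript_id, beta, se, t, p, n,
#'   r_squared).
#' @export
test_pair <- function(methylation_residuals, expression_residuals, pair) {
  fit <- pair_ols(methylation_residuals[, pair$cpg_id],
                  expression_residuals[, pair$transcript_id])
  data.frame(cpg_id = pair$cpg_id, transcript_id = pair$transcript_id,
             beta = fit$beta, se = fit$se, t = fit$t, p = fit$p, n = fit$n,
             r_squared = fit$r_squared, stringsAsFactors = FALSE)
}

#' Scan all CpG-transcript pairs
#'
#' Tests every pair with the per-pair linear model and flags significance
#' with `p <= cis_alpha` for cis pairs and `p <= trans_alpha` for trans
#' pairs (inclusive thresholds). Pairs with missing values fall back to
#' pairwise-complete testing; complete data uses a vectorized closed form.
#'
#' @inheritParams test_pair
#' @param pairs pair table from [define_pairs()].
#' @param cis_alpha,trans_alpha inclusive significance thresholds.
#' @return list of class `eqtm_scan` with `results` (AssociationResult
#'   table including cis, distance_bp and significant columns),
#'   `cis_significant`, `trans_significant`, and a `summary` list with
#'   counts of significant pairs, unique eQTM CpGs and unique eGenes.
#' @export
eqtm_scan <- function(methylation_residuals, expression_residuals, pairs,
                      cis_alpha = 1e-8, trans_alpha = 1e-12) {
  check_shared_samples(methylation_residuals, expression_residuals)
  n <- nrow(methylation_residuals)
  npair <- nrow(pairs)
  beta <- se <- tval <- pv <- r2 <- numeric(npair)
  nn <- integer(npair)
  has_na <- anyNA(methylation_residuals) || anyNA(expression_residuals)
  chunk <- 5000L
  for (lo in seq(1L, npair, by = chunk)) {
    hi <- min(lo + chunk - 1L, npair)
    idx <- lo:hi
    X <- methylation_residuals[, pairs$cpg_id[idx], drop = FALSE]
    Y <- expression_residuals[, pairs$transcript_id[idx], drop = FALSE]
    if (!has_na) {
      xc <- sweep(X, 2, colMeans(X)); yc <- sweep(Y, 2, colMeans(Y))
      sxx <- colSums(xc^2); syy <- colSums(yc^2)
      sxy <- colSums(xc * yc)
      b <- sxy / sxx
      rss <- pmax(syy - b^2 * sxx, 0)
      s <- sqrt(rss / ((n - 2) * sxx))
      tv <- b / s
      beta[idx] <- b; se[idx] <- s; tval[idx] <- tv
      pv[idx] <- pmax(2 * stats::pt(-abs(tv), n - 2), .Machine$double.xmin)
      r2[idx] <- 1 - rss / syy
      nn[idx] <- n
    } else {
      for (j in seq_along(idx)) {
        fit <- pair_ols(X[, j], Y[, j])
        beta[idx[j]] <- fit$beta; se[idx[j]] <- fit$se
        tval[idx[j]] <- fit$t; pv[idx[j]] <- fit$p
        r2[idx[j]] <- fit$r_squared; nn[idx[j]] <- fit$n
      }
    }
  }
  res <- data.frame(pairs, beta = beta, se = se, t = tval, p = pv, n = nn,
                    r_squared = r2, stringsAsFactors = FALSE)
  res$significant <- ifelse(res$cis, res$p <= cis_alpha, res$p <= trans_alpha)
  cis_sig <- res[res$cis & res$significant, , drop = FALSE]
  trans_sig <- res[!res$cis & res$significant, , drop = FALSE]
  structure(list(
    results = res, cis_significant = cis_sig, trans_significant = trans_sig,
    summary = list(
      n_cis_significant = nrow(cis_sig),
      n_trans_significant = nrow(trans_sig),
      n_eqtm_cpgs = length(unique(c(cis_sig$cpg_id, trans_sig$cpg_id))),
      n_egenes = length(unique(c(cis_sig$transcript_id,
                                 trans_sig$transcript_id))),
      cis_alpha = cis_alpha, trans_alpha = trans_alpha)),
    class = "eqtm_scan")
}

#' Summarize the distance-effect relationship of cis associations
#'
#' @param results cis AssociationResult table with `distance_bp` and
#'   `r_squared` columns (>= 3 rows).
#' @return list with `pearson_r` (correlation of distance with r-squared),
#'   `p`, `median_r_squared`, `fraction_within_100kb`, and `degenerate`
#'   (TRUE with NA correlation when r-squared has no variance).
#' @export
distance_effect_summary <- function(results) {
  if (nrow(results) < 3) stop("need at least 3 cis results")
  out <- list(pearson_r = NA_real_, p = NA_real_,
              median_r_squared = stats::median(results$r_squared),
              fraction_within_100kb = mean(results$distance_bp <= 100000),
              degenerate = FALSE)
  if (stats::var(results$r_squared) == 0 || stats::var(results$distance_bp) == 0) {
    out$degenerate <- TRUE
    return(out)
  }
  ct <- stats::cor.test(results$distance_bp, results$r_squared,
                        method = "pearson")
  out$pearson_r <- unname(ct$estimate)
  out$p <- ct$p.value
  out
}
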
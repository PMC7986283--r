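#' Greedy LD pruning (clumping) of candidate instruments
#'
#' Repeatedly retains the smallest-p SNP and discards every remaining SNP
#' whose squared dosage correlation with it reaches the threshold, until no
#' candidates remain. Output is ordered by retention.
#'
#' @param candidates data.frame with columns `snp` and `p_exposure`.
#' @param ld SNP x SNP r-squared matrix with dimnames covering all
#'   candidates (see [ld_matrix()]).
#' @param r2_threshold discard threshold (default 0.001, i.e. near-perfect
#'   independence required).
#' @return character vector of retained SNP ids.
#' @export
ld_prune <- function(candidates, ld, r2_threshold = 0.001) {
  snps <- candidates$snp
  missing <- setdiff(snps, rownames(ld))
  if (length(missing) > 0)
    stop("missing LD entries for: ", paste(missing, collapse = ", "))
  sub <- ld[snps, snps, drop = FALSE]
  if (anyNA(sub)) {
    idx <- which(is.na(sub), arr.ind = TRUE)
    stop("missing LD entries for pairs: ",
         paste(paste(rownames(sub)[idx[, 1]], colnames(sub)[idx[, 2]],
                     sep = "-")[seq_len(min(5, nrow(idx)))], collapse = ", "))
  }
  p <- candidates$p_exposure
  remaining <- order(p, snps) # deterministic: p then id
  kept <- character(0)
  while (length(remaining) > 0) {
    lead <- remaining[1]
    kept <- c(kept, snps[lead])
    r2 <- sub[lead, remaining]
    remaining <- remaining[r2 < r2_threshold]
  }
  kept
}

#' Pairwise r-squared from a genotype reference matrix
#' @param genotypes dosage omics matrix.
#' @return symmetric matrix of squared Pearson correlations of dosages.
#' @export
ld_matrix <- function(genotypes) {
  stats::cor(genotypes)^2
}

#' Harmonize exposure and outcome summary statistics into instruments
#'
#' Aligns the outcome table's effect alleles to the exposure table's
#' (resolving swaps and strand flips; palindromic SNPs resolved by allele
#' frequency or dropped, see [intersect_region()] for the convention).
#'
#' @param exposure_stats,outcome_stats summary statistic tables.
#' @param palindromic_tol drop palindromic SNPs whose allele frequency is
#'   within this distance of 0.5 in either table.
#' @return instrument data.frame: snp, effect_allele, beta_exposure,
#'   se_exposure, p_exposure, beta_outcome, se_outcome; attribute
#'   `n_dropped_palindromic`.
#' @export
harmonize_instruments <- function(exposure_stats, outcome_stats,
                                  palindromic_tol = 0.08) {
  h <- harmonize_tables(exposure_stats[!is.na(exposure_stats$beta), ],
                        outcome_stats[!is.na(outcome_stats$beta), ],
                        palindromic_tol)
  m <- h$merged
  out <- data.frame(snp = m$snp, effect_allele = m$effect_allele_a,
                    beta_exposure = m$beta_a, se_exposure = m$se_a,
                    p_exposure = m$p_a,
                    beta_outcome = m$beta_b, se_outcome = m$se_b,
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped_palindromic") <- h$n_dropped_palindromic
  out
}

mr_result <- function(exposure_id, outcome_id, method, beta, se,
                      n_instruments, direction_tag = "forward", Q = NA_real_) {
  structure(data.frame(
    exposure_id = exposure_id, outcome_id = outcome_id, method = method,
    beta = beta, se = se, p = 2 * stats::pnorm(-abs(beta / se)),
    n_instruments = as.integer(n_instruments),
    direction_tag = direction_tag, Q = Q, stringsAsFactors = FALSE),
    class = c("mr_result", "data.frame"))
}

#' Wald ratio causal estimate from a single instrument
#'
#' `beta = beta_outcome / beta_exposure`, with the first-order delta-method
#' standard error `|se_outcome / beta_exposure|` and a two-sided normal
#' p-value.
#'
#' @param inst one-row instrument data.frame (see
#'   [harmonize_instruments()]).
#' @param exposure_id,outcome_id labels carried into the result.
#' @param direction_tag `"forward"` or `"reverse"`.
#' @return one-row `mr_result` data.frame.
#' @export
wald_ratio <- function(inst, exposure_id = "exposure",
                       outcome_id = "outcome", direction_tag = "forward") {
  if (inst$beta_exposure == 0)
    stop("weak instrument: beta_exposure is zero")
  mr_result(exposure_id, outcome_id, "wald_ratio",
            inst$beta_outcome / inst$beta_exposure,
            abs(inst$se_outcome / inst$beta_exposure),
            1L, direction_tag)
}

#' Inverse-variance-weighted multi-instrument causal estimate
#'
#' Pools per-instrument Wald ratios with weights equal to the inverse
#' first-order variance (fixed effect); equivalent to a zero-intercept
#' weighted least squares regression of outcome betas on exposure betas
#' with weights `1/se_outcome^2`. Cochran's Q is reported as a
#' heterogeneity diagnostic, not absorbed into the standard error. With a
#' single instrument the call defers to [wald_ratio()] with a message.
#'
#' @param instruments instrument data.frame (>= 2 rows for IVW proper).
#' @inheritParams wald_ratio
#' @return one-row `mr_result` data.frame.
#' @export
mr_ivw <- function(instruments, exposure_id = "exposure",
                   outcome_id = "outcome", direction_tag = "forward") {
  if (nrow(instruments) < 1) stop("no instruments")
  if (nrow(instruments) < 2) {
    message("single instrument: deferring to the Wald ratio")
    return(wald_ratio(instruments, exposure_id, outcome_id, direction_tag))
  }
  if (any(instruments$beta_exposure == 0))
    stop("weak instrument: beta_exposure is zero")
  bj <- instruments$beta_outcome / instruments$beta_exposure
  sej <- abs(instruments$se_outcome / instruments$beta_exposure)
  w <- 1 / sej^2
  beta <- sum(w * bj) / sum(w)
  se <- sqrt(1 / sum(w))
  Q <- sum(w * (bj - beta)^2)
  mr_result(exposure_id, outcome_id, "ivw", beta, se,
            nrow(instruments), direction_tag, Q)
}

# auto-select the estimator by instrument count
mr_auto <- function(instruments, exposure_id = "exposure",
                    outcome_id = "outcome", direction_tag = "forward") {
  if (nrow(instruments) == 1)
    wald_ratio(instruments, exposure_id, outcome_id, direction_tag)
  else mr_ivw(instruments, exposure_id, outcome_id, direction_tag)
}

#' Bidirectional two-sample Mendelian randomization
#'
#' Runs the forward test (e.g. CpG methylation as exposure, smoking
#' pack-years as outcome, instrumented by mQTLs) and the reverse test
#' (pack-years as exposure, methylation as outcome, instrumented by trait
#' GWAS SNPs), tagging each result with its direction. Each instrument set
#' must have been selected for its association with its own exposure: any
#' instrument whose exposure p-value exceeds `iv_p_max` triggers a
#' validation error, which also catches the misuse of picking an IV for
#' its outcome association.
#'
#' @param forward_instruments,reverse_instruments harmonized, LD-pruned
#'   instrument data.frames with a `p_exposure` column.
#' @param exposure_id,outcome_id labels of the forward direction (reversed
#'   for the reverse test).
#' @param iv_p_max maximum admissible instrument-exposure p-value.
#' @return list with `forward` and `reverse` one-row `mr_result`
#'   data.frames.
#' @export
bidirectional_mr <- function(forward_instruments, reverse_instruments,
                             exposure_id = "exposure",
                             outcome_id = "outcome", iv_p_max = 1e-3) {
  check_iv <- function(inst, dir) {
    if (!"p_exposure" %in% names(inst) || anyNA(inst$p_exposure))
      stop("instrument validation error (", dir,
           "): p_exposure missing; instruments must be selected on their ",
           "exposure association")
    if (any(inst$p_exposure > iv_p_max))
      stop("instrument validation error (", dir, "): instrument(s) ",
           paste(inst$snp[inst$p_exposure > iv_p_max], collapse = ", "),
           " not associated with the exposure (p > ", iv_p_max, ")")
  }
  check_iv(forward_instruments, "forward")
  check_iv(reverse_instruments, "reverse")
  list(forward = mr_auto(forward_instruments, exposure_id, outcome_id,
                         "forward"),
       reverse = mr_auto(reverse_instruments, outcome_id, exposure_id,
                         "reverse"))
}
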
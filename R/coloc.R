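#' Per-SNP prior probabilities for colocalization
#'
#' @param p1,p2 prior probability that a SNP is associated with trait 1
#'   (mQTL) / trait 2 (eQTL) only.
#' @param p12 prior probability that a SNP is associated with both traits.
#' @return list of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  for (p in c(p1, p2, p12))
    if (p <= 0 || p >= 1) stop("priors must lie in (0, 1)")
  if (p1 + p2 + p12 >= 1) stop("p1 + p2 + p12 must be < 1")
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

# alleles whose complement equals the swap (A/T, C/G): strand-ambiguous
is_palindromic <- function(a1, a2) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  comp[a1] == a2
}

# harmonize table b's effect alleles to table a's; resolves swaps and
# strand flips; palindromic SNPs resolved by allele frequency unless the
# frequency is uninformative (within tol of 0.5), in which case dropped
harmonize_tables <- function(a, b, palindromic_tol = 0.08) {
  m <- merge(a, b, by = "snp", suffixes = c("_a", "_b"))
  if (nrow(m) == 0) return(list(merged = m, n_dropped_palindromic = 0L))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ea_a <- m$effect_allele_a; oa_a <- m$other_allele_a
  ea_b <- m$effect_allele_b; oa_b <- m$other_allele_b
  pal <- is_palindromic(ea_a, oa_a)
  flip <- rep(NA, nrow(m))
  direct <- ea_b == ea_a & oa_b == oa_a
  swapped <- ea_b == oa_a & oa_b == ea_a
  strand <- comp[ea_b] == ea_a & comp[oa_b] == oa_a
  strand_swapped <- comp[ea_b] == oa_a & comp[oa_b] == ea_a
  flip[direct | strand] <- FALSE
  flip[swapped | strand_swapped] <- TRUE
  drop <- is.na(flip)
  if (any(pal, na.rm = TRUE)) {
    amb <- pal & !drop
    if ("eaf_a" %in% names(m) && "eaf_b" %in% names(m)) {
      uninformative <- abs(m$eaf_a - 0.5) < palindromic_tol |
        abs(m$eaf_b - 0.5) < palindromic_tol
      # frequency-resolved orientation: matching minor/major sides means
      # the alleles already refer to the same strand orientation
      freq_flip <- (m$eaf_a - 0.5) * (m$eaf_b - 0.5) < 0
      flip[amb & !uninformative] <- freq_flip[amb & !uninformative]
      drop[amb & uninformative] <- TRUE
    } else {
      drop[amb] <- TRUE
    }
  }
  n_pal_dropped <- sum(drop & pal, na.rm = TRUE)
  m <- m[!drop, , drop = FALSE]
  flip <- flip[!drop]
  m$beta_b <- ifelse(flip, -m$beta_b, m$beta_b)
  if ("eaf_b" %in% names(m)) m$eaf_b <- ifelse(flip, 1 - m$eaf_b, m$eaf_b)
  m$effect_allele_b <- m$effect_allele_a
  m$other_allele_b <- m$other_allele_a
  list(merged = m, n_dropped_palindromic = n_pal_dropped)
}

#' Intersect mQTL and eQTL summary statistics over a genomic region
#'
#' Restricts both tables to the closed window `[center - window,
#' center + window]`, intersects their SNP sets, and harmonizes effect
#' alleles (sign flips for swapped alleles, strand flips resolved by
#' complementing; palindromic SNPs resolved by allele frequency or dropped
#' with a count). An empty intersection returns an explicit empty-region
#' object so downstream callers return a no-call rather than H0.
#'
#' @param mqtl,eqtl summary statistic tables (columns snp, pos,
#'   effect_allele, other_allele, eaf, beta, se).
#' @param center_pos region center in bp.
#' @param window half-window in bp (default 1 Mb each side).
#' @return list of class `region_stats` with vectors snp, pos, beta_m,
#'   se_m, beta_e, se_e, n_snps, n_dropped_palindromic and `empty` flag.
#' @export
intersect_region <- function(mqtl, eqtl, center_pos, window = 1e6) {
  sel_m <- !is.na(mqtl$beta) & mqtl$pos >= center_pos - window &
    mqtl$pos <= center_pos + window
  sel_e <- !is.na(eqtl$beta) & eqtl$pos >= center_pos - window &
    eqtl$pos <= center_pos + window
  h <- harmonize_tables(mqtl[sel_m, , drop = FALSE],
                        eqtl[sel_e, , drop = FALSE])
  m <- h$merged
  structure(list(snp = m$snp, pos = m$pos_a,
                 beta_m = m$beta_a, se_m = m$se_a,
                 beta_e = m$beta_b, se_e = m$se_b,
                 n_snps = nrow(m),
                 n_dropped_palindromic = h$n_dropped_palindromic,
                 empty = nrow(m) == 0L),
            class = "region_stats")
}

#' Log approximate Bayes factor for a single SNP association
#'
#' Wakefield's asymptotic Bayes factor in favour of association, computed
#' from the estimate, its standard error, and a normal effect prior with
#' standard deviation `prior_sd_W`:
#' `log ABF = 0.5 log(1 - r) + z^2 r / 2` with `z = beta/se`,
#' `r = W^2 / (W^2 + se^2)`.
#'
#' @param beta,se association estimate and standard error (se > 0).
#' @param prior_sd_W prior effect standard deviation W (> 0).
#' @return log approximate Bayes factor (vectorized).
#' @export
log_abf <- function(beta, se, prior_sd_W) {
  if (any(se <= 0)) stop("se must be positive")
  if (any(prior_sd_W <= 0)) stop("prior_sd_W must be positive")
  r <- prior_sd_W^2 / (prior_sd_W^2 + se^2)
  z <- beta / se
  0.5 * log(1 - r) + z^2 * r / 2
}

#' Bayesian colocalization of two association signals over one region
#'
#' Computes posterior probabilities of the five hypotheses H0 (no
#' association), H1 (trait-1 only), H2 (trait-2 only), H3 (two distinct
#' causal variants) and H4 (one shared causal variant) from per-SNP
#' approximate Bayes factors, assuming at most one causal variant per
#' trait. With a single SNP H3 has no support and PP3 is exactly zero
#' (flagged).
#'
#' @param region a `region_stats` object from [intersect_region()] (or a
#'   list with beta_m, se_m, beta_e, se_e).
#' @param priors a [coloc_priors()] object.
#' @param W_m,W_e prior effect standard deviations for the methylation and
#'   expression traits.
#' @param pp4_cutoff posterior threshold calling colocalization.
#' @return one-row data.frame of class `coloc_result`: pp0..pp4, n_snps,
#'   colocalized, single_snp, plus an `h3_clamped` flag when the H3 mass
#'   had to be clamped for numerical reasons.
#' @export
colocalize <- function(region, priors = coloc_priors(), W_m = 0.15,
                       W_e = 0.15, pp4_cutoff = 0.8) {
  if (isTRUE(region$empty) || length(region$beta_m) == 0)
    stop("empty region: no shared SNPs (no-call)")
  a <- log_abf(region$beta_m, region$se_m, W_m)
  b <- log_abf(region$beta_e, region$se_e, W_e)
  k <- length(a)
  L1 <- logsumexp(a); L2 <- logsumexp(b); L12 <- logsumexp(a + b)
  h3_clamped <- FALSE
  if (k == 1) {
    h3 <- -Inf
  } else {
    d <- L12 - (L1 + L2)
    if (d >= 0) { # numerically L12 >= L1+L2: no distinct-variant mass left
      h3 <- -Inf
      h3_clamped <- TRUE
    } else {
      h3 <- log(priors$p1) + log(priors$p2) + L1 + L2 + log1p(-exp(d))
    }
  }
  h <- c(0,
         log(priors$p1) + L1,
         log(priors$p2) + L2,
         h3,
         log(priors$p12) + L12)
  pp <- exp(h - logsumexp(h))
  pp <- pp / sum(pp)
  structure(data.frame(pp0 = pp[1], pp1 = pp[2], pp2 = pp[3], pp3 = pp[4],
                       pp4 = pp[5], n_snps = k,
                       colocalized = pp[5] > pp4_cutoff,
                       single_snp = k == 1L, h3_clamped = h3_clamped,
                       stringsAsFactors = FALSE),
            class = c("coloc_result", "data.frame"))
}

#' Screen CpG-transcript pairs and colocalize those with shared QTL support
#'
#' For each candidate pair, SNPs are screened for QTL significance within
#' each summary-statistic store (Benjamini-Hochberg FDR across the store,
#' default 5%); a pair qualifies when at least one SNP passes the screen in
#' both its mQTL and its eQTL table. Qualifying pairs are colocalized over
#' all their shared (harmonized) SNPs; the rest are labeled
#' `no_shared_snp`.
#'
#' @param pair_list data.frame with cpg_id, transcript_id.
#' @param mqtl_store named list of summary-stat tables keyed by cpg_id.
#' @param eqtl_store named list of summary-stat tables keyed by
#'   transcript_id.
#' @param priors a [coloc_priors()].
#' @param fdr screen threshold on BH-adjusted p within each store.
#' @param W_m,W_e,pp4_cutoff passed to [colocalize()].
#' @return data.frame with one row per pair: cpg_id, transcript_id, status,
#'   n_snps, pp0..pp4, colocalized.
#' @export
coloc_screen <- function(pair_list, mqtl_store, eqtl_store,
                         priors = coloc_priors(), fdr = 0.05,
                         W_m = 0.15, W_e = 0.15, pp4_cutoff = 0.8) {
  adjust_store <- function(store) {
    all_p <- unlist(lapply(store, function(t) t$p), use.names = FALSE)
    adj <- stats::p.adjust(all_p, method = "BH")
    i <- 0L
    lapply(store, function(t) {
      t$p_fdr <- adj[i + seq_len(nrow(t))]
      i <<- i + nrow(t)
      t
    })
  }
  mqtl_store <- adjust_store(mqtl_store)
  eqtl_store <- adjust_store(eqtl_store)
  rows <- lapply(seq_len(nrow(pair_list)), function(i) {
    cpg <- pair_list$cpg_id[i]; tx <- pair_list$transcript_id[i]
    base <- data.frame(cpg_id = cpg, transcript_id = tx,
                       status = "no_shared_snp", n_snps = 0L,
                       pp0 = NA_real_, pp1 = NA_real_, pp2 = NA_real_,
                       pp3 = NA_real_, pp4 = NA_real_, colocalized = NA,
                       stringsAsFactors = FALSE)
    mt <- mqtl_store[[cpg]]; et <- eqtl_store[[tx]]
    if (is.null(mt) || is.null(et)) return(base)
    sig_m <- mt$snp[!is.na(mt$p_fdr) & mt$p_fdr < fdr]
    sig_e <- et$snp[!is.na(et$p_fdr) & et$p_fdr < fdr]
    h <- harmonize_tables(mt[!is.na(mt$beta), ], et[!is.na(et$beta), ])
    shared <- h$merged$snp
    if (length(intersect(intersect(sig_m, sig_e), shared)) == 0) return(base)
    region <- structure(list(beta_m = h$merged$beta_a, se_m = h$merged$se_a,
                             beta_e = h$merged$beta_b, se_e = h$merged$se_b,
                             empty = FALSE), class = "region_stats")
    cr <- colocalize(region, priors, W_m, W_e, pp4_cutoff)
    data.frame(cpg_id = cpg, transcript_id = tx, status = "ok",
               n_snps = cr$n_snps, pp0 = cr$pp0, pp1 = cr$pp1, pp2 = cr$pp2,
               pp3 = cr$pp3, pp4 = cr$pp4, colocalized = cr$colocalized,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
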
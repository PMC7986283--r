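#' Define the causal architecture of a synthetic cohort
#'
#' The architecture collects every injected effect the generator realizes:
#' SNP effects on CpG methylation (mQTLs, on the logit-methylation scale),
#' CpG effects on transcript expression (eQTMs, with an explicit sign),
#' SNP effects on expression (eQTLs), pack-year effects on methylation,
#' and effects of molecular traits or smoking exposure on a binary disease
#' outcome. Shared-variant and distinct-variant triples record the ground
#' truth used to label colocalization scenarios (one SNP driving both
#' methylation and expression versus two different SNPs).
#'
#' @param mqtl_effects data.frame with columns `snp_id`, `cpg_id`, `beta`
#'   (logit-methylation units per dosage allele).
#' @param eqtm_effects data.frame with columns `cpg_id`, `transcript_id`,
#'   `beta` and optionally `sign` (`"+"` or `"-"`); when `sign` is present
#'   the stored beta is `abs(beta)` carrying that sign.
#' @param eqtl_effects data.frame with columns `snp_id`, `transcript_id`,
#'   `beta` (expression units per dosage allele).
#' @param shared_causal data.frame with columns `snp_id`, `cpg_id`,
#'   `transcript_id`: truth labels for pairs driven by one shared variant.
#' @param distinct_causal data.frame with columns `snp_a`, `cpg_id`,
#'   `snp_b`, `transcript_id`: truth labels for pairs driven by two
#'   distinct variants.
#' @param smoking_effects data.frame with columns `cpg_id`, `beta`
#'   (logit-methylation units per pack-year).
#' @param outcome_effects data.frame with columns `source` (a transcript id,
#'   a CpG id, or `"packyears"`) and `beta` (log-odds per unit).
#' @param covariate_effects_methylation,covariate_effects_expression
#'   data.frames with columns `covariate`, `feature_id`, `beta` injecting
#'   measured-covariate (or batch) structure into the molecular matrices.
#' @param noise_sd_methylation,noise_sd_expression positive residual
#'   standard deviations on the latent logit scale and the expression scale.
#' @param mu_methylation optional named numeric of per-CpG baselines on the
#'   logit scale; CpGs not named (or a `NULL` value) get baselines drawn by
#'   the generator.
#' @param alpha_expression optional named numeric of per-transcript
#'   intercepts; defaults to zero.
#' @return an object of class `causal_architecture`.
#' @export
causal_architecture <- function(mqtl_effects = NULL,
                                eqtm_effects = NULL,
                                eqtl_effects = NULL,
                                shared_causal = NULL,
                                distinct_causal = NULL,
                                smoking_effects = NULL,
                                outcome_effects = NULL,
                                covariate_effects_methylation = NULL,
                                covariate_effects_expression = NULL,
                                noise_sd_methylation = 0.5,
                                noise_sd_expression = 1,
                                mu_methylation = NULL,
                                alpha_expression = NULL) {
  if (!is.null(eqtm_effects) && nrow(eqtm_effects) > 0 &&
      "sign" %in% names(eqtm_effects)) {
    bad <- !eqtm_effects$sign %in% c("+", "-")
    if (any(bad)) stop("eqtm_effects$sign must be '+' or '-'")
    eqtm_effects$beta <- abs(eqtm_effects$beta) *
      ifelse(eqtm_effects$sign == "-", -1, 1)
  }
  if (noise_sd_methylation <= 0 || noise_sd_expression <= 0)
    stop("noise standard deviations must be positive")
  if (!is.null(shared_causal) && !is.null(distinct_causal) &&
      nrow(shared_causal) > 0 && nrow(distinct_causal) > 0) {
    key_s <- paste(shared_causal$cpg_id, shared_causal$transcript_id)
    key_d <- paste(distinct_causal$cpg_id, distinct_causal$transcript_id)
    if (any(key_s %in% key_d))
      stop("a (cpg, transcript) pair cannot be both shared- and distinct-causal")
  }
  structure(list(
    mqtl_effects = mqtl_effects, eqtm_effects = eqtm_effects,
    eqtl_effects = eqtl_effects, shared_causal = shared_causal,
    distinct_causal = distinct_causal, smoking_effects = smoking_effects,
    outcome_effects = outcome_effects,
    covariate_effects_methylation = covariate_effects_methylation,
    covariate_effects_expression = covariate_effects_expression,
    noise_sd_methylation = noise_sd_methylation,
    noise_sd_expression = noise_sd_expression,
    mu_methylation = mu_methylation,
    alpha_expression = alpha_expression
  ), class = "causal_architecture")
}

# check that every id an effect table references exists among known ids
check_arch_ids <- function(ids, known, what) {
  missing <- setdiff(ids, known)
  if (length(missing) > 0)
    stop("unknown ", what, " referenced in architecture: ",
         paste(utils::head(missing, 5), collapse = ", "))
  invisible(TRUE)
}

#' Draw a realistic random causal architecture for a set of annotations
#'
#' Picks cis CpG-transcript pairs (CpG within the window around the
#' transcript unit) and assigns effects emulating a whole-blood cohort:
#' two thirds of eQTM effects negative, mQTL/eQTL effects on nearby SNPs,
#' a subset of shared-variant (one SNP driving both methylation and
#' expression) and distinct-variant (two unlinked SNPs) pairs for
#' colocalization truth, smoking effects lowering methylation, and a
#' pack-year effect on the disease outcome.
#'
#' @param cpg_annotation,transcript_annotation,snp_annotation annotation
#'   tables from [simulate_genotypes()] / [simulate_covariates()].
#' @param n_eqtm number of cis eQTM effects.
#' @param n_shared,n_distinct number of shared-/distinct-variant pairs.
#' @param n_smoking number of smoking-affected CpGs.
#' @param eqtm_beta_range magnitude range of eQTM effects (expression
#'   units per unit beta value).
#' @param mqtl_beta,eqtl_beta effect sizes for causal SNPs.
#' @param smoking_beta logit-methylation change per pack-year.
#' @param frac_negative fraction of eQTM effects with negative sign.
#' @param cis_window window used to pick cis CpGs.
#' @param outcome_packyears_beta log-odds of disease per pack-year.
#' @param noise_sd_methylation,noise_sd_expression residual sds.
#' @param seed integer seed.
#' @return a [causal_architecture()].
#' @export
random_architecture <- function(cpg_annotation, transcript_annotation,
                                snp_annotation, n_eqtm = 10,
                                n_shared = 3, n_distinct = 3,
                                n_smoking = 5,
                                eqtm_beta_range = c(2, 8),
                                mqtl_beta = 0.8, eqtl_beta = 0.6,
                                smoking_beta = -0.02,
                                frac_negative = 2 / 3,
                                cis_window = 500000,
                                outcome_packyears_beta = 0.03,
                                noise_sd_methylation = 0.4,
                                noise_sd_expression = 1, seed = 1L) {
  set.seed(seed)
  # cis candidates: nearest CpG-transcript combinations within the window
  pairs <- define_pairs(cpg_annotation, transcript_annotation, cis_window)
  cis <- pairs[pairs$cis, , drop = FALSE]
  cis <- cis[sample.int(nrow(cis)), , drop = FALSE]
  cis <- cis[!duplicated(cis$cpg_id) & !duplicated(cis$transcript_id), ,
             drop = FALSE]
  n_eqtm <- min(n_eqtm, nrow(cis))
  pick <- cis[seq_len(n_eqtm), , drop = FALSE]
  sgn <- ifelse(stats::runif(n_eqtm) < frac_negative, "-", "+")
  eqtm <- data.frame(cpg_id = pick$cpg_id, transcript_id = pick$transcript_id,
                     beta = stats::runif(n_eqtm, eqtm_beta_range[1],
                                         eqtm_beta_range[2]),
                     sign = sgn, stringsAsFactors = FALSE)
  nearest_snp <- function(pos, exclude = character(0)) {
    ok <- !snp_annotation$snp_id %in% exclude
    snp_annotation$snp_id[ok][which.min(abs(snp_annotation$pos[ok] - pos))]
  }
  cpg_pos <- stats::setNames(cpg_annotation$pos, cpg_annotation$cpg_id)
  tx_pos <- stats::setNames(transcript_annotation$tss,
                            transcript_annotation$transcript_id)
  mqtl <- eqtl <- shared <- distinct <- NULL
  n_shared <- min(n_shared, n_eqtm)
  if (n_shared > 0) {
    sh <- pick[seq_len(n_shared), , drop = FALSE]
    snp <- vapply(sh$cpg_id, function(c) nearest_snp(cpg_pos[c]), character(1))
    shared <- data.frame(snp_id = snp, cpg_id = sh$cpg_id,
                         transcript_id = sh$transcript_id,
                         stringsAsFactors = FALSE)
    mqtl <- data.frame(snp_id = snp, cpg_id = sh$cpg_id, beta = mqtl_beta)
    eqtl <- data.frame(snp_id = snp, transcript_id = sh$transcript_id,
                       beta = eqtl_beta)
  }
  if (n_distinct > 0 && n_eqtm > n_shared) {
    di <- pick[(n_shared + 1):min(n_shared + n_distinct, n_eqtm), ,
               drop = FALSE]
    snp_a <- vapply(di$cpg_id, function(c) nearest_snp(cpg_pos[c]),
                    character(1))
    snp_b <- vapply(seq_len(nrow(di)), function(i)
      nearest_snp(tx_pos[di$transcript_id[i]], exclude = snp_a[i]),
      character(1))
    distinct <- data.frame(snp_a = snp_a, cpg_id = di$cpg_id, snp_b = snp_b,
                           transcript_id = di$transcript_id,
                           stringsAsFactors = FALSE)
    mqtl <- rbind(mqtl, data.frame(snp_id = snp_a, cpg_id = di$cpg_id,
                                   beta = mqtl_beta))
    eqtl <- rbind(eqtl, data.frame(snp_id = snp_b,
                                   transcript_id = di$transcript_id,
                                   beta = eqtl_beta))
  }
  smoking <- if (n_smoking > 0)
    data.frame(cpg_id = sample(cpg_annotation$cpg_id,
                               min(n_smoking, nrow(cpg_annotation))),
               beta = smoking_beta, stringsAsFactors = FALSE)
  else NULL
  # per-CpG baselines are a property of the CpG, not the cohort: fixing
  # them in the architecture lets several cohorts share the same loci
  mu <- stats::setNames(stats::runif(nrow(cpg_annotation), -2, 2),
                        cpg_annotation$cpg_id)
  causal_architecture(
    mu_methylation = mu,
    mqtl_effects = mqtl, eqtm_effects = eqtm, eqtl_effects = eqtl,
    shared_causal = shared, distinct_causal = distinct,
    smoking_effects = smoking,
    outcome_effects = data.frame(source = "packyears",
                                 beta = outcome_packyears_beta),
    noise_sd_methylation = noise_sd_methylation,
    noise_sd_expression = noise_sd_expression)
}
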
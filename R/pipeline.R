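#' Configuration for an end-to-end synthetic study
#'
#' Collects the simulation config, the causal architecture, every analysis
#' threshold, and stage toggles. Every run writes (or returns) a manifest
#' echoing the resolved values.
#'
#' @param sim a [sim_config()].
#' @param architecture a [causal_architecture()].
#' @param prevalence target outcome prevalence.
#' @param n_svs surrogate variables for the two-stage residualization.
#' @param cis_window cis window in bp around the transcript unit.
#' @param cis_alpha,trans_alpha inclusive scan significance thresholds.
#' @param conditional_alpha conditional-analysis threshold (strict).
#' @param conditional_mode `"single_round"` or `"stepwise"`.
#' @param qtl_fdr BH FDR screen for shared-SNP eligibility in coloc.
#' @param priors a [coloc_priors()].
#' @param pp4_cutoff colocalization call threshold on PP4.
#' @param coloc_window half-window in bp for QTL stores around a feature.
#' @param ld_r2 LD pruning threshold for MR instruments.
#' @param iv_alpha instrument-exposure significance threshold.
#' @param censor_p storage threshold assumed for censored cohorts.
#' @param smoking_alpha threshold flagging smoking-associated CpGs.
#' @param mr_max_exposures cap on the number of CpG exposures taken to MR.
#' @param stages named logical vector toggling scan, conditional, coloc,
#'   mr and enrichment stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim, architecture, prevalence = 0.2,
                            n_svs = 25L, cis_window = 500000,
                            cis_alpha = 1e-8, trans_alpha = 1e-12,
                            conditional_alpha = 1e-8,
                            conditional_mode = "single_round",
                            qtl_fdr = 0.05, priors = coloc_priors(),
                            pp4_cutoff = 0.8, coloc_window = 1e6,
                            ld_r2 = 0.001, iv_alpha = 1e-5,
                            censor_p = 1e-4, smoking_alpha = 1e-5,
                            mr_max_exposures = 10L,
                            stages = c(scan = TRUE, conditional = TRUE,
                                       coloc = TRUE, mr = TRUE,
                                       enrichment = TRUE)) {
  thresholds <- list(n_svs = n_svs, cis_window = cis_window,
                     cis_alpha = cis_alpha, trans_alpha = trans_alpha,
                     conditional_alpha = conditional_alpha,
                     qtl_fdr = qtl_fdr, p1 = priors$p1, p2 = priors$p2,
                     p12 = priors$p12, pp4_cutoff = pp4_cutoff,
                     coloc_window = coloc_window, ld_r2 = ld_r2,
                     iv_alpha = iv_alpha, censor_p = censor_p,
                     smoking_alpha = smoking_alpha)
  if (any(vapply(thresholds, function(x) !is.finite(x) || x <= 0,
                 logical(1))))
    stop("all thresholds must be positive")
  structure(list(sim = sim, architecture = architecture,
                 prevalence = prevalence, priors = priors,
                 thresholds = thresholds,
                 conditional_mode = conditional_mode,
                 mr_max_exposures = mr_max_exposures, stages = stages),
            class = "pipeline_config")
}

# marginal QTL summary stats for one feature's residual vector over SNPs
# within a window around the feature position
qtl_table <- function(genotypes, snp_annotation, trait, center, window) {
  sel <- snp_annotation$pos >= center - window &
    snp_annotation$pos <= center + window
  emit_summary_stats(genotypes[, snp_annotation$snp_id[sel], drop = FALSE],
                     trait, "quantitative", snp_annotation)
}

#' Run the full synthetic eQTM study
#'
#' Executes the stages in dependency order: cohort simulation, two-stage
#' residualization of methylation and expression, cis/trans scan,
#' conditional analysis, mQTL/eQTL colocalization screen, forward and
#' reverse Mendelian randomization against pack-years of smoking, and
#' annotation enrichment. Identical configs (including seeds) reproduce
#' identical outputs; a manifest records every threshold, seed and stage
#' row count. When `out_dir` is given, stage outputs are written as TSVs
#' plus a YAML manifest.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list of class `pipeline_run` with cohort, residuals, scan,
#'   conditional, coloc, mr, enrichment and manifest elements (disabled
#'   stages are NULL).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  th <- config$thresholds
  on_fail <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cohort <- on_fail("simulate",
                    simulate_cohort(config$sim, config$architecture,
                                    config$prevalence))
  meth_res <- on_fail("residualize",
                      double_residualize(cohort$methylation,
                                         cohort$covariates, th$n_svs))
  expr_res <- on_fail("residualize",
                      double_residualize(cohort$expression,
                                         cohort$covariates, th$n_svs))
  scan <- conditional <- coloc <- mr <- enrichment <- NULL
  if (isTRUE(config$stages[["scan"]])) {
    pairs <- on_fail("scan", define_pairs(cohort$cpg_annotation,
                                          cohort$transcript_annotation,
                                          th$cis_window))
    scan <- on_fail("scan", eqtm_scan(meth_res, expr_res, pairs,
                                      th$cis_alpha, th$trans_alpha))
  }
  if (isTRUE(config$stages[["conditional"]]) && !is.null(scan)) {
    conditional <- on_fail("conditional",
      condition_on_top(meth_res, expr_res, scan$cis_significant,
                       cohort$cpg_annotation, th$conditional_alpha,
                       config$conditional_mode))
  }
  nonred <- if (!is.null(conditional)) conditional$nonredundant else NULL
  if (isTRUE(config$stages[["coloc"]]) && !is.null(nonred) &&
      nrow(nonred) > 0) {
    coloc <- on_fail("coloc", {
      pair_list <- unique(nonred[, c("cpg_id", "transcript_id")])
      cpg_pos <- stats::setNames(cohort$cpg_annotation$pos,
                                 cohort$cpg_annotation$cpg_id)
      tx_pos <- stats::setNames(cohort$transcript_annotation$tss,
                                cohort$transcript_annotation$transcript_id)
      mqtl_store <- lapply(stats::setNames(nm = unique(pair_list$cpg_id)),
        function(cpg) qtl_table(cohort$genotypes, cohort$snp_annotation,
                                meth_res[, cpg], cpg_pos[cpg],
                                th$coloc_window))
      eqtl_store <- lapply(stats::setNames(nm = unique(pair_list$transcript_id)),
        function(tx) qtl_table(cohort$genotypes, cohort$snp_annotation,
                               expr_res[, tx], tx_pos[tx], th$coloc_window))
      coloc_screen(pair_list, mqtl_store, eqtl_store, config$priors,
                   th$qtl_fdr, pp4_cutoff = th$pp4_cutoff)
    })
  }
  if (isTRUE(config$stages[["mr"]])) {
    mr <- on_fail("mr", {
      exposures <- if (!is.null(nonred) && nrow(nonred) > 0)
        utils::head(unique(nonred$cpg_id), config$mr_max_exposures)
      else character(0)
      outcome_ss <- emit_summary_stats(cohort$genotypes, cohort$packyears,
                                       "quantitative", cohort$snp_annotation)
      ld <- ld_matrix(cohort$genotypes)
      cpg_pos <- stats::setNames(cohort$cpg_annotation$pos,
                                 cohort$cpg_annotation$cpg_id)
      rows <- lapply(exposures, function(cpg) {
        exp_ss <- qtl_table(cohort$genotypes, cohort$snp_annotation,
                            meth_res[, cpg], cpg_pos[cpg], th$coloc_window)
        cand <- exp_ss[!is.na(exp_ss$p) & exp_ss$p < th$iv_alpha, ]
        if (nrow(cand) == 0) return(NULL)
        kept <- ld_prune(data.frame(snp = cand$snp, p_exposure = cand$p),
                         ld, th$ld_r2)
        inst <- harmonize_instruments(exp_ss[exp_ss$snp %in% kept, ],
                                      outcome_ss)
        if (nrow(inst) == 0) return(NULL)
        mr_auto(inst, cpg, "packyears", "forward")
      })
      do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    })
  }
  if (isTRUE(config$stages[["enrichment"]]) && !is.null(scan)) {
    enrichment <- on_fail("enrichment", {
      eqtm_cpgs <- unique(scan$cis_significant$cpg_id)
      ctx <- if (length(eqtm_cpgs) > 0)
        context_enrichment(eqtm_cpgs, cohort$cpg_annotation) else NULL
      # pack-year EWAS on the residualized methylation flags smoking CpGs
      py_p <- stats::setNames(rep(NA_real_, ncol(meth_res)),
                              colnames(meth_res))
      for (j in seq_len(ncol(meth_res))) {
        fit <- pair_ols(cohort$packyears, meth_res[, j])
        py_p[j] <- fit$p
      }
      smoking_cpgs <- names(py_p)[py_p < th$smoking_alpha]
      ov <- if (length(smoking_cpgs) > 0 && length(eqtm_cpgs) > 0)
        overlap_test(smoking_cpgs, eqtm_cpgs, cohort$cpg_annotation$cpg_id)
      else NULL
      list(context = ctx, smoking_cpgs = smoking_cpgs, overlap = ov)
    })
  }
  manifest <- list(
    seeds = list(master = config$sim$seed),
    thresholds = th,
    conditional_mode = config$conditional_mode,
    sizes = list(n_samples = config$sim$n_samples,
                 n_snps = config$sim$n_snps, n_cpgs = config$sim$n_cpgs,
                 n_transcripts = config$sim$n_transcripts),
    rows = list(
      scan = if (!is.null(scan)) nrow(scan$results) else 0L,
      cis_significant = if (!is.null(scan)) nrow(scan$cis_significant) else 0L,
      nonredundant = if (!is.null(nonred)) nrow(nonred) else 0L,
      coloc = if (!is.null(coloc)) nrow(coloc) else 0L,
      mr = if (!is.null(mr)) nrow(mr) else 0L))
  run <- structure(list(cohort = cohort, methylation_residuals = meth_res,
                        expression_residuals = expr_res, scan = scan,
                        conditional = conditional, coloc = coloc, mr = mr,
                        enrichment = enrichment, manifest = manifest),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_pipeline_outputs(run, out_dir)
  run
}

# write stage TSVs and the YAML manifest under out_dir
write_pipeline_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_omics_matrix(run$cohort$methylation,
                     file.path(out_dir, "methylation.tsv.gz"))
  write_omics_matrix(run$cohort$expression,
                     file.path(out_dir, "expression.tsv.gz"))
  write_omics_matrix(run$cohort$genotypes,
                     file.path(out_dir, "genotypes.tsv.gz"))
  write_annotation_bed(run$cohort$cpg_annotation,
                       file.path(out_dir, "cpgs.bed"))
  write_annotation_bed(run$cohort$transcript_annotation,
                       file.path(out_dir, "transcripts.bed"))
  if (!is.null(run$scan))
    utils::write.table(run$scan$results, file.path(out_dir, "scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$conditional))
    utils::write.table(run$conditional$results,
                       file.path(out_dir, "conditional.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$coloc))
    utils::write.table(run$coloc, file.path(out_dir, "coloc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$mr))
    utils::write.table(run$mr, file.path(out_dir, "mr.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(run$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
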
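# Shared simulation fixtures, built in code at test time.

# small cohort with one strong cis eQTM chain, for module-level tests
small_cohort <- function(n = 400, seed = 11) {
  cfg <- sim_config(n_samples = n, n_snps = 60, n_cpgs = 40,
                    n_transcripts = 12, ld_block_size = 5, ld_rho = 0.8,
                    genome_length_bp = 2e6, seed = seed)
  ann <- simulate_covariates(cfg)
  arch <- random_architecture(ann$cpg_annotation, ann$transcript_annotation,
                              simulate_genotypes(cfg)$snp_annotation,
                              n_eqtm = 6, n_shared = 2, n_distinct = 2,
                              n_smoking = 3, seed = seed)
  simulate_cohort(cfg, arch)
}

# single-region cohort for colocalization scenarios: one CpG, one
# transcript, 30 SNPs in LD blocks; scenario "h4" = one shared causal SNP,
# "h3" = two causal SNPs in different (unlinked) blocks, "null" = none
simulate_coloc_region <- function(n = 2000, scenario = c("h4", "h3", "null"),
                                  seed = 1, mqtl_beta = 0.8,
                                  eqtl_beta = 0.6) {
  scenario <- match.arg(scenario)
  cfg <- sim_config(n_samples = n, n_snps = 30, n_cpgs = 1,
                    n_transcripts = 1, ld_block_size = 5, ld_rho = 0.8,
                    genome_length_bp = 2e6, seed = seed)
  geno <- simulate_genotypes(cfg)
  cov <- simulate_covariates(cfg)
  mqtl <- eqtl <- NULL
  if (scenario == "h4") {
    mqtl <- data.frame(snp_id = "rs00008", cpg_id = "cg000001",
                       beta = mqtl_beta)
    eqtl <- data.frame(snp_id = "rs00008", transcript_id = "tx0001",
                       beta = eqtl_beta)
  } else if (scenario == "h3") {
    mqtl <- data.frame(snp_id = "rs00003", cpg_id = "cg000001",
                       beta = mqtl_beta)
    eqtl <- data.frame(snp_id = "rs00023", transcript_id = "tx0001",
                       beta = eqtl_beta)
  }
  arch <- causal_architecture(mqtl_effects = mqtl, eqtl_effects = eqtl,
                              noise_sd_methylation = 0.4,
                              noise_sd_expression = 1)
  meth <- simulate_methylation(geno$genotypes, cov$covariates,
                               cov$packyears, arch, seed + 7000L,
                               "cg000001")
  expr <- simulate_expression(meth, geno$genotypes, arch, seed + 8000L,
                              "tx0001")
  mq <- emit_summary_stats(geno$genotypes, meth[, 1], "quantitative",
                           geno$snp_annotation)
  eq <- emit_summary_stats(geno$genotypes, expr[, 1], "quantitative",
                           geno$snp_annotation)
  list(mqtl = mq, eqtl = eq, snp_annotation = geno$snp_annotation)
}

# two-sample MR chain: independent SNPs -> exposure in sample A,
# exposure -> outcome (true effect theta) in an independent sample B
two_sample_mr_sim <- function(theta, n = 5000, m = 5, gamma = 0.2,
                              seed = 1) {
  cfg_a <- sim_config(n_samples = n, n_snps = m, n_cpgs = 1,
                      n_transcripts = 1, maf_range = c(0.3, 0.3),
                      ld_block_size = 1L, ld_rho = 0, seed = seed)
  cfg_b <- cfg_a; cfg_b$seed <- seed + 500000L
  ga <- simulate_genotypes(cfg_a)
  gb <- simulate_genotypes(cfg_b)
  set.seed(seed + 900000L)
  xa <- as.vector(ga$genotypes %*% rep(gamma, m)) + rnorm(n)
  xb <- as.vector(gb$genotypes %*% rep(gamma, m)) + rnorm(n)
  yb <- theta * xb + rnorm(n)
  # both samples genotype the same variants: share one annotation
  exp_ss <- emit_summary_stats(ga$genotypes, xa, "quantitative",
                               ga$snp_annotation)
  out_ss <- emit_summary_stats(gb$genotypes, yb, "quantitative",
                               ga$snp_annotation)
  harmonize_instruments(exp_ss, out_ss)
}

# directional chain for bidirectional MR: instrument set G1 drives the CpG,
# a disjoint set G2 drives pack-years directly; `direction` picks which
# causal path between CpG and pack-years is real
bidirectional_sim <- function(direction = c("cpg_to_smoking",
                                            "smoking_to_cpg", "none"),
                              effect = 0.5, n = 4000, m = 4,
                              gamma = 0.25, seed = 1) {
  direction <- match.arg(direction)
  cfg_a <- sim_config(n_samples = n, n_snps = 2 * m, n_cpgs = 1,
                      n_transcripts = 1, maf_range = c(0.3, 0.3),
                      ld_block_size = 1L, ld_rho = 0, seed = seed)
  cfg_b <- cfg_a; cfg_b$seed <- seed + 500000L
  ga <- simulate_genotypes(cfg_a)$genotypes
  ann <- simulate_genotypes(cfg_a)$snp_annotation
  gb <- simulate_genotypes(cfg_b)$genotypes
  g1 <- 1:m; g2 <- (m + 1):(2 * m)
  set.seed(seed + 900000L)
  draw <- function(G) {
    e_cpg <- rnorm(nrow(G)); e_py <- rnorm(nrow(G))
    base_cpg <- as.vector(G[, g1] %*% rep(gamma, m))
    base_py <- as.vector(G[, g2] %*% rep(gamma, m))
    if (direction == "cpg_to_smoking") {
      cpg <- base_cpg + e_cpg
      py <- base_py + effect * cpg + e_py
    } else if (direction == "smoking_to_cpg") {
      py <- base_py + e_py
      cpg <- base_cpg + effect * py + e_cpg
    } else {
      cpg <- base_cpg + e_cpg
      py <- base_py + e_py
    }
    list(cpg = cpg, py = py)
  }
  ta <- draw(ga); tb <- draw(gb)
  # forward: mQTL instruments (G1) on CpG (sample A), outcome pack-years
  # (sample B); reverse: pack-year GWAS instruments (G2), outcome CpG
  cpg_a <- emit_summary_stats(ga, ta$cpg, "quantitative", ann)
  py_b <- emit_summary_stats(gb, tb$py, "quantitative", ann)
  py_a <- emit_summary_stats(ga, ta$py, "quantitative", ann)
  cpg_b <- emit_summary_stats(gb, tb$cpg, "quantitative", ann)
  fwd <- harmonize_instruments(cpg_a[g1, ], py_b[g1, ])
  rev <- harmonize_instruments(py_a[g2, ], cpg_b[g2, ])
  list(forward = fwd, reverse = rev)
}

# per-study meta-analysis draws under selective storage: effects stored
# only when their p-value beats the storage threshold
censored_studies_sim <- function(theta, se = rep(0.1, 5), censor_p = 1e-4,
                                 seed = 1) {
  set.seed(seed)
  beta <- rnorm(length(se), theta, se)
  p <- 2 * pnorm(-abs(beta / se))
  reported <- p < censor_p
  data.frame(study_id = paste0("st", seq_along(se)),
             beta = ifelse(reported, beta, NA), se = se,
             reported = reported, censor_p = censor_p)
}
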
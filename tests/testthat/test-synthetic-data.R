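test_that("genotype generator respects MAF, LD structure and determinism", {
  cfg <- sim_config(n_samples = 10000, n_snps = 20, n_cpgs = 2,
                    n_transcripts = 2, maf_range = c(0.3, 0.3),
                    ld_block_size = 5, ld_rho = 0, seed = 42)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$genotypes %in% 0:2))
  expect_false(is.unsorted(g$snp_annotation$pos))
  # pooled allele frequency within the binomial sampling bound
  af <- mean(g$genotypes) / 2
  expect_lt(abs(af - 0.3), 3 * sqrt(0.3 * 0.7 / (2 * 10000)))
  # independence case: between-SNP correlations near zero
  cc <- cor(g$genotypes)
  expect_lt(max(abs(cc[upper.tri(cc)])), 3 / sqrt(10000))

  cfg2 <- sim_config(n_samples = 2000, n_snps = 30, n_cpgs = 2,
                     n_transcripts = 2, ld_block_size = 5, ld_rho = 0.9,
                     seed = 42)
  g2 <- simulate_genotypes(cfg2)$genotypes
  r2 <- cor(g2)^2
  block <- (seq_len(30) - 1) %/% 5
  same <- outer(block, block, "==") & upper.tri(r2)
  diff <- !outer(block, block, "==") & upper.tri(r2)
  expect_gt(mean(r2[same]), mean(r2[diff]))

  # identical config and seed reproduce byte-identical output
  expect_identical(simulate_genotypes(cfg2), simulate_genotypes(cfg2))
  expect_error(sim_config(0, 1, 1, 1), "configuration error")
})

test_that("methylation generator injects mQTL and smoking effects on the logit scale", {
  cfg <- sim_config(n_samples = 2000, n_snps = 10, n_cpgs = 3,
                    n_transcripts = 2, ld_block_size = 1, ld_rho = 0,
                    seed = 5)
  g <- simulate_genotypes(cfg)
  cov <- simulate_covariates(cfg)
  cpgs <- c("cg1", "cg2", "cg3")
  # deterministic limit: zero effects, tiny noise -> logistic of baseline
  arch0 <- causal_architecture(noise_sd_methylation = 1e-12,
                               mu_methylation = c(cg1 = -1, cg2 = 0, cg3 = 2))
  m0 <- simulate_methylation(g$genotypes, cov$covariates, cov$packyears,
                             arch0, 1, cpgs)
  expect_equal(unname(m0[1, ]), plogis(c(-1, 0, 2)), tolerance = 1e-6)
  expect_true(all(m0 > 0 & m0 < 1))

  # parameter recovery: OLS of logit(beta) on dosage within +-3 se
  arch <- causal_architecture(
    mqtl_effects = data.frame(snp_id = "rs00004", cpg_id = "cg2", beta = 0.8),
    smoking_effects = data.frame(cpg_id = "cg3", beta = -0.02),
    noise_sd_methylation = 0.3,
    mu_methylation = c(cg1 = 0, cg2 = 0, cg3 = 0))
  m <- simulate_methylation(g$genotypes, cov$covariates, cov$packyears,
                            arch, 2, cpgs)
  fit <- summary(lm(qlogis(m[, "cg2"]) ~ g$genotypes[, "rs00004"]))$coefficients
  expect_lt(abs(fit[2, 1] - 0.8), 3 * fit[2, 2])
  # smoking lowers methylation for heavy smokers (injected sign)
  heavy <- cov$packyears >= 30
  expect_lt(mean(m[heavy, "cg3"]), mean(m[cov$packyears == 0, "cg3"]))
  expect_error(
    simulate_methylation(g$genotypes, cov$covariates, cov$packyears,
                         causal_architecture(mqtl_effects = data.frame(
                           snp_id = "nope", cpg_id = "cg1", beta = 1)),
                         1, cpgs),
    "unknown snp_id")
})

test_that("expression generator honors the eQTM identity chain and signs", {
  cfg <- sim_config(n_samples = 2000, n_snps = 4, n_cpgs = 2,
                    n_transcripts = 2, seed = 9)
  g <- simulate_genotypes(cfg)
  cov <- simulate_covariates(cfg)
  arch <- causal_architecture(
    eqtm_effects = data.frame(cpg_id = "cg1", transcript_id = "t1",
                              beta = 1, sign = "+"),
    noise_sd_methylation = 0.4, noise_sd_expression = 1e-12)
  m <- simulate_methylation(g$genotypes, cov$covariates, cov$packyears,
                            arch, 3, c("cg1", "cg2"))
  e <- simulate_expression(m, g$genotypes, arch, 4, c("t1", "t2"))
  # identity chain: expression minus intercept equals the beta value
  expect_equal(unname(e[, "t1"] - attr(e, "alpha")["t1"]),
               unname(m[, "cg1"]), tolerance = 1e-6)

  archn <- causal_architecture(
    eqtm_effects = data.frame(cpg_id = "cg1", transcript_id = "t1",
                              beta = 5, sign = "-"),
    noise_sd_methylation = 0.4, noise_sd_expression = 0.5)
  en <- simulate_expression(m, g$genotypes, archn, 4, c("t1", "t2"))
  expect_lt(cor(m[, "cg1"], en[, "t1"]), 0)
})

test_that("outcome generator hits the target prevalence and recovers effects", {
  cfg <- sim_config(n_samples = 10000, n_snps = 2, n_cpgs = 1,
                    n_transcripts = 1, seed = 21)
  g <- simulate_genotypes(cfg)
  cov <- simulate_covariates(cfg)
  arch0 <- causal_architecture()
  m <- simulate_methylation(g$genotypes, cov$covariates, cov$packyears,
                            arch0, 1, "cg1")
  e <- simulate_expression(m, g$genotypes, arch0, 2, "t1")
  y0 <- simulate_outcome(e, m, cov$packyears, arch0, 3, prevalence = 0.2)
  expect_lt(abs(mean(y0) - 0.2), 3 * sqrt(0.2 * 0.8 / 10000))

  arch <- causal_architecture(outcome_effects = data.frame(source = "t1",
                                                           beta = 0.5))
  y <- simulate_outcome(e, m, cov$packyears, arch, 4, prevalence = 0.3)
  fit <- summary(glm(y ~ e[, "t1"], family = binomial()))$coefficients
  expect_lt(abs(fit[2, 1] - 0.5), 3 * fit[2, 2])
  expect_error(simulate_outcome(e, m, cov$packyears, arch, 1, prevalence = 1.2),
               "configuration error")
})

test_that("summary statistics match a per-SNP regression oracle and calibrate under the null", {
  cfg <- sim_config(n_samples = 800, n_snps = 1000, n_cpgs = 1,
                    n_transcripts = 1, ld_block_size = 1, ld_rho = 0,
                    seed = 33)
  g <- simulate_genotypes(cfg)
  set.seed(1)
  trait <- rnorm(800)
  ss <- emit_summary_stats(g$genotypes, trait, "quantitative",
                           g$snp_annotation)
  # brute-force OLS oracle on a handful of SNPs
  for (j in c(1, 50, 999)) {
    o <- oracle_ols(g$genotypes[, j, drop = FALSE], trait)[2, ]
    expect_equal(ss$beta[j], o$beta, tolerance = 1e-8)
    expect_equal(ss$se[j], o$se, tolerance = 1e-8)
    expect_equal(ss$p[j], o$p, tolerance = 1e-8)
  }
  # null calibration across 1000 SNPs
  expect_lt(abs(mean(ss$p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))

  # exact linear relation
  g2 <- g$genotypes[, 1:3]
  ss2 <- emit_summary_stats(g2, 2 * g2[, 2], "quantitative")
  expect_equal(ss2$beta[2], 2, tolerance = 1e-10)
  expect_lt(ss2$p[2], 1e-200)

  # monomorphic SNP flagged, not dropped
  g3 <- g2; g3[, 1] <- 1
  ss3 <- emit_summary_stats(omics_matrix(g3), trait)
  expect_true(ss3$monomorphic[1])
  expect_true(is.na(ss3$beta[1]))
  expect_equal(nrow(ss3), 3)
})

test_that("a full cohort is internally consistent and reproducible", {
  co <- small_cohort(n = 200, seed = 3)
  expect_true(all(co$methylation > 0 & co$methylation < 1))
  expect_true(all(co$genotypes >= 0 & co$genotypes <= 2))
  expect_false(anyNA(co$expression))
  cells <- as.matrix(co$covariates[, c("cd4t", "cd8t", "nk", "bcell",
                                       "mono", "gran")])
  expect_true(all(cells >= 0 & cells <= 1))
  expect_true(all(rowSums(cells) <= 1))
  expect_true(all(co$packyears[co$smoking_status == "never"] == 0))
  # byte-identical after serialization
  co2 <- small_cohort(n = 200, seed = 3)
  expect_identical(serialize(co, NULL), serialize(co2, NULL))
})
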
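fake_ss <- function(snp, pos, beta, se, ea = "A", oa = "G", eaf = 0.3,
                    p = NULL) {
  data.frame(snp = snp, chr = "chr1", pos = pos, effect_allele = ea,
             other_allele = oa, eaf = eaf, beta = beta, se = se,
             p = if (is.null(p)) 2 * pnorm(-abs(beta / se)) else p,
             n = 1000, monomorphic = FALSE, stringsAsFactors = FALSE)
}

test_that("region intersection applies a closed 1-Mb window and harmonizes alleles", {
  m <- fake_ss(c("s1", "s2", "s3"), c(1e6, 2e6, 2000001), c(0.5, 0.3, 0.2),
               0.05)
  e <- fake_ss(c("s1", "s2", "s3"), c(1e6, 2e6, 2000001), c(0.4, 0.2, 0.1),
               0.05)
  r <- intersect_region(m, e, center_pos = 1e6, window = 1e6)
  # boundary SNP at center + 1,000,000 exactly is included
  expect_setequal(r$snp, c("s1", "s2"))
  # swapped alleles flip the effect sign, then results match the unswapped run
  e2 <- e
  e2$effect_allele <- "G"; e2$other_allele <- "A"; e2$beta <- -e2$beta
  e2$eaf <- 1 - e2$eaf
  r2 <- intersect_region(m, e2, 1e6, 1e6)
  expect_equal(r2$beta_e, r$beta_e, tolerance = 1e-12)
  # disjoint SNP sets: explicit empty-region signal, and coloc refuses
  e3 <- fake_ss("zz", 1e6, 0.1, 0.05)
  r3 <- intersect_region(m, e3, 1e6, 1e6)
  expect_true(r3$empty)
  expect_error(colocalize(r3), "empty region")
})

test_that("log approximate Bayes factors behave at the limits and match quadrature", {
  # null z: negative evidence
  expect_lt(log_abf(0, 0.1, 0.15), 0)
  expect_equal(log_abf(0, 0.1, 0.15),
               0.5 * log(1 - 0.15^2 / (0.15^2 + 0.1^2)))
  # degenerate prior: no evidence either way
  expect_equal(log_abf(0.5, 0.1, 1e-8), 0, tolerance = 1e-6)
  # quadrature oracle at z = 5
  got <- exp(log_abf(0.5, 0.1, 0.15))
  expect_equal(got, oracle_abf_quadrature(0.5, 0.1, 0.15), tolerance = 0.02)
  expect_error(log_abf(0.1, 0, 0.15), "positive")
})

test_that("posteriors match brute-force configuration enumeration on small regions", {
  set.seed(99)
  pri <- coloc_priors()
  for (k in 2:5) {
    for (rep in 1:10) {
      bm <- rnorm(k, 0, 0.3); be <- rnorm(k, 0, 0.3)
      sem <- runif(k, 0.02, 0.2); see <- runif(k, 0.02, 0.2)
      region <- structure(list(beta_m = bm, se_m = sem, beta_e = be,
                               se_e = see, empty = FALSE),
                          class = "region_stats")
      got <- colocalize(region, pri)
      o <- oracle_coloc_enumeration(log_abf(bm, sem, 0.15),
                                    log_abf(be, see, 0.15),
                                    pri$p1, pri$p2, pri$p12)
      expect_equal(as.numeric(got[1, paste0("pp", 0:4)]), unname(o),
                   tolerance = 1e-10)
      expect_equal(sum(got[1, paste0("pp", 0:4)]), 1, tolerance = 1e-10)
    }
  }
})

test_that("colocalization honors single-SNP, null and symmetry properties", {
  pri <- coloc_priors()
  one <- colocalize(structure(list(beta_m = 0.5, se_m = 0.02, beta_e = 0.4,
                                   se_e = 0.02, empty = FALSE),
                              class = "region_stats"), pri)
  expect_identical(one$pp3, 0)
  expect_true(one$single_snp)
  expect_gt(one$pp4, 0.5)
  # global null: three SNPs, no signal
  null <- colocalize(structure(list(beta_m = rep(0, 3), se_m = rep(0.1, 3),
                                    beta_e = rep(0, 3), se_e = rep(0.1, 3),
                                    empty = FALSE), class = "region_stats"),
                     pri)
  expect_gt(null$pp0, 0.99)
  # label symmetry: swapping traits swaps pp1 and pp2 (p1 = p2 here)
  set.seed(3)
  bm <- rnorm(4, 0, 0.2); be <- rnorm(4, 0, 0.1)
  reg <- function(a, sa, b, sb) structure(
    list(beta_m = a, se_m = sa, beta_e = b, se_e = sb, empty = FALSE),
    class = "region_stats")
  fwd <- colocalize(reg(bm, rep(0.05, 4), be, rep(0.07, 4)), pri)
  swp <- colocalize(reg(be, rep(0.07, 4), bm, rep(0.05, 4)), pri)
  expect_equal(fwd$pp1, swp$pp2, tolerance = 1e-12)
  expect_equal(fwd$pp2, swp$pp1, tolerance = 1e-12)
  expect_equal(fwd$pp0, swp$pp0, tolerance = 1e-12)
  expect_equal(fwd$pp3, swp$pp3, tolerance = 1e-12)
  expect_equal(fwd$pp4, swp$pp4, tolerance = 1e-12)
  # raising p12 never lowers pp4
  pp4s <- vapply(c(1e-6, 1e-5, 1e-4), function(p12)
    colocalize(reg(bm, rep(0.05, 4), be, rep(0.07, 4)),
               coloc_priors(p12 = p12))$pp4, numeric(1))
  expect_true(all(diff(pp4s) >= 0))
  expect_error(coloc_priors(p1 = 0.5, p2 = 0.5, p12 = 0.5), "< 1")
})

test_that("screening requires a shared FDR-significant SNP in both stores", {
  m_sig <- fake_ss(c("s1", "s2"), c(1e6, 1.1e6), c(0.8, 0.02),
                   c(0.05, 0.05))
  e_sig <- fake_ss(c("s1", "s2"), c(1e6, 1.1e6), c(0.6, 0.01),
                   c(0.05, 0.05))
  e_null <- fake_ss(c("s1", "s2"), c(1e6, 1.1e6), c(0.001, 0.002),
                    c(0.05, 0.05))
  pairs <- data.frame(cpg_id = c("cg1", "cg1"),
                      transcript_id = c("txA", "txB"))
  out <- coloc_screen(pairs, list(cg1 = m_sig),
                      list(txA = e_sig, txB = e_null))
  expect_equal(out$status, c("ok", "no_shared_snp"))
  expect_true(is.na(out$pp4[2]))
  expect_gt(out$pp4[1], 0.5)
})

test_that("end-to-end shared-variant and distinct-variant regions are discriminated", {
  h4 <- simulate_coloc_region(n = 2000, scenario = "h4", seed = 77)
  r4 <- intersect_region(h4$mqtl, h4$eqtl, center_pos = 1e6, window = 2e6)
  c4 <- colocalize(r4)
  expect_gt(c4$pp4, 0.8)
  h3 <- simulate_coloc_region(n = 2000, scenario = "h3", seed = 78)
  r3 <- intersect_region(h3$mqtl, h3$eqtl, center_pos = 1e6, window = 2e6)
  c3 <- colocalize(r3)
  expect_gt(c3$pp3, c3$pp4)
})
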
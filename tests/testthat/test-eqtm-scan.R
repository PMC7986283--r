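toy_annotations <- function() {
  list(cpgs = data.frame(cpg_id = c("c1", "c2", "c3", "c4"),
                         chrom = c("chr1", "chr1", "chr1", "chr2"),
                         pos = c(500000L, 1200000L, 2000001L, 1200000L)),
       tx = data.frame(transcript_id = "t1", chrom = "chr1",
                       tss = 1000000L, tes = 1500000L, strand = "+"))
}

test_that("cis/trans classification uses a closed 500-kb window and correct distances", {
  a <- toy_annotations()
  pairs <- define_pairs(a$cpgs, a$tx, cis_window = 500000)
  p <- function(cpg) pairs[pairs$cpg_id == cpg, ]
  # tss - 500000 exactly: cis (closed interval)
  expect_true(p("c1")$cis)
  expect_equal(p("c1")$distance_bp, 500000L)
  # inside the gene body: distance zero
  expect_true(p("c2")$cis)
  expect_equal(p("c2")$distance_bp, 0L)
  # tes + 500001: trans with that exact distance
  expect_false(p("c3")$cis)
  expect_equal(p("c3")$distance_bp, 500001L)
  # other chromosome: trans, distance undefined
  expect_false(p("c4")$cis)
  expect_true(is.na(p("c4")$distance_bp))
  # strand normalization: swapped tss/tes classify identically
  tx_m <- transform(a$tx, tss = 1500000L, tes = 1000000L, strand = "-")
  expect_equal(define_pairs(a$cpgs, tx_m)$cis, pairs$cis)
  bad <- a$cpgs; bad$chrom[1] <- "chrX"
  expect_error(define_pairs(bad, a$tx, known_chroms = c("chr1", "chr2")),
               "chrX")
})

test_that("per-pair OLS matches the normal-equations oracle on random instances", {
  set.seed(42)
  n <- 50
  for (i in 1:20) {
    x <- rnorm(n); y <- 0.3 * x + rnorm(n)
    M <- omics_matrix(cbind(c1 = x), paste0("s", 1:n), "c1")
    E <- omics_matrix(cbind(t1 = y), paste0("s", 1:n), "t1")
    got <- test_pair(M, E, list(cpg_id = "c1", transcript_id = "t1"))
    o <- oracle_ols(cbind(x = x), y)[2, ]
    expect_equal(got$beta, o$beta, tolerance = 1e-10)
    expect_equal(got$se, o$se, tolerance = 1e-10)
    expect_equal(got$p, o$p, tolerance = 1e-10)
    expect_equal(got$t, got$beta / got$se, tolerance = 1e-10)
    expect_equal(got$r_squared, got$t^2 / (got$t^2 + n - 2),
                 tolerance = 1e-12)
  }
  # identity pair: slope one, r-squared one, underflow-safe p
  z <- rnorm(n)
  M <- omics_matrix(cbind(c1 = z), paste0("s", 1:n), "c1")
  got <- test_pair(M, omics_matrix(cbind(t1 = z), paste0("s", 1:n), "t1"),
                   list(cpg_id = "c1", transcript_id = "t1"))
  expect_equal(got$beta, 1, tolerance = 1e-12)
  expect_equal(got$r_squared, 1, tolerance = 1e-12)
  expect_gt(got$p, 0)
  expect_error(test_pair(M, omics_matrix(cbind(t1 = rep(1, n)),
                                         paste0("s", 1:n), "t1"),
                         list(cpg_id = "c1", transcript_id = "t1")),
               "degenerate")
})

test_that("scan flags significance inclusively and counts directions symmetrically", {
  set.seed(8)
  n <- 100
  M <- omics_matrix(matrix(rnorm(n * 30), n, 30), paste0("s", 1:n),
                    paste0("c", 1:30))
  E <- omics_matrix(matrix(rnorm(n * 30), n, 30), paste0("s", 1:n),
                    paste0("t", 1:30))
  E[, 1] <- 2 * M[, 1] + 0.1 * rnorm(n)
  E[, 2] <- -2 * M[, 2] + 0.1 * rnorm(n)
  pairs <- data.frame(cpg_id = paste0("c", 1:30),
                      transcript_id = paste0("t", 1:30),
                      cis = rep(c(TRUE, FALSE), 15),
                      distance_bp = 1000L)
  sc <- eqtm_scan(M, E, pairs)
  res <- sc$results
  # inclusive threshold: a pair at exactly the cutoff is significant
  i <- which(res$cis)[1]
  res$p[i] <- 1e-8
  expect_true(all(ifelse(res$cis, res$p <= 1e-8, res$p <= 1e-12) ==
                  (res$p <= ifelse(res$cis, 1e-8, 1e-12))))
  expect_equal(sum(sc$results$significant),
               nrow(sc$cis_significant) + nrow(sc$trans_significant))
  expect_equal(sum(sign(sc$cis_significant$beta) > 0) +
               sum(sign(sc$cis_significant$beta) < 0),
               nrow(sc$cis_significant))
  # injected effects with near-unit power are detected
  expect_true("c1" %in% sc$cis_significant$cpg_id)
  expect_true("c2" %in% sc$trans_significant$cpg_id)
  # vectorized path agrees with the scalar path
  one <- test_pair(M, E, list(cpg_id = "c3", transcript_id = "t3"))
  expect_equal(res$beta[3], one$beta, tolerance = 1e-12)
  expect_equal(res$p[3], one$p, tolerance = 1e-12)
})

test_that("scan handles missing values by pairwise-complete deletion", {
  set.seed(11)
  n <- 60
  M <- omics_matrix(matrix(rnorm(n * 2), n, 2), paste0("s", 1:n),
                    c("c1", "c2"))
  E <- omics_matrix(matrix(rnorm(n * 2), n, 2), paste0("s", 1:n),
                    c("t1", "t2"))
  M[1:5, 1] <- NA
  pairs <- data.frame(cpg_id = c("c1", "c2"), transcript_id = c("t1", "t2"),
                      cis = TRUE, distance_bp = 0L)
  sc <- eqtm_scan(M, E, pairs)
  expect_equal(sc$results$n, c(55L, 60L))
  o <- oracle_ols(cbind(x = M[6:60, 1]), E[6:60, 1])[2, ]
  expect_equal(sc$results$beta[1], o$beta, tolerance = 1e-10)
})

test_that("distance-effect summary recovers decay, exact lines and degenerate inputs", {
  # perfect linear case
  r <- distance_effect_summary(data.frame(distance_bp = c(0, 10, 20),
                                          r_squared = c(0.3, 0.2, 0.1)))
  expect_equal(r$pearson_r, -1, tolerance = 1e-12)
  expect_equal(r$median_r_squared, 0.2)
  expect_equal(r$fraction_within_100kb, 1)
  # constant r-squared: flagged NA, not zero
  rc <- distance_effect_summary(data.frame(distance_bp = c(0, 10, 20),
                                           r_squared = rep(0.2, 3)))
  expect_true(rc$degenerate)
  expect_true(is.na(rc$pearson_r))
  # synthetic hyperbolic decay yields a recovered negative correlation
  set.seed(5)
  d <- runif(500, 0, 5e5)
  r2 <- 0.3 / (1 + d / 1e4) + runif(500, 0, 0.02)
  rs <- distance_effect_summary(data.frame(distance_bp = d, r_squared = r2))
  expect_lt(rs$pearson_r, 0)
  expect_lt(rs$p, 0.01)
  expect_error(distance_effect_summary(data.frame(distance_bp = 1,
                                                  r_squared = 0.1)),
               "at least 3")
})
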
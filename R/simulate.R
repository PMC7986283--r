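#' Simulation configuration for a synthetic cohort
#'
#' @param n_samples,n_snps,n_cpgs,n_transcripts positive integers.
#' @param maf_range length-2 numeric in (0, 0.5]; per-SNP minor allele
#'   frequencies are drawn uniformly from this interval.
#' @param ld_block_size SNPs per linkage-disequilibrium block (>= 1).
#' @param ld_rho latent within-block haplotype correlation in \[0, 1).
#' @param genome_length_bp span of the simulated chromosome; feature
#'   positions are uniform on `[1, genome_length_bp]`.
#' @param chrom chromosome label used in all annotation tables.
#' @param seed integer master seed; every data layer derives its own
#'   stream from it, so identical configs reproduce byte-identical cohorts.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_samples, n_snps, n_cpgs, n_transcripts,
                       maf_range = c(0.05, 0.5), ld_block_size = 5L,
                       ld_rho = 0.8, genome_length_bp = 2e6,
                       chrom = "chr1", seed = 1L) {
  for (d in c(n_samples, n_snps, n_cpgs, n_transcripts))
    if (length(d) != 1 || !is.finite(d) || d < 1)
      stop("configuration error: dimensions must be positive integers")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("configuration error: maf_range must be increasing within (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1)
    stop("configuration error: ld_rho must lie in [0, 1)")
  if (ld_block_size < 1)
    stop("configuration error: ld_block_size must be >= 1")
  structure(list(n_samples = as.integer(n_samples),
                 n_snps = as.integer(n_snps),
                 n_cpgs = as.integer(n_cpgs),
                 n_transcripts = as.integer(n_transcripts),
                 maf_range = as.numeric(maf_range),
                 ld_block_size = as.integer(ld_block_size),
                 ld_rho = as.numeric(ld_rho),
                 genome_length_bp = as.numeric(genome_length_bp),
                 chrom = chrom, seed = as.integer(seed)),
            class = "sim_config")
}

# derive a bounded child seed from the master seed; keeps all streams
# distinct across layers while staying within 32-bit integer range
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

#' Simulate LD-blocked genotype dosages
#'
#' Haplotypes are generated from a block-equicorrelated latent Gaussian
#' (shared block factor weight `sqrt(ld_rho)`) thresholded at the allele
#' frequency quantile; the dosage is the sum of two independent haplotypes,
#' so genotypes are in Hardy-Weinberg proportions with controllable
#' within-block correlation and none between blocks.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (samples x SNPs dosage matrix) and
#'   `snp_annotation` (snp_id, chrom, pos, effect_allele, other_allele, maf),
#'   positions sorted ascending.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 101L))
  n <- config$n_samples; p <- config$n_snps
  maf <- stats::runif(p, config$maf_range[1], config$maf_range[2])
  block <- (seq_len(p) - 1L) %/% config$ld_block_size
  nb <- max(block) + 1L
  rho <- config$ld_rho
  hap <- function() {
    shared <- matrix(stats::rnorm(n * nb), n, nb)[, block + 1L, drop = FALSE]
    z <- sqrt(rho) * shared + sqrt(1 - rho) * matrix(stats::rnorm(n * p), n, p)
    # threshold at qnorm(maf): allele carried iff latent below quantile
    sweep(z, 2, stats::qnorm(maf), "<") * 1
  }
  g <- hap() + hap()
  pos <- sort(sample.int(config$genome_length_bp, p))
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, p, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1L), character(1))
  snp_ids <- sprintf("rs%05d", seq_len(p))
  ann <- data.frame(snp_id = snp_ids, chrom = config$chrom, pos = pos,
                    effect_allele = ea, other_allele = unname(oa), maf = maf,
                    stringsAsFactors = FALSE)
  list(genotypes = omics_matrix(g, sprintf("S%04d", seq_len(n)), snp_ids),
       snp_annotation = ann)
}

#' Simulate covariates, smoking exposure and feature annotations
#'
#' Covariates emulate a whole-blood cohort: age, sex, six leukocyte
#' proportions summing to at most one, and a two-level technical batch.
#' Smoking status is never/former/current with pack-years zero for never
#' smokers and gamma-distributed otherwise.
#'
#' @param config a [sim_config()].
#' @return list with `covariates` (data.frame), `smoking_status`,
#'   `packyears`, `cpg_annotation`, `transcript_annotation`.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 202L))
  n <- config$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))
  cells_raw <- matrix(stats::rgamma(n * 6, shape = c(12, 4, 3, 2, 1.5, 1)),
                      n, 6, byrow = TRUE)
  # estimated proportions sum below 1 by a variable margin, as in practice
  cells <- stats::runif(n, 0.85, 0.99) * cells_raw / rowSums(cells_raw)
  colnames(cells) <- c("cd4t", "cd8t", "nk", "bcell", "mono", "gran")
  status <- sample(c("never", "former", "current"), n, replace = TRUE,
                   prob = c(0.45, 0.35, 0.20))
  packyears <- ifelse(status == "never", 0,
                      stats::rgamma(n, shape = 2, scale = 10))
  cov <- data.frame(sample_id = sample_ids,
                    age = stats::rnorm(n, 55, 10),
                    sex = stats::rbinom(n, 1, 0.5),
                    cells,
                    batch = sample(c("b1", "b2"), n, replace = TRUE),
                    stringsAsFactors = FALSE)
  ctx <- sample(c("island", "north_shore", "south_shore", "shelf", "open_sea"),
                config$n_cpgs, replace = TRUE,
                prob = c(0.30, 0.12, 0.12, 0.10, 0.36))
  cpg_ann <- data.frame(
    cpg_id = sprintf("cg%06d", seq_len(config$n_cpgs)),
    chrom = config$chrom,
    pos = sort(sample.int(config$genome_length_bp, config$n_cpgs)),
    island_context = ctx, stringsAsFactors = FALSE)
  tss <- sort(sample.int(max(config$genome_length_bp - 1e5, 1),
                         config$n_transcripts))
  len <- pmax(1e3, stats::rgamma(config$n_transcripts, 2, scale = 1.5e4))
  tx_ann <- data.frame(
    transcript_id = sprintf("tx%04d", seq_len(config$n_transcripts)),
    chrom = config$chrom, tss = tss,
    tes = pmin(tss + round(len), config$genome_length_bp),
    strand = sample(c("+", "-"), config$n_transcripts, replace = TRUE),
    stringsAsFactors = FALSE)
  list(covariates = cov, smoking_status = status, packyears = packyears,
       cpg_annotation = cpg_ann, transcript_annotation = tx_ann)
}

# numeric covariate design used for effect injection (not for residualization)
covariate_numeric <- function(covariates) {
  num <- covariates[, setdiff(names(covariates), c("sample_id", "batch")),
                    drop = FALSE]
  num <- as.matrix(num)
  if ("batch" %in% names(covariates))
    num <- cbind(num, batch = as.numeric(factor(covariates$batch)) - 1)
  num
}

#' Simulate methylation beta values
#'
#' Per CpG, a latent logit-scale value sums baseline, mQTL dosage effects,
#' smoking pack-year effects, covariate effects and Gaussian noise; the
#' reported beta value is its logistic transform, so methylation stays in
#' (0, 1).
#'
#' @param genotypes dosage omics matrix.
#' @param covariates covariate data.frame (see [simulate_covariates()]).
#' @param packyears per-sample pack-years vector.
#' @param architecture a [causal_architecture()].
#' @param seed integer seed for baselines and noise.
#' @param cpg_ids feature ids of the CpGs to simulate.
#' @return methylation omics matrix with attribute `mu` (per-CpG logit
#'   baselines used).
#' @export
simulate_methylation <- function(genotypes, covariates, packyears,
                                 architecture, seed, cpg_ids) {
  set.seed(seed)
  n <- nrow(genotypes)
  p <- length(cpg_ids)
  mu <- stats::runif(p, -2, 2)
  names(mu) <- cpg_ids
  if (!is.null(architecture$mu_methylation)) {
    given <- architecture$mu_methylation
    mu[names(given)] <- given
  }
  latent <- matrix(mu, n, p, byrow = TRUE, dimnames = list(rownames(genotypes), cpg_ids))
  mq <- architecture$mqtl_effects
  if (!is.null(mq) && nrow(mq) > 0) {
    check_arch_ids(mq$snp_id, colnames(genotypes), "snp_id")
    check_arch_ids(mq$cpg_id, cpg_ids, "cpg_id")
    for (i in seq_len(nrow(mq)))
      latent[, mq$cpg_id[i]] <- latent[, mq$cpg_id[i]] +
        mq$beta[i] * genotypes[, mq$snp_id[i]]
  }
  sm <- architecture$smoking_effects
  if (!is.null(sm) && nrow(sm) > 0) {
    check_arch_ids(sm$cpg_id, cpg_ids, "cpg_id")
    for (i in seq_len(nrow(sm)))
      latent[, sm$cpg_id[i]] <- latent[, sm$cpg_id[i]] + sm$beta[i] * packyears
  }
  ce <- architecture$covariate_effects_methylation
  if (!is.null(ce) && nrow(ce) > 0) {
    num <- covariate_numeric(covariates)
    check_arch_ids(ce$covariate, colnames(num), "covariate")
    check_arch_ids(ce$feature_id, cpg_ids, "cpg_id")
    for (i in seq_len(nrow(ce)))
      latent[, ce$feature_id[i]] <- latent[, ce$feature_id[i]] +
        ce$beta[i] * num[, ce$covariate[i]]
  }
  latent <- latent + matrix(stats::rnorm(n * p, 0, architecture$noise_sd_methylation), n, p)
  beta <- stats::plogis(latent)
  out <- omics_matrix(beta, rownames(genotypes), cpg_ids)
  attr(out, "mu") <- mu
  out
}

#' Simulate expression driven by methylation and genotypes
#'
#' Per transcript, expression is an intercept plus eQTM effects of CpG beta
#' values, eQTL dosage effects, covariate effects and Gaussian noise.
#'
#' @inheritParams simulate_methylation
#' @param methylation methylation omics matrix (beta values).
#' @param transcript_ids feature ids of the transcripts to simulate.
#' @return expression omics matrix with attribute `alpha` (intercepts used).
#' @export
simulate_expression <- function(methylation, genotypes, architecture, seed,
                                transcript_ids, covariates = NULL) {
  set.seed(seed)
  check_shared_samples(methylation, genotypes)
  n <- nrow(methylation)
  k <- length(transcript_ids)
  alpha <- stats::setNames(numeric(k), transcript_ids)
  if (!is.null(architecture$alpha_expression)) {
    given <- architecture$alpha_expression
    alpha[names(given)] <- given
  }
  y <- matrix(alpha, n, k, byrow = TRUE,
              dimnames = list(rownames(methylation), transcript_ids))
  eq <- architecture$eqtm_effects
  if (!is.null(eq) && nrow(eq) > 0) {
    check_arch_ids(eq$cpg_id, colnames(methylation), "cpg_id")
    check_arch_ids(eq$transcript_id, transcript_ids, "transcript_id")
    for (i in seq_len(nrow(eq)))
      y[, eq$transcript_id[i]] <- y[, eq$transcript_id[i]] +
        eq$beta[i] * methylation[, eq$cpg_id[i]]
  }
  el <- architecture$eqtl_effects
  if (!is.null(el) && nrow(el) > 0) {
    check_arch_ids(el$snp_id, colnames(genotypes), "snp_id")
    check_arch_ids(el$transcript_id, transcript_ids, "transcript_id")
    for (i in seq_len(nrow(el)))
      y[, el$transcript_id[i]] <- y[, el$transcript_id[i]] +
        el$beta[i] * genotypes[, el$snp_id[i]]
  }
  ce <- architecture$covariate_effects_expression
  if (!is.null(ce) && nrow(ce) > 0) {
    if (is.null(covariates))
      stop("covariates required when the architecture injects covariate effects")
    num <- covariate_numeric(covariates)
    check_arch_ids(ce$covariate, colnames(num), "covariate")
    check_arch_ids(ce$feature_id, transcript_ids, "transcript_id")
    for (i in seq_len(nrow(ce)))
      y[, ce$feature_id[i]] <- y[, ce$feature_id[i]] +
        ce$beta[i] * num[, ce$covariate[i]]
  }
  y <- y + matrix(stats::rnorm(n * k, 0, architecture$noise_sd_expression), n, k)
  out <- omics_matrix(y, rownames(methylation), transcript_ids)
  attr(out, "alpha") <- alpha
  out
}

#' Simulate a binary disease outcome on the liability (logistic) scale
#'
#' The linear predictor sums the architecture's outcome effects (expression,
#' methylation, or pack-years sources); the intercept is solved numerically
#' so the expected prevalence matches the target.
#'
#' @inheritParams simulate_methylation
#' @param expression expression omics matrix.
#' @param methylation methylation omics matrix.
#' @param prevalence target expected case fraction in (0, 1).
#' @return integer 0/1 vector with attribute `intercept`.
#' @export
simulate_outcome <- function(expression, methylation, packyears, architecture,
                             seed, prevalence = 0.2) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("configuration error: prevalence must lie in (0, 1)")
  set.seed(seed)
  n <- nrow(expression)
  lp <- numeric(n)
  oe <- architecture$outcome_effects
  if (!is.null(oe) && nrow(oe) > 0) {
    for (i in seq_len(nrow(oe))) {
      src <- oe$source[i]
      x <- if (src == "packyears") packyears
           else if (src %in% colnames(expression)) expression[, src]
           else if (src %in% colnames(methylation)) methylation[, src]
           else stop("unknown outcome effect source: ", src)
      lp <- lp + oe$beta[i] * x
    }
  }
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + lp)) - prevalence,
                       c(-50, 50))$root
  y <- stats::rbinom(n, 1, stats::plogis(b0 + lp))
  attr(y, "intercept") <- b0
  y
}

#' Compute GWAS-style marginal summary statistics for one trait
#'
#' Each SNP is tested marginally against the trait: ordinary least squares
#' for quantitative traits (vectorized closed form) or logistic regression
#' for binary traits. Monomorphic SNPs are kept with missing beta/se and a
#' `monomorphic` flag rather than dropped.
#'
#' @param genotypes dosage omics matrix.
#' @param trait numeric (quantitative) or 0/1 (binary) vector aligned with
#'   the sample axis.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param snp_annotation optional annotation supplying chr/pos/alleles.
#' @return data.frame with columns snp, chr, pos, effect_allele,
#'   other_allele, eaf, beta, se, p, n, monomorphic.
#' @export
emit_summary_stats <- function(genotypes, trait,
                               trait_type = c("quantitative", "binary"),
                               snp_annotation = NULL) {
  trait_type <- match.arg(trait_type)
  if (length(trait) != nrow(genotypes))
    stop("trait length does not match the sample axis")
  n <- nrow(genotypes); p <- ncol(genotypes)
  eaf <- colMeans(genotypes) / 2
  mono <- apply(genotypes, 2, stats::var) == 0
  beta <- se <- pv <- rep(NA_real_, p)
  if (trait_type == "quantitative") {
    y <- trait - mean(trait)
    xc <- sweep(genotypes, 2, colMeans(genotypes))
    sxx <- colSums(xc^2)
    sxy <- as.vector(crossprod(xc, y))
    ok <- !mono
    beta[ok] <- sxy[ok] / sxx[ok]
    rss <- sum(y^2) - beta[ok] * sxy[ok]
    se[ok] <- sqrt(pmax(rss, 0) / ((n - 2) * sxx[ok]))
    tt <- beta[ok] / se[ok]
    pv[ok] <- 2 * stats::pt(-abs(tt), n - 2)
  } else {
    if (!all(trait %in% c(0, 1))) stop("binary trait must be 0/1")
    for (j in which(!mono)) {
      fit <- suppressWarnings(
        stats::glm(trait ~ genotypes[, j], family = stats::binomial()))
      cf <- summary(fit)$coefficients
      beta[j] <- cf[2, 1]; se[j] <- cf[2, 2]; pv[j] <- cf[2, 4]
    }
  }
  if (is.null(snp_annotation)) {
    snp_annotation <- data.frame(snp_id = colnames(genotypes),
                                 chrom = NA_character_, pos = NA_integer_,
                                 effect_allele = "A", other_allele = "G",
                                 stringsAsFactors = FALSE)
  }
  idx <- match(colnames(genotypes), snp_annotation$snp_id)
  data.frame(snp = colnames(genotypes),
             chr = snp_annotation$chrom[idx],
             pos = snp_annotation$pos[idx],
             effect_allele = snp_annotation$effect_allele[idx],
             other_allele = snp_annotation$other_allele[idx],
             eaf = eaf, beta = beta, se = se, p = pv, n = n,
             monomorphic = mono, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Simulate a complete cohort from one configuration and architecture
#'
#' Runs every data layer in order, each on its own seed stream derived from
#' the config's master seed. An optional platform effect (per-transcript
#' multiplicative rescaling plus extra noise) emulates a replication cohort
#' measured on a different expression array.
#'
#' @param config a [sim_config()].
#' @param architecture a [causal_architecture()].
#' @param prevalence target outcome prevalence.
#' @param platform_effect if TRUE, rescale each transcript by
#'   `exp(N(0, 0.2))` and add independent noise (sd 0.5).
#' @return list of class `cohort_dataset` with genotypes, methylation,
#'   expression, covariates, smoking_status, packyears, outcome and the
#'   three annotation tables.
#' @export
simulate_cohort <- function(config, architecture, prevalence = 0.2,
                            platform_effect = FALSE) {
  geno <- simulate_genotypes(config)
  cov <- simulate_covariates(config)
  meth <- simulate_methylation(geno$genotypes, cov$covariates, cov$packyears,
                               architecture, child_seed(config$seed, 303L),
                               cov$cpg_annotation$cpg_id)
  expr <- simulate_expression(meth, geno$genotypes, architecture,
                              child_seed(config$seed, 404L),
                              cov$transcript_annotation$transcript_id,
                              cov$covariates)
  if (platform_effect) {
    set.seed(child_seed(config$seed, 505L))
    scale <- exp(stats::rnorm(ncol(expr), 0, 0.2))
    expr <- sweep(expr, 2, scale, "*") +
      matrix(stats::rnorm(length(expr), 0, 0.5), nrow(expr), ncol(expr))
    expr <- omics_matrix(expr)
  }
  outcome <- simulate_outcome(expr, meth, cov$packyears, architecture,
                              child_seed(config$seed, 606L), prevalence)
  structure(list(genotypes = geno$genotypes, methylation = meth,
                 expression = expr, covariates = cov$covariates,
                 smoking_status = cov$smoking_status,
                 packyears = cov$packyears, outcome = outcome,
                 snp_annotation = geno$snp_annotation,
                 cpg_annotation = cov$cpg_annotation,
                 transcript_annotation = cov$transcript_annotation,
                 config = config),
            class = "cohort_dataset")
}
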
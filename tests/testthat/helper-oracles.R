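# Independent oracle implementations used to cross-check the package's
# statistics. These deliberately use different code paths (explicit
# normal equations, enumeration, quadrature) from the implementation.

# simple / multiple OLS via explicit normal equations
oracle_ols <- function(X, y) {
  X <- cbind(`(Intercept)` = 1, X)
  XtX <- t(X) %*% X
  bhat <- solve(XtX, t(X) %*% y)
  res <- y - X %*% bhat
  n <- length(y)
  sigma2 <- sum(res^2) / (n - ncol(X))
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- as.vector(bhat) / se
  p <- 2 * pt(-abs(tval), n - ncol(X))
  data.frame(term = colnames(X), beta = as.vector(bhat), se = se,
             t = tval, p = p, row.names = NULL)
}

# residual projector (I - X (X'X)^-1 X') Y
oracle_projector <- function(X, Y) {
  X <- cbind(1, X)
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  (diag(nrow(X)) - H) %*% Y
}

# five-hypothesis posterior by brute-force enumeration over all causal
# configuration pairs (trait 1 causal SNP or none) x (trait 2 ditto)
oracle_coloc_enumeration <- function(la, lb, p1, p2, p12) {
  k <- length(la)
  # collect the log mass of every causal configuration, by hypothesis
  logs <- list(h0 = 0, h1 = log(p1) + la, h2 = log(p2) + lb,
               h3 = numeric(0), h4 = numeric(0))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) {
      logs$h4 <- c(logs$h4, log(p12) + la[i] + lb[j])
    } else {
      logs$h3 <- c(logs$h3, log(p1) + log(p2) + la[i] + lb[j])
    }
  }
  M <- max(unlist(logs))
  mass <- vapply(logs, function(l) sum(exp(l - M)), numeric(1))
  mass / sum(mass)
}

# Wakefield Bayes factor by numerical integration over the normal prior
oracle_abf_quadrature <- function(beta, se, W) {
  lik <- function(b) dnorm(beta, b, se)
  num <- integrate(function(b) lik(b) * dnorm(b, 0, W), -Inf, Inf)$value
  num / lik(0)
}

# exhaustive greedy LD clumping, re-implemented directly
oracle_greedy_prune <- function(snps, p, r2mat, thr) {
  kept <- character(0)
  alive <- seq_along(snps)
  while (length(alive) > 0) {
    o <- alive[order(p[alive], snps[alive])]
    lead <- o[1]
    kept <- c(kept, snps[lead])
    alive <- setdiff(alive, lead)
    alive <- alive[r2mat[lead, alive] < thr]
  }
  kept
}

# two-sided Fisher exact p by hypergeometric enumeration
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n_ <- c_ + d; k <- a + c_
  xs <- max(0, k - n_):min(k, m)
  probs <- dhyper(xs, m, n_, k)
  obs <- dhyper(a, m, n_, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# textbook 2x2 chi-square without continuity correction
oracle_chi2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# inverse-variance weighted mean
oracle_ivw <- function(beta, se) {
  w <- 1 / se^2
  c(theta = sum(w * beta) / sum(w), se = sqrt(1 / sum(w)))
}

# zero-intercept weighted least squares of outcome on exposure betas
oracle_wls_mr <- function(bx, by, se_out) {
  w <- 1 / se_out^2
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se <- sqrt(1 / sum(w * bx^2))
  c(beta = beta, se = se)
}
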
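#' Fixed-effect inverse-variance-weighted meta-analysis
#'
#' @param effects data.frame of fully reported study effects with columns
#'   `beta` and `se` (and optionally `study_id`).
#' @return one-row data.frame of class `meta_result`: theta, se_theta, tau,
#'   p, n_reported, n_censored, method.
#' @export
ivw_fixed_meta <- function(effects) {
  if (nrow(effects) < 1) stop("need at least one study")
  if (any(!is.finite(effects$se)) || any(effects$se <= 0))
    stop("all standard errors must be positive")
  w <- 1 / effects$se^2
  theta <- sum(w * effects$beta) / sum(w)
  se_theta <- sqrt(1 / sum(w))
  structure(data.frame(theta = theta, se_theta = se_theta, tau = 0,
                       p = 2 * stats::pnorm(-abs(theta / se_theta)),
                       n_reported = nrow(effects), n_censored = 0L,
                       method = "ivw_fixed", converged = TRUE,
                       stringsAsFactors = FALSE),
            class = c("meta_result", "data.frame"))
}

# log-likelihood of (theta, tau2) for a mix of reported and censored studies;
# censored studies contribute P(|beta/se| < z_crit) under N(theta, se^2+tau2)
censored_meta_loglik <- function(theta, tau2, beta, se, reported, zcrit) {
  s <- sqrt(se^2 + tau2)
  ll <- 0
  if (any(reported))
    ll <- ll + sum(stats::dnorm(beta[reported], theta, s[reported], log = TRUE))
  if (any(!reported)) {
    cse <- se[!reported]; cs <- s[!reported]; zc <- zcrit[!reported]
    pr <- stats::pnorm((zc * cse - theta) / cs) -
      stats::pnorm((-zc * cse - theta) / cs)
    ll <- ll + sum(log(pmax(pr, 1e-300)))
  }
  ll
}

#' Censored-likelihood meta-analysis of selectively stored effects
#'
#' Some cohorts store per-pair effects only when the association p-value
#' passes a storage threshold (e.g. p < 1e-4); ignoring the unstored
#' studies biases a complete-case meta-analysis away from zero. This
#' estimator maximizes a proper censored-normal likelihood: reported
#' studies contribute the usual normal density, and each censored study
#' contributes the probability that its z-statistic falls inside the
#' non-stored region `|beta/se| < z_crit(censor_p)` under
#' `N(theta, se^2 + tau^2)`. Censored studies must carry an `se` proxy
#' (e.g. `sd_proxy/sqrt(n)` from the study's reported results). The random
#' model profiles over the between-study variance with the tau = 0
#' boundary handled by comparing against the fixed fit; the fixed model
#' pins tau at 0. The standard error of theta comes from the observed
#' information (numerical second derivative at the maximum).
#'
#' @param effects data.frame with columns `beta`, `se`, `reported`
#'   (logical) and `censor_p` (storage threshold; required where
#'   `reported` is FALSE). `beta` may be NA for censored studies.
#' @param model `"fixed"` (tau = 0) or `"random"`.
#' @return one-row `meta_result` data.frame; `converged` is FALSE with a
#'   diagnostic attribute when the bounded restarts fail.
#' @export
censored_mle_meta <- function(effects, model = c("fixed", "random")) {
  model <- match.arg(model)
  reported <- as.logical(effects$reported)
  if (any(!is.finite(effects$se)) || any(effects$se <= 0))
    stop("all studies (including censored) need a positive se or se proxy")
  if (any(!reported) && (!"censor_p" %in% names(effects) ||
                         any(!is.finite(effects$censor_p[!reported]))))
    stop("censored studies must carry their censor_p storage threshold")
  if (!any(reported) && sum(!reported) < 2)
    stop("need >= 1 reported study or >= 2 censored studies")
  beta <- effects$beta; se <- effects$se
  zcrit <- rep(Inf, nrow(effects))
  if (any(!reported))
    zcrit[!reported] <- stats::qnorm(1 - effects$censor_p[!reported] / 2)
  nll_fixed <- function(th)
    -censored_meta_loglik(th, 0, beta, se, reported, zcrit)
  # bracket wide enough to contain the MLE for any censoring pattern
  spread <- max(se) * (max(zcrit[is.finite(zcrit)], 2) + 6)
  lo <- min(c(beta[reported], 0)) - spread
  hi <- max(c(beta[reported], 0)) + spread
  fit_fixed <- stats::optimize(nll_fixed, c(lo, hi), tol = 1e-10)
  theta <- fit_fixed$minimum; tau2 <- 0
  nll_min <- fit_fixed$objective
  converged <- TRUE
  if (model == "random") {
    nll2 <- function(par)
      -censored_meta_loglik(par[1], exp(par[2]), beta, se, reported, zcrit)
    starts_th <- stats::quantile(c(beta[reported], theta),
                                 c(0.1, 0.5, 0.9), na.rm = TRUE)
    vb <- if (sum(reported) >= 2) stats::var(beta[reported]) else 1e-2
    starts <- expand.grid(th = unique(starts_th),
                          ltau = log(c(1e-4, vb + 1e-4)))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      f <- tryCatch(stats::optim(as.numeric(starts[i, ]), nll2,
                                 method = "Nelder-Mead",
                                 control = list(maxit = 2000, reltol = 1e-12)),
                    error = function(e) NULL)
      if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
    }
    if (is.null(best)) {
      converged <- FALSE
    } else if (best$value < nll_min - 1e-8) {
      # profile comparison against the tau = 0 boundary fit
      theta <- best$par[1]; tau2 <- exp(best$par[2]); nll_min <- best$value
      if (best$convergence != 0) converged <- FALSE
    }
  }
  # observed information for theta at the maximum (tau held at its MLE)
  h <- 1e-4 * max(abs(theta), 1)
  d2 <- (-censored_meta_loglik(theta + h, tau2, beta, se, reported, zcrit) +
         2 * censored_meta_loglik(theta, tau2, beta, se, reported, zcrit) -
         censored_meta_loglik(theta - h, tau2, beta, se, reported, zcrit)) / h^2
  se_theta <- if (d2 > 0) sqrt(1 / d2) else NA_real_
  out <- structure(data.frame(
    theta = theta, se_theta = se_theta, tau = sqrt(tau2),
    p = if (is.na(se_theta)) NA_real_
        else 2 * stats::pnorm(-abs(theta / se_theta)),
    n_reported = sum(reported), n_censored = sum(!reported),
    method = "censored_mle", converged = converged,
    stringsAsFactors = FALSE),
    class = c("meta_result", "data.frame"))
  if (!converged)
    attr(out, "diagnostics") <- "optimizer did not converge within restarts"
  out
}

#' Assess replication of discovery associations in a meta-analyzed cohort set
#'
#' Applies the Bonferroni threshold `0.05 / n_tests` to the replication
#' p-values of discovery-significant pairs and reports the replication rate
#' and the fraction with concordant effect direction.
#'
#' @param discovery AssociationResult table with cpg_id, transcript_id,
#'   beta, p.
#' @param replication table with cpg_id, transcript_id, theta, p (e.g.
#'   stacked [censored_mle_meta()] rows).
#' @param n_tests number of discovery tests defining the Bonferroni
#'   denominator.
#' @return list with `replication_rate`, `sign_concordance`, `n_joined`,
#'   `threshold`.
#' @export
assess_replication <- function(discovery, replication, n_tests) {
  j <- merge(discovery, replication, by = c("cpg_id", "transcript_id"),
             suffixes = c("_disc", "_repl"))
  if (nrow(j) == 0) stop("empty join between discovery and replication tables")
  thr <- 0.05 / n_tests
  p_repl <- if ("p_repl" %in% names(j)) j$p_repl else j$p.y
  beta_disc <- if ("beta" %in% names(j)) j$beta else j$beta_disc
  list(replication_rate = mean(p_repl < thr),
       sign_concordance = mean(sign(beta_disc) == sign(j$theta)),
       n_joined = nrow(j), threshold = thr)
}
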
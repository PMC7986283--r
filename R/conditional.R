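# multiple-regression fit returning stats for each non-intercept column
ols_multi <- function(X, y) {
  q <- qr(cbind(1, X))
  cf <- qr.coef(q, y)
  res <- y - cbind(1, X) %*% cf
  n <- length(y); pterm <- ncol(X) + 1L
  sigma2 <- sum(res^2) / (n - pterm)
  XtXinv <- chol2inv(qr.R(q))
  se <- sqrt(sigma2 * diag(XtXinv))
  tval <- cf / se
  p <- 2 * stats::pt(-abs(tval), n - pterm)
  data.frame(term = c("(Intercept)", colnames(X)),
             beta = cf, se = se, t = tval,
             p = pmax(p, 1e-300), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Conditional analysis of correlated CpGs per transcript
#'
#' For each transcript with marginally significant CpGs, the most
#' associated CpG (lowest p, ties broken by larger absolute t then smaller
#' genomic position) is added to the per-pair model as a covariate, and
#' every remaining significant CpG is re-tested conditionally. In
#' `single_round` mode (the default) a CpG is non-redundant iff its
#' conditional p is below `alpha`; the top CpG is always retained. In
#' `stepwise` mode the best surviving CpG is added to the conditioning set
#' and testing repeats until no CpG survives. CpGs nearly collinear with a
#' conditioning CpG (|r| > 0.999) are declared redundant with a
#' collinearity flag rather than failing numerically. p-values are clamped
#' at 1e-300 before comparison so underflow cannot create spurious ties.
#'
#' @param methylation_residuals,expression_residuals residual omics
#'   matrices sharing the sample axis.
#' @param scan_results AssociationResult table (typically the cis
#'   significant subset of an [eqtm_scan()]), with columns cpg_id,
#'   transcript_id, p, t.
#' @param cpg_annotation optional annotation supplying `pos` for
#'   deterministic tie-breaking.
#' @param alpha conditional significance threshold (strict `<`).
#' @param mode `"single_round"` or `"stepwise"`.
#' @return list with `results` (ConditionalResult table: transcript_id,
#'   tested_cpg_id, conditioned_on, beta, se, t, p, round_index,
#'   collinear), `nonredundant` (transcript_id, cpg_id), and `mode`.
#' @export
condition_on_top <- function(methylation_residuals, expression_residuals,
                             scan_results, cpg_annotation = NULL,
                             alpha = 1e-8,
                             mode = c("single_round", "stepwise")) {
  mode <- match.arg(mode)
  check_shared_samples(methylation_residuals, expression_residuals)
  sr <- scan_results
  sr$p <- pmax(sr$p, 1e-300)
  pos <- if (!is.null(cpg_annotation))
    stats::setNames(cpg_annotation$pos, cpg_annotation$cpg_id)
  else stats::setNames(rep(NA_real_, 0), character(0))
  res_rows <- list()
  keep_rows <- list()
  for (tx in sort(unique(sr$transcript_id))) {
    sub <- sr[sr$transcript_id == tx, , drop = FALSE]
    if (nrow(sub) == 0) next
    # deterministic ordering: p asc, |t| desc, genomic position asc, id asc
    posv <- pos[sub$cpg_id]
    posv[is.na(posv)] <- Inf
    ord <- order(sub$p, -abs(sub$t), posv, sub$cpg_id)
    sub <- sub[ord, , drop = FALSE]
    top <- sub$cpg_id[1]
    remaining <- sub$cpg_id[-1]
    cond_set <- top
    y <- expression_residuals[, tx]
    round_i <- 1L
    repeat {
      if (length(remaining) == 0) break
      round_res <- lapply(remaining, function(cpg) {
        xj <- methylation_residuals[, cpg]
        Xc <- methylation_residuals[, cond_set, drop = FALSE]
        collinear <- any(abs(stats::cor(xj, Xc)) > 0.999)
        if (collinear) {
          return(data.frame(transcript_id = tx, tested_cpg_id = cpg,
                            conditioned_on = paste(cond_set, collapse = ","),
                            beta = NA_real_, se = NA_real_, t = NA_real_,
                            p = 1, round_index = round_i, collinear = TRUE,
                            stringsAsFactors = FALSE))
        }
        X <- cbind(xj, Xc)
        colnames(X) <- c(cpg, cond_set)
        fit <- ols_multi(X, y)
        row <- fit[fit$term == cpg, ]
        data.frame(transcript_id = tx, tested_cpg_id = cpg,
                   conditioned_on = paste(cond_set, collapse = ","),
                   beta = row$beta, se = row$se, t = row$t,
                   p = max(row$p, 1e-300), round_index = round_i,
                   collinear = FALSE, stringsAsFactors = FALSE)
      })
      round_df <- do.call(rbind, round_res)
      res_rows[[length(res_rows) + 1L]] <- round_df
      if (mode == "single_round") {
        cond_set <- c(cond_set,
                      round_df$tested_cpg_id[!round_df$collinear &
                                             round_df$p < alpha])
        break
      }
      surv <- round_df[!round_df$collinear & round_df$p < alpha, , drop = FALSE]
      if (nrow(surv) == 0) break
      posv <- pos[surv$tested_cpg_id]; posv[is.na(posv)] <- Inf
      best <- surv$tested_cpg_id[order(surv$p, -abs(surv$t), posv,
                                       surv$tested_cpg_id)][1]
      cond_set <- c(cond_set, best)
      remaining <- setdiff(remaining, best)
      round_i <- round_i + 1L
    }
    keep_rows[[length(keep_rows) + 1L]] <-
      data.frame(transcript_id = tx, cpg_id = cond_set,
                 stringsAsFactors = FALSE)
  }
  empty_res <- data.frame(transcript_id = character(), tested_cpg_id = character(),
                          conditioned_on = character(), beta = numeric(),
                          se = numeric(), t = numeric(), p = numeric(),
                          round_index = integer(), collinear = logical(),
                          stringsAsFactors = FALSE)
  list(results = if (length(res_rows)) do.call(rbind, res_rows) else empty_res,
       nonredundant = if (length(keep_rows)) do.call(rbind, keep_rows)
                      else data.frame(transcript_id = character(),
                                      cpg_id = character()),
       mode = mode)
}
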
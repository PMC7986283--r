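#' Pack-years of smoking
#'
#' `(cigarettes per day / 20) * years smoked`, with zero assigned to never
#' smokers regardless of the history fields. Vectorized.
#'
#' @param cigs_per_day nonnegative average cigarettes smoked per day.
#' @param years_smoked nonnegative years of smoking.
#' @param status `"current"`, `"former"` or `"never"`.
#' @return nonnegative numeric vector of pack-years.
#' @export
pack_years <- function(cigs_per_day, years_smoked, status) {
  if (any(cigs_per_day < 0) || any(years_smoked < 0))
    stop("validation error: cigarettes per day and years smoked must be >= 0")
  if (any(!status %in% c("current", "former", "never")))
    stop("validation error: status must be current, former or never")
  ifelse(status == "never", 0, cigs_per_day / 20 * years_smoked)
}

#' CpG island-context enrichment of an eQTM set
#'
#' For each island context category (island, shores, shelf, open sea), a
#' 2x2 chi-square test (no continuity correction) of eQTM membership
#' against category membership over the full background. Categories absent
#' from the background yield a flagged NA row.
#'
#' @param eqtm_cpgs character vector of eQTM CpG ids (subset of the
#'   background).
#' @param background_cpgs CpG annotation data.frame with `cpg_id` and
#'   `island_context`.
#' @return data.frame with context, n_eqtm, n_background, observed_frac,
#'   expected_frac, chi2, p, note.
#' @export
context_enrichment <- function(eqtm_cpgs, background_cpgs) {
  if (!all(eqtm_cpgs %in% background_cpgs$cpg_id))
    stop("eqtm_cpgs must be a subset of the background CpG ids")
  contexts <- c("island", "north_shore", "south_shore", "shelf", "open_sea")
  in_set <- background_cpgs$cpg_id %in% eqtm_cpgs
  rows <- lapply(contexts, function(ctx) {
    in_ctx <- background_cpgs$island_context == ctx
    base <- data.frame(context = ctx, n_eqtm = sum(in_set & in_ctx),
                       n_background = sum(in_ctx),
                       observed_frac = NA_real_, expected_frac = NA_real_,
                       chi2 = NA_real_, p = NA_real_, note = "",
                       stringsAsFactors = FALSE)
    if (sum(in_ctx) == 0) {
      base$note <- "empty category"
      return(base)
    }
    base$observed_frac <- mean(in_ctx[in_set])
    base$expected_frac <- mean(in_ctx)
    tab <- table(factor(in_set, c(FALSE, TRUE)), factor(in_ctx, c(FALSE, TRUE)))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    base$chi2 <- unname(ct$statistic)
    base$p <- ct$p.value
    base
  })
  do.call(rbind, rows)
}

#' Exact overlap test of two feature sets within a universe
#'
#' Builds the 2x2 contingency table (in both, A only, B only, neither) and
#' tests enrichment with the two-sided Fisher exact test (tables with
#' point probability at most that of the observed table are summed). The
#' odds ratio is the cross-product `(a d)/(b c)`, with a Haldane 0.5
#' correction applied (and flagged) when any cell is zero.
#'
#' @param set_a,set_b character vectors of feature ids.
#' @param universe character vector containing both sets.
#' @return list with `table` (a, b, c, d), `odds_ratio`,
#'   `haldane_corrected`, `fisher_p`.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("universe smaller than the union of the sets")
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  c_ <- length(setdiff(set_b, set_a))
  d <- length(universe) - a - b - c_
  f <- stats::fisher.test(matrix(c(a, b, c_, d), 2, 2, byrow = TRUE))
  haldane <- any(c(a, b, c_, d) == 0)
  cells <- c(a, b, c_, d) + if (haldane) 0.5 else 0
  list(table = c(a = a, b = b, c = c_, d = d),
       odds_ratio = (cells[1] * cells[4]) / (cells[2] * cells[3]),
       haldane_corrected = haldane,
       fisher_p = f$p.value)
}
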
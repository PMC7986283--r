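Package: eqtmr
Title: Methylation-Expression Association Mapping with Colocalization and
    Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for whole-blood expression quantitative trait methylation
    (eQTM) analysis: two-stage covariate and surrogate-variable
    residualization, cis/trans CpG-transcript association scanning with
    conditional analysis of correlated CpGs, cross-cohort meta-analysis
    tolerant of selectively stored (censored) effects, Bayesian
    colocalization of mQTL and eQTL signals via approximate Bayes factors,
    bidirectional two-sample Mendelian randomization with LD-pruned
    instruments, and annotation-context enrichment. Includes a synthetic
    cohort generator with a configurable causal architecture (mQTL, eQTM,
    eQTL, smoking and disease effects) so the whole chain can be exercised
    and validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
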
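Package: cystirep
Title: Dual-Phenotype Drug Screening and Signature-Reversal Analysis for
    Cystinosis Drug Repurposing
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to run an integrative drug-repurposing analysis for
    nephropathic cystinosis: plate-level assay quality control with the
    Z-factor statistic (plain and replicate-adjusted), hit calling for
    cystine-depletion and apoptosis-protection screens, intersection of
    the two hit sets with four-parameter logistic dose-response
    confirmation and one-way ANOVA follow-up, a negative-binomial
    two-group differential-expression test with Benjamini-Hochberg
    correction, opposite-direction k-of-n voting between the disease
    signature and per-compound ranked gene lists, and hypergeometric
    over-representation analysis against GMT gene-set collections.
    Seeded synthetic-data generators emulate the full study design
    (plates with controls, counts with planted regulation, ranked lists
    with planted reversal genes) so the whole pipeline is testable end
    to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
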
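Package: osintegrate
Title: Multi-Omics Evidence Integration for Phenotypically Extreme Osteosarcomas
Version: 0.1.0
Authors@R:
    person("OS", "Integrate Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for integrating genomic,
    transcriptomic and functional drug-screen evidence from phenotypically
    extreme ("aggressive" versus "curable") osteosarcoma cohorts.
    Implements negative-binomial exact-test differential expression with a
    conservative dual-dispersion FDR decision rule and an unadjusted-p
    fallback; gene-level aggregation of impact-annotated somatic variants
    with cross-specimen set algebra and gene-family clustering;
    four-parameter logistic dose-response fitting with IC50 censoring,
    Chou-Talalay combination indices and hypergeometric kinase target
    deconvolution from inhibitor-panel profiles; and druggability-filtered
    hypergeometric pathway over-representation with per-gene evidence
    annotation. A synthetic-data generator provides ground truth for every
    stage, including a spiked driver pathway whose genes are simultaneously
    differentially expressed, mutated and targeted by effective compounds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
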
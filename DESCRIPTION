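Package: hematrio
Title: Epistasis and c-Myb-Dependent Expression Analysis for Compound
    KIX-Domain Mutant Mice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the genetic-interaction (epistasis) statistic for
    blood-cell phenotypes of four-genotype mouse crosses combining c-Myb
    and CBP/p300 KIX-domain mutant alleles, using a log-scale linear mixed
    model with an experiment (batch) random intercept and contrast-based
    confidence intervals. Also implements the companion expression
    analyses: fold-change classification of c-Myb activated and repressed
    gene sets with KIX-mutation sensitivity and cross-dataset direction
    concordance, and a from-scratch gene set enrichment analysis
    (signal-to-noise ranking, weighted running-sum enrichment score,
    phenotype-permutation NES, FDR q and FWER p). Synthetic blood-count
    and expression generators with planted ground truth make every stage
    verifiable without the original animal or array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
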
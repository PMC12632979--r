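Package: tierscreen
Title: Integrated Phenotypic and Proteomic Screening for Target Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable analysis pipeline for siRNA target-validation screens
    in sensitized microglial cell models. Combines random-intercept mixed-model
    hit calling on replicate cellular assay readouts, per-protein differential
    abundance (one-way ANOVA with Tukey HSD contrasts), preranked gene-set
    enrichment mapped onto disease biological domains, disease-signature
    concordance and reversal scoring (Kendall rank correlation of enrichment
    signatures, per-domain protein-level Pearson correlation through an
    ortholog map), and cross-modal integration that nominates top-tier targets
    supported by both phenotypic and proteomic evidence. Ships a synthetic
    data generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    lmerTest,
    fgsea
Config/testthat/edition: 3
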
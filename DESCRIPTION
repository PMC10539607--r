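Package: coexdrug
Title: Gene Coexpression Modules, Preservation, and Drug Signature
    Susceptibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Weighted gene coexpression network analysis for bulk
    transcriptomes: soft-threshold selection, topological overlap,
    static tree-cut module detection, module eigengenes and hub genes;
    permutation-based module preservation against an external cohort;
    Fisher overlap enrichment of modules in gene-set libraries;
    cell-type localization by constrained least-squares deconvolution
    and eigengene-covariate association; a drug susceptibility metric
    scoring each module against a panel of perturbation signatures; and
    a directional interaction analysis (overlap, sign discordance,
    two-sample Kolmogorov-Smirnov) for pairs of drug-response
    signatures.  Includes a latent-factor synthetic-data generator with
    recorded ground truth for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
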
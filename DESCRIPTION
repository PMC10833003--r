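Package: ptmr
Title: Proteome- and Transcriptome-Wide Association with Tier-Gated Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-phase discovery-confirmatory framework for identifying plasma-protein
    biomarkers from GWAS and QTL summary statistics. Phase one computes FUSION-style
    proteome/transcriptome-wide association Z-statistics across evidence layers (plasma
    proteome, whole-blood and tissue transcriptome) with Benjamini-Hochberg control, and
    assesses shared causal variants by Wakefield approximate-Bayes-factor colocalization.
    Layer-level significance and colocalization evidence are combined into a 0-6 score
    with Weak/Moderate/Strong tiers and a cross-layer direction-consistency flag. Phase
    two estimates causal effects for Strong/Moderate consistent features by two-sample
    Mendelian randomization (Wald ratio, inverse-variance weighted, MR-Egger) with
    Cochran's Q, Egger-intercept and Steiger-directionality sensitivity analyses and
    external-cohort replication calls. A synthetic-data module generates LD panels, QTL
    weight models and summary statistics with known ground truth for calibration.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
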
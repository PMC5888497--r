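Package: guidemeth
Title: On- and Off-Target CpG Methylation Analysis for RNA-Guided dCas9
    Methyltransferases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide characterization of de novo CpG
    methylation deposited by catalytically dead Cas9 fused to DNMT3A/3B
    catalytic domains. Implements per-CpG methylation quantification from
    bisulfite count tables (depth filtering, lambda spike-in conversion
    rate, on-target profiles around gRNA sites), a smoothed Wald-test
    caller for differentially methylated regions, a declarative
    dose/gRNA monotonicity filter for excluding stochastic DMRs across a
    multi-group transfection design, genomic-feature / DNase
    hypersensitive site / seed-PAM density enrichment with matched random
    background windows, and DMR versus ChIP-peak overlap analysis. A
    fully ground-truthed synthetic study generator (annotated genome,
    guide placement, beta-binomial bisulfite counts with injected on- and
    off-target effects) provides a download-free test surface for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
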
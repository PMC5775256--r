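Package: methylaxis
Title: Dorsal-Ventral Methylome and Transcriptome Analysis Along the Dentate Gyrus Axis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing whole-genome bisulfite (MethylC-Seq) and
    Tet-assisted bisulfite (TAB-Seq) methylomes between tissue subregions,
    as in dorsal versus ventral dentate gyrus studies. Provides spike-in
    calibrated maximum-likelihood correction of methylation and
    hydroxymethylation levels, per-context (mCG, mCH) global, binned and
    feature-centered methylation summaries, a fully specified
    differentially methylated region (DMR) caller with Fisher site tests
    and Stouffer region combination, TSS-distance DMR enrichment curves
    with expression-matched resampling control bands, hypergeometric
    peak-DMR colocalization, and a filter/contrast differential expression
    workflow with Benjamini-Hochberg FDR control. Includes a forward
    simulator that generates genomes, methylomes, spike-in controls and
    RNA-Seq counts with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
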
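Package: epitarget
Title: Epigenetic Silencing Screens and Patient-Covering Gene Panels for
    Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate tumor-suppressor genes silenced by promoter
    DNA hypermethylation in a multi-omic tumor cohort and assembles gene
    panels that cover the patient population.  Provides rank-based
    single-sample gene-set scoring with k-nearest-neighbor molecular subtype
    label transfer, an empirical-Bayes moderated-t differential expression
    procedure with fold-change threshold (TREAT-style) testing, an
    expression-methylation anticorrelation screen with per-patient
    hypermethylation and copy-number-loss targetability calls, greedy
    set-cover panel selection, exhaustive CRISPR guide RNA off-target
    enumeration with regulatory-feature annotation, delta-delta-Ct qPCR
    quantification, and Benjamini-Hochberg / two-stage
    Benjamini-Krieger-Yekutieli false discovery rate control.  A synthetic
    cohort generator with ground truth makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
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
    utils
Suggests:
    IRanges,
    knitr,
    limma,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
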
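Package: rbomics
Title: Integrative Multi-Omics Analysis of Retinoblastoma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for desk-scale reanalysis of retinoblastoma
    multi-omics cohorts: a somatic variant filtering cascade for matched and
    tumor-only exomes (panel-of-normals, read-support, allele-fraction,
    population-frequency, dbSNP-exception and shared-indel rules), a
    two-of-three variant-effect-predictor consensus for deleteriousness,
    arm-level copy-number calling with permutation-based cohort recurrence,
    ChIP-seq peak-to-gene integration with TSS-distance binning and
    super-enhancer overlap, binding-motif presence and co-occurrence with
    hypergeometric enrichment, single-cell RNA-seq quality control, and
    oncoprint-style cohort summaries. Every input can be generated by the
    bundled synthetic-data simulators with ground-truth labels, so the whole
    pipeline is exercisable without controlled-access data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    Matrix,
    GenomicRanges,
    IRanges,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
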
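Package: exomecase
Title: Tumour-Normal-RNA Variant Analysis for Single Exome Cases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a single-case tumour exome plus
    blood exome plus tumour mRNA analysis: pileup-based variant calling with
    explicit per-sample read-level criteria, somatic versus germline
    classification against the matched blood sample, a damaging-variant
    selection and exclusion cascade (control-exome panel, population
    frequency, segmental duplications, gene blacklist) with per-filter
    provenance, coding-consequence and mutation-spectrum annotation,
    DNA-to-RNA variant-expression integration, loss-of-heterozygosity
    detection with tumour-purity estimation under explicit copy models, and
    hypergeometric gene-set overlap statistics. Ships a seeded synthetic
    case generator that plants a known truth (subclonal somatic variants,
    a germline nonsense two-hit with somatic loss of the wild-type allele
    in an impure tumour, an expression split, and per-filter decoys) so the
    whole pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    withr,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    jsonlite
Config/testthat/edition: 3
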
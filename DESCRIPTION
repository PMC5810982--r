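Package: cehtools
Title: Conserved Extended Haplotypes of the MHC: Phasing, Frequency
    Spectra, Association and Selection-Conversion Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for conserved extended haplotypes (CEHs) of
    the major histocompatibility complex. Provides a synthetic diploid
    case-control generator over a configurable CEH pool, expectation-
    maximization phasing of multi-allelic HLA loci together with an 11-SNP
    haplotype locus, frequency-spectrum and coverage summaries, conditional
    carrier odds-ratio testing with motif-exclusion rules, homozygote-excess
    tests against Hardy-Weinberg expectations, a two-class rare/frequent
    haplotype conversion-selection equilibrium model, and Hamming-distance
    profiling of HLA-motif carriage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
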
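Package: cdrforge
Title: Non-Combinatorial Synthetic CDR Repertoire Design and Antibody Library NGS QC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs synthetic antibody complementarity-determining-region (CDR)
    repertoires by simulating natural germline usage and somatic-hypermutation
    spectra, removes post-translational-modification liability motifs
    (N-glycosylation sequons, Asp-Gly, Asn-Gly, Asp-Pro, Cys, Met), partitions
    the designed sequences into array-synthesis oligonucleotide pools with
    framework flanks, and assembles scFv sequences. A companion NGS quality
    control pipeline annotates merged amplicon reads by framework-anchor
    alignment, extracts CDRs, and computes design-fidelity statistics
    (in-frame, designed-length, designed-sequence and coverage percentages,
    mutation loads, PTM motif burdens, functional-fraction estimators). A
    synthetic-data module generates germline sets, natural-like repertoires
    with known parameters, and error-bearing reads so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
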
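Package: lcrscan
Title: Like-Charge Region Analysis of Intrinsically Disordered Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse charge decoration in intrinsically disordered
    protein sequences. Extracts like-charge regions (LCRs) -- maximal
    stretches whose charged residues are all of one sign -- and computes the
    run-length statistics used to characterise FG nucleoporins: ranked LCR
    lengths, rank gaps and ratios, LCR-covered percentages, FG-motif density
    and disorder-fraction filters, and detection of long positive
    low-charge-density regions (lpLCRs). Includes dataset-level comparison
    summaries (scatter data, Tukey boxplot statistics, outlier fractions,
    coverage histograms) and a synthetic-sequence generator that plants
    lpLCRs with full ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
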
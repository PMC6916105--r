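Package: sigrefine
Title: Signature-Guided Refinement of Somatic Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates somatic point-mutation calls into a refined set dominated
    by biological mutational processes and an artifactual set dominated by
    sequencing-artifact processes. Per-variant quality metrics extracted from a
    VCF (variant allele fraction, base quality, read depths, strand counts) are
    thresholded by a conjunction of filter cutoffs; cutoffs are chosen by a
    seeded real-coded genetic algorithm that maximizes a four-term objective
    built from non-negative least-squares refitting of SBS96 trinucleotide
    spectra against a reference mutational-signature catalog with a designated
    artifact subset. Includes post-refinement strand-bias and filter-parameter
    statistics, sequence-context motif profiling, clinical rescue from a local
    annotation table, a self-contained synthetic-data simulator with truth
    labels, and an HTML run report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    IRanges,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
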
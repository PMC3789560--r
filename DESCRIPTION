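Package: ssrmine
Title: Genome-Wide Microsatellite Marker Discovery Across Resequenced Genome Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects perfect simple sequence repeats (SSRs) in genome
    sequences with MISA-style minimum repeat-count thresholds, screens
    flanking-sequence uniqueness with a seeded ungapped search, designs
    locus-specific primer pairs under Primer3-style box constraints with a
    nearest-neighbor melting-temperature model, verifies primer specificity
    by electronic PCR, merges SSR calls across a panel of
    reference-anchored genomes into polymorphic candidate marker loci, and
    computes the descriptive statistics used in genome-wide SSR surveys
    (density and marker intervals, repeat-class composition, genomic-region
    distribution, GC content, polymorphism information content). A
    synthetic panel simulator with planted, mutated SSR alleles and a
    machine-readable truth table makes the whole pipeline testable without
    any genome download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    data.table,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
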
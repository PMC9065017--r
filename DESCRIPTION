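Package: cartivscreen
Title: Design and Sort-Seq Analysis of CARTIV Synthetic Promoter Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for engineering cytokine-inducible synthetic promoters
    (CARTIV: chimeric antigen receptor tumor-induced vectors) by degenerate
    library screening. Parses IUPAC degenerate promoter templates and
    enumerates or samples the variant space; simulates the full multi-round
    ON/OFF FACS sort-seq screen (log-normal reporter expression with basal,
    per-cytokine and synergistic components, quantile gating, six final
    sorted populations, overdispersed multinomial sequencing with
    substitution errors); converts per-population FASTQ reads into a
    variant-by-population count table by template-anchored extraction of the
    variable positions; applies the read-count filter and cross-population
    "x-trend" enrichment ranking; scores validated promoters (fold
    induction, background, synergism, potency index) from geometric-mean
    fluorescence; and reports per-position base composition of selected
    candidates.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
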
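Package: glycoscan
Title: Genome Scanning for Monosaccharide Biosynthesis Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Infers the "glycan alphabet" of prokaryotic genomes: the set of
    monosaccharides an organism can biosynthesize as nucleotide sugars.
    Ships a curated registry of biosynthesis pathways (monosaccharides,
    nucleotide sugars, enzyme families with bit-score or blastp thresholds,
    step graphs, precursor and product pairs), parses HMMER and BLAST hit
    tables, resolves multi-profile annotations with genomic-context rules,
    calls pathway completeness per genome, and aggregates presence/absence
    into prevalence groups, strain ranges and phylum tables. Includes
    bit-score threshold calibration (ROC, scatter partition, seed-score
    thresholds) and a synthetic-universe generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
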
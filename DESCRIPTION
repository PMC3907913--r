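Package: panelsift
Title: Coverage QC, Artifact Filtering and Variant Prioritization for
    Targeted Gene Panel Pyrosequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the diagnostic analysis of targeted capture panel
    sequencing call sets, modeled on pyrosequencing (454-style) deafness and
    Usher syndrome panels. Provides capture-design handling (interval merging,
    distance-to-exon queries), coverage quality control (per-region and
    per-gene average depth of coverage, on/overlap/off-target read accounting,
    low-coverage flagging with GC annotation), three-rule artifact filtering of
    raw variant calls (allele fraction, strand disequilibrium of indels,
    distance of indels from exons), cohort-frequency prioritization with a
    known-pathogenic whitelist, an evidence-based rule-table classifier for
    variants of unknown clinical significance (UV1-UV4), and a deterministic
    synthetic-data generator with truth labels so every stage can be validated
    offline against sensitivity and specificity targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
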
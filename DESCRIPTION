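Package: riboTE
Title: Translational Efficiency Analysis for Paired Ribo-Seq and RNA-Seq
    Experiments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genome-wide translational-control analysis from paired
    ribosome-profiling (Ribo-seq) and RNA-seq count matrices. Computes
    per-gene translation efficiency (TE), tests mRNA, footprint and TE
    changes between conditions with a negative-binomial count model,
    classifies every gene into six regulatory categories (including
    translational buffering) plus an unregulated class, and measures
    enrichment of each category in user-supplied gene lists with Fisher's
    exact test. Includes a negative-binomial synthetic-data generator with
    planted ground truth, a template-switch homopolymer artifact trimmer
    for FASTQ reads, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    DESeq2
Config/testthat/edition: 3
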
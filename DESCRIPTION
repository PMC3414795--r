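Package: mejaseq
Title: No-Replicate Differential Expression and Assembly QC for Elicitation Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for two-library de novo transcriptome experiments
    without biological replicates, of the kind used to profile methyl
    jasmonate-elicited plant cell cultures. Implements RPKM expression
    quantification, the Audic-Claverie exact conditional test for two
    sequencing libraries with a two-sided p-value and Benjamini-Hochberg FDR
    thresholding, fold-change based DEG classification, comparative-Ct
    (delta-delta-Ct) relative expression, assembly and sequencing quality
    statistics (N50, gap ratio, Q20/N/GC percentages, length bins), and
    seeded generators of synthetic count tables, FASTA and FASTQ data with
    known ground truth for calibration of type-I error and power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
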
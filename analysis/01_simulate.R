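#!/usr/bin/env Rscript
# Generates the synthetic study inputs at desk scale: a two-library count
# table with known DE structure (with truth table), a unigene-like FASTA set
# with controlled gap content, and a FASTQ read set with controlled quality
# and base composition. All downstream analysis scripts read these files.

suppressMessages(library(mejaseq))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(i <- which(args == "--seed"))) args[i + 1] else 1)

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sc <- synthetic_scenario(seed = seed)
sim <- simulate_counts(sc)
write_count_table(sim, sc, file.path(out, "counts.tsv"),
                  file.path(out, "truth.tsv"))
cat(sprintf("counts: %d genes, library totals %d / %d (targets %d / %d)\n",
            nrow(sim$counts), sum(sim$counts$x), sum(sim$counts$y),
            sc$lib_size_a, sc$lib_size_b))
cat(sprintf("truth: %d DE genes (%.1f%%)\n",
            sum(sim$truth$true_status != "not_de"),
            100 * mean(sim$truth$true_status != "not_de")))

fa <- simulate_fasta(2000, seed = seed)
write_fasta_sequences(fa$sequences, file.path(out, "unigenes.fasta"),
                      seed = seed)
write.table(fa$truth, file.path(out, "unigenes_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("fasta: %d records, %.1f%% with gap ratio < 5%%\n",
            length(fa$sequences), 100 * mean(fa$truth$gap_ok)))

fq <- simulate_fastq(5000, 200, seed = seed)
write_fastq_reads(fq, file.path(out, "reads.fastq"))
cat(sprintf("fastq: 5000 reads of 200 bp (seed %d)\n", seed))
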
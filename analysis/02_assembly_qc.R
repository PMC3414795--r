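#!/usr/bin/env Rscript
# Sequencing and assembly QC on the simulated data: Q20/N/GC percentages of
# the read set and the assembly statistics block (N50, mean length, length
# bins, gap-ok fraction) of the unigene set. Writes results/qc_report.tsv.

suppressMessages(library(mejaseq))

reads <- read_fastq_reads("results/sim/reads.fastq")
st <- fastq_stats(reads$sequences, reads$qualities)
cat(sprintf("reads: Q20 %.2f%%, N %.2f%%, GC %.2f%%\n",
            st[["q20_pct"]], st[["n_pct"]], st[["gc_pct"]]))

unigenes <- read_fasta_sequences("results/sim/unigenes.fasta")
as <- assembly_stats(unigenes)
cat(sprintf("unigenes: n=%d, total %d bp, N50 %d bp, mean %.0f bp\n",
            as$n_sequences, as$total_bases, as$n50, as$mean_length))
cat(sprintf("          %.2f%% >= 500 bp; gap ratio < 5%% for %.2f%%\n",
            as$prop_ge_500_pct, 100 * as$gap_ok_fraction))
print(as$bins, row.names = FALSE)

dir.create("results", showWarnings = FALSE)
report <- data.frame(
  field = c("q20_pct", "n_pct", "gc_pct", "n_sequences", "total_bases",
            "n50", "mean_length", "prop_ge_500_pct", "gap_ok_fraction"),
  value = c(round_half_up(st[["q20_pct"]], 2), round_half_up(st[["n_pct"]], 2),
            round_half_up(st[["gc_pct"]], 2), as$n_sequences, as$total_bases,
            as$n50, round(as$mean_length, 1), as$prop_ge_500_pct,
            round(as$gap_ok_fraction, 4)))
write.table(report, "results/qc_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/qc_report.tsv\n")
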
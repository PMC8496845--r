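#!/usr/bin/env Rscript
# Stage 2: draw ground truth and simulate the sequencing experiment.
#
# Ground truth: log-normal copy numbers, sequence-determined designed-
# spliced fractions, low-level cryptic isoforms at downstream HAG motifs,
# five-isoform mixtures for two-intron designs. Reads: two RNA repeats
# plus a DNA control, merged amplicons with substitution errors, split
# over 4 control indexes.

suppressPackageStartupMessages(library(splicelib))

seed <- 20210927L
out <- "results"
manifest <- read_manifest(file.path(out, "manifest.tsv"))

truth <- simulate_ground_truth(manifest, seed = derive_seed(seed, "truth"))
write.table(truth$isoforms, file.path(out, "truth_isoforms.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sim <- simulate_experiment(manifest, truth,
                           n_reads_rna = 250000L, n_reads_dna = 60000L,
                           error_rate = 0.001,
                           seed = derive_seed(seed, "reads"))
write_reads_fastq(sim$reads, file.path(out, "reads.fastq"))
write.table(sim$truth_counts, file.path(out, "truth_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Simulated %d reads (%d RNA across 2 repeats, %d DNA)\n",
            nrow(sim$reads), sum(sim$reads$sample == "RNA"),
            sum(sim$reads$sample == "DNA")))
des <- truth$isoforms[truth$isoforms$isoform == "designed", ]
cat(sprintf("True designed-spliced fractions: median %.3f, %d%% above 0.5\n",
            median(des$fraction), round(100 * mean(des$fraction > 0.5))))
cat(sprintf("%d variants carry a cryptic isoform in truth\n",
            sum(truth$isoforms$isoform == "cryptic")))
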
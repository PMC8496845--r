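#!/usr/bin/env Rscript
# Stage 1: design the synthetic intron library.
#
# Builds a scaled-down library with every subset of the full design:
# combinatorial synthetic introns (splice-site catalog x lengths x
# BS-to-3'SS distances x U elements), negative controls with mock sites,
# natural-intron insertions, and all ordered two-intron pairs from a
# short-intron pool. Writes the manifest and oligo FASTA under results/.

suppressPackageStartupMessages(library(splicelib))

seed <- 20210927L
out <- "results"
dir.create(out, showWarnings = FALSE)

manifest <- build_library(
  n_combinatorial = 600L, # sampled from the full catalog grid
  n_negative = 24L,
  n_natural = 60L,
  two_intron_pool = 10L, # 100 ordered pairs
  seed = seed)

write_manifest(manifest, file.path(out, "manifest.tsv"),
               fasta = file.path(out, "library.fasta"))

cat(sprintf("Designed %d variants:\n", nrow(manifest)))
print(table(manifest$subset))
cat("\nEvery variable region is", unique(nchar(manifest$region)),
    "nt; single-intron designs start their intron at oligo position",
    unique(manifest$i1_start[!is.na(manifest$i1_start)]), "\n")
cat("Wrote", file.path(out, "manifest.tsv"), "and",
    file.path(out, "library.fasta"), "\n")
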
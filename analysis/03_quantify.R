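#!/usr/bin/env Rscript
# Stage 3: quantify splicing efficiencies from the simulated reads.
#
# Barcode decoding (Levenshtein <= 2, unique nearest neighbour), junction
# classification (normalized Smith-Waterman > 0.8), cryptic search on
# undetermined reads (fit alignment, longest uninterrupted gap), SE
# aggregation (read-weighted mean over repeats, median over indexes),
# read floor 10, DNA artifact filter at 0.05, cryptic reporting floor
# 0.01. Ends by comparing the estimates with the simulator's truth.

suppressPackageStartupMessages(library(splicelib))

out <- "results"
manifest <- read_manifest(file.path(out, "manifest.tsv"))
reads <- read_reads_fastq(file.path(out, "reads.fastq"))
truth_iso <- read.table(file.path(out, "truth_isoforms.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)

q <- quantify_experiment(reads, manifest)
write.table(q$se, file.path(out, "splicing_efficiency.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(q$abundance, file.path(out, "abundance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Classification drop log:\n")
print(q$drop_log)

kept <- unique(q$se$variant_id[!q$se$low_reads])
des <- q$se[q$se$isoform == "designed", ]
est <- des$se[match(kept, des$variant_id)]
est[is.na(est)] <- 0
tru <- truth_iso[truth_iso$isoform == "designed", ]
tv <- tru$fraction[match(kept, tru$variant_id)]
tv[is.na(tv)] <- 0
cat(sprintf("\nDesigned-isoform SE recovery over %d variants: Pearson r = %.4f, max |error| = %.4f\n",
            length(kept), cor(est, tv), max(abs(est - tv))))
# the largest errors are pure sampling noise on low-coverage variants
nr <- q$se$n_reads[match(kept, q$se$variant_id)]
deep <- nr >= 200
cat(sprintf("  restricted to variants with >= 200 reads (n = %d): r = %.4f, max |error| = %.4f\n",
            sum(deep), cor(est[deep], tv[deep]), max(abs(est - tv)[deep])))

neg <- manifest$variant_id[manifest$subset == "negative_control"]
cat(sprintf("Negative controls with SE > 0.05: %d of %d\n",
            sum(est[kept %in% neg] > 0.05), sum(kept %in% neg)))

cr <- q$se[startsWith(q$se$isoform, "cryptic:"), ]
cat(sprintf("Cryptic clusters reported (SE > 0.01): %d across %d variants\n",
            nrow(cr), length(unique(cr$variant_id))))

# SE vs total RNA abundance (the designed + cryptic sum per variant)
sp <- q$se[!q$se$isoform %in% c("unspliced", "undetermined", "unclassified") &
             !q$se$low_reads, ]
tot_se <- tapply(sp$se, sp$variant_id, sum)
m <- match(names(tot_se), q$abundance$variant_id)
ok <- !is.na(m) & is.finite(q$abundance$abundance[m]) & !is.na(tot_se)
ct <- cor.test(as.numeric(tot_se[ok]), q$abundance$abundance[m][ok])
cat(sprintf("Total SE vs RNA abundance: Pearson r = %.3f (p = %.2g, n = %d)\n",
            ct$estimate, ct$p.value, sum(ok)))
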
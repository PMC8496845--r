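#!/usr/bin/env Rscript
# Stage 4: sequence-feature analyses of the measured splicing efficiencies,
# plus the two randomization controls.
#
# Binned-SE analyses on consensus-site variants: U content of the 20-nt
# window upstream of the 3'SS (expected positive trend), the Y-content
# control restricted to elements with >= 30% C among their pyrimidines
# (expected no trend under a U-specific mechanism), BS-to-3'SS distance,
# and intronic GC (expected negative trend). Controls: barcode-quartet
# variance vs shuffled quartets, and the mock-variant SE-abundance null.

suppressPackageStartupMessages(library(splicelib))

seed <- 20210927L
out <- "results"
manifest <- read_manifest(file.path(out, "manifest.tsv"))
se <- read.table(file.path(out, "splicing_efficiency.tsv"), header = TRUE,
                 sep = "\t", stringsAsFactors = FALSE)

des <- se[se$isoform == "designed" & !se$low_reads, ]
fm <- extract_feature_matrix(manifest)
m <- match(fm$variant_id, des$variant_id)
fm$se <- ifelse(is.na(m), 0, des$se[m])
# consensus-branch-site combinatorial variants (the BS dominates SE, so
# conditioning on it isolates the 3' end features)
cons <- fm[fm$variant_id %in%
             manifest$variant_id[manifest$subset == "combinatorial"] &
             fm$is_consensus_bs == 1, ]

report_bins <- function(label, res, se_vec, feat_vec) {
  ct <- cor.test(feat_vec, se_vec)
  cat(sprintf("%s:\n  bin-mean trend r = %+.3f (p = %.3g; bins n = %s); per-variant r = %+.3f (p = %.3g, n = %d)\n",
              label, res$cor, res$p_value, paste(res$bins$n, collapse = "/"),
              ct$estimate, ct$p.value, length(se_vec)))
  res$bins
}

u_bins <- report_bins("U content upstream of 3'SS vs SE",
                      binned_se(cons$se, cons$u_content_w20,
                                edges = seq(0, 1, by = 0.2)),
                      cons$se, cons$u_content_w20)
write.table(u_bins, file.path(out, "bins_u_content.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# Y-content control: only elements with at least 30% C among pyrimidines
ycon <- cons[cons$c_frac_of_y_w20 >= 0.3, ]
y_bins <- report_bins(sprintf("Y content control (n = %d after C filter)",
                              nrow(ycon)),
                      binned_se(ycon$se, ycon$y_content_w20,
                                edges = seq(0, 1, by = 0.2)),
                      ycon$se, ycon$y_content_w20)
write.table(y_bins, file.path(out, "bins_y_content.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

bs_bins <- report_bins("BS-to-3'SS distance vs SE",
                       binned_se(cons$se, cons$bs_to_3ss_len,
                                 edges = c(15, 25, 35, 45, 55)),
                       cons$se, cons$bs_to_3ss_len)
write.table(bs_bins, file.path(out, "bins_bs_to_3ss.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

gc_bins <- report_bins("Intronic GC content vs SE",
                       binned_se(cons$se, cons$intron_gc,
                                 edges = seq(0.2, 0.6, by = 0.08)),
                       cons$se, cons$intron_gc)
write.table(gc_bins, file.path(out, "bins_gc.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## Barcode-quartet variance control -----------------------------------------
# Rebuild 25 designs with four barcodes each, simulate, and compare the
# within-quartet SE variance with shuffled quartets.
cat("\nBarcode-quartet variance control:\n")
catal <- splice_site_catalog(seed = seed)
bcs <- generate_barcodes(100, seed = derive_seed(seed, "quartet-bc"))
bg <- random_background(derive_seed(seed, "quartet-bg"))
rows <- list()
grid <- expand.grid(five = catal$five_prime_sites,
                    len = c(73L, 89L, 105L, 121L, 137L),
                    stringsAsFactors = FALSE)
for (g in seq_len(25)) {
  f <- design_features(grid$five[g], "TACTAAC", "TAG", grid$len[g], 30L,
                       "TTTAA")
  for (b in seq_len(4)) {
    rows[[length(rows) + 1]] <- build_combinatorial_variant(
      f, bg, bcs[(g - 1) * 4 + b], sprintf("q%02d_bc%d", g, b))
  }
}
qman <- do.call(rbind, rows)
qtruth <- simulate_ground_truth(qman, seed = derive_seed(seed, "quartet"))
qsim <- simulate_experiment(qman, qtruth, 40000, 10000, error_rate = 0.001,
                            seed = derive_seed(seed, "quartet-sim"))
qq <- quantify_experiment(qsim$reads, qman)
qdes <- qq$se[qq$se$isoform == "designed" & !qq$se$low_reads, ]
grp <- sub("_bc[0-9]$", "", qdes$variant_id)
bvc <- barcode_variance_control(qdes$se, grp, n_shuffles = 10000,
                                seed = derive_seed(seed, "quartet-null"))
cat(sprintf("  observed mean within-quartet variance %.4f vs null median %.4f (p = %.4g)\n",
            bvc$observed, median(bvc$null), bvc$p))

## Randomized SE-abundance control -------------------------------------------
ctrl <- randomized_abundance_control(n = 5000,
                                     seed = derive_seed(seed, "mock"))
cat(sprintf("Mock-variant SE vs abundance: r = %+.3f, p = %.3f (expected null)\n",
            ctrl$r, ctrl$p_value))
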
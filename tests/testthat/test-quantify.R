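test_that("barcode decoding applies the strict distance-and-uniqueness rule", {
  bcs <- c("AAAAAACCCCCC", "AAAAAAGGGGGG", "TTTTTTCCCCCC", "AAAAAACCGGGG")
  idx <- barcode_index(bcs, c("v1", "v2", "v3", "v4"))
  tail <- strrep("T", 20)

  expect_equal(decode_barcodes(paste0(bcs[1], tail), idx)$variant_id, "v1")

  # two substitutions: still assigned
  expect_equal(decode_barcodes(paste0("ACGAAACCCCCC", tail), idx)$variant_id,
               "v1")
  # an insertion inside the barcode: window scan tolerates the shift
  expect_equal(decode_barcodes(paste0("AAAAAAACCCCCC", tail), idx)$variant_id,
               "v1")
  # three substitutions: dropped ("< 3" is strict)
  d3 <- decode_barcodes(paste0("TTTAAACCCCCC", tail), idx)
  expect_true(is.na(d3$variant_id))

  # equidistant between v1 and v4 (distance 2 from both): ambiguous
  amb <- decode_barcodes(paste0("AAAAAACCGGCC", tail), idx)
  expect_true(is.na(amb$variant_id))
  expect_equal(amb$drop_reason, "ambiguous")
})

test_that("dereplication groups exact sequences and conserves counts", {
  u <- dereplicate(c("AAA", "AAA", "AAA"))
  expect_equal(nrow(u), 1)
  expect_equal(u$count, 3)

  all_diff <- dereplicate(c("AAA", "CCC", "GGG"))
  expect_equal(nrow(all_diff), 3)
  expect_true(all(all_diff$count == 1))

  set.seed(30)
  reads <- sample(c("ACGT", "TTTT", "GGCC"), 200, replace = TRUE)
  expect_equal(sum(dereplicate(reads)$count), 200)
})

test_that("single-intron reads follow the three-rule junction decision", {
  v <- fixture_variant(seed = 23)
  oligo <- oligo_seq(v)
  expect_equal(classify_single(oligo, v), "unspliced")
  expect_equal(classify_single(splice_out(oligo, v$i1_start, v$i1_end), v),
               "designed_spliced")
  # a chimeric read containing all three junctions is undetermined
  j <- variant_junctions(v)
  chimera <- paste0(j["exon_intron1"], j["intron1_exon2"], j["exon_exon"])
  expect_equal(classify_single(chimera, v), "undetermined")
  # a cryptic product matches no rule either
  h <- first_downstream_hag(oligo, v$i1_end)
  expect_equal(classify_single(splice_out(oligo, v$i1_start, h + 2), v),
               "undetermined")
})

test_that("two-intron reads classify to all five isoform classes", {
  v <- fixture_two_intron(seed = 24)
  oligo <- oligo_seq(v)
  s1 <- v$i1_start; e1 <- v$i1_end; s2 <- v$i2_start; e2 <- v$i2_end
  expect_equal(classify_two_intron(oligo, v), "unspliced")
  expect_equal(classify_two_intron(splice_out(oligo, s1, e1), v), "intron1")
  expect_equal(classify_two_intron(splice_out(oligo, s2, e2), v), "intron2")
  expect_equal(classify_two_intron(splice_out(oligo, s1, e2), v),
               "exon_skipping")
  expect_equal(classify_two_intron(splice_out(oligo, c(s1, s2), c(e1, e2)), v),
               "both")
  expect_error(classify_two_intron(oligo, fixture_variant(seed = 23)),
               "two-intron")
})

test_that("cryptic clusters key on exact intron ends and redirect designed ends", {
  v <- fixture_variant(seed = 25)
  oligo <- oligo_seq(v)
  h <- first_downstream_hag(oligo, v$i1_end)
  cr_read <- splice_out(oligo, v$i1_start, h + 2)
  calls <- find_cryptic(c(cr_read, splice_out(oligo, v$i1_start, v$i1_end)), v)
  expect_equal(calls[1], sprintf("cryptic:%d-%d", v$i1_start, h + 2))
  expect_equal(calls[2], "designed_spliced")
  expect_identical(find_cryptic(character(0), v), character(0))
})

test_that("splicing efficiency aggregates by weighted mean then median", {
  # one index, two repeats: (SE 0.2, n 100) and (SE 0.6, n 300) -> 0.5
  counts <- data.frame(
    variant_id = "v1",
    isoform = rep(c("designed", "unspliced"), 2),
    index = 1L, rep = c(1L, 1L, 2L, 2L),
    count = c(20L, 80L, 180L, 120L))
  se <- splicing_efficiency(counts)
  expect_equal(se$se[se$isoform == "designed"], 0.5)

  # 3 spliced / 10 total
  c2 <- data.frame(variant_id = "v2", isoform = c("designed", "unspliced"),
                   index = 1L, rep = 1L, count = c(3L, 7L))
  expect_equal(splicing_efficiency(c2)$se[1], 0.3)

  # fewer than 10 reads: flagged, SE undefined
  c3 <- data.frame(variant_id = "v3", isoform = c("designed", "unspliced"),
                   index = 1L, rep = 1L, count = c(3L, 6L))
  se3 <- splicing_efficiency(c3)
  expect_true(all(se3$low_reads))
  expect_true(all(is.na(se3$se)))
})

test_that("isoform efficiencies partition the reads", {
  man <- fixture_library(seed = 26, n_combinatorial = 6, n_negative = 2,
                         n_natural = 2, two_intron_pool = 2)
  truth <- simulate_ground_truth(man, seed = 26)
  sim <- simulate_experiment(man, truth, 4000, 1000, error_rate = 0.001,
                             seed = 26)
  cls <- classify_sample(sim$reads[sim$reads$sample == "RNA", ], man)
  n_rna <- sum(sim$reads$sample == "RNA")
  expect_equal(sum(cls$counts$count) + sum(cls$drop_log), n_rna)

  # within each (index, repeat) cell the isoform efficiencies are an exact
  # partition of the assigned reads
  cells <- unique(cls$counts[, c("variant_id", "index", "rep")])
  for (k in seq_len(nrow(cells))) {
    cc <- cls$counts[cls$counts$variant_id == cells$variant_id[k] &
                       cls$counts$index == cells$index[k] &
                       cls$counts$rep == cells$rep[k], ]
    expect_equal(sum(cc$count / sum(cc$count)), 1)
  }
  # the index-median aggregation preserves additivity up to sampling slack
  se <- splicing_efficiency(cls$counts)
  sums <- tapply(se$se[!se$low_reads], se$variant_id[!se$low_reads], sum)
  expect_true(all(sums <= 1.05, na.rm = TRUE))
})

test_that("abundance is the log ratio of within-sample frequencies", {
  expect_equal(rna_abundance(0.01, 0.01), 0)
  expect_equal(rna_abundance(0.1, 0.01), 1)
  expect_equal(rna_abundance(0.001, 0.01), -1)
  expect_warning(out <- rna_abundance(0, 0.01), "undefined")
  expect_true(is.na(out))
})

test_that("the DNA artifact filter zeroes only strictly exceeding isoforms", {
  se_rna <- data.frame(variant_id = c("v1", "v2"), isoform = "designed",
                       se = c(0.8, 0.8), n_reads = 100, low_reads = FALSE)
  se_dna <- data.frame(variant_id = c("v1", "v2"), isoform = "designed",
                       se = c(0.06, 0.05), n_reads = 100, low_reads = FALSE)
  out <- dna_artifact_filter(se_rna, se_dna)
  expect_equal(out$se[out$variant_id == "v1"], 0)
  expect_true(out$dna_artifact[out$variant_id == "v1"])
  expect_equal(out$se[out$variant_id == "v2"], 0.8) # 0.05 exactly: retained
  expect_false(out$dna_artifact[out$variant_id == "v2"])
})

test_that("low cryptic clusters are suppressed at the reporting floor", {
  se <- data.frame(variant_id = "v1",
                   isoform = c("cryptic:18-100", "cryptic:18-120", "designed"),
                   se = c(0.005, 0.05, 0.002), n_reads = 1000,
                   low_reads = FALSE)
  out <- suppress_low_cryptic(se)
  expect_false("cryptic:18-100" %in% out$isoform)
  expect_true("cryptic:18-120" %in% out$isoform)
  expect_true("designed" %in% out$isoform) # floor applies to cryptic only
})
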
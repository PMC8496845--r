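test_that("ground-truth mixtures are valid probability vectors", {
  man <- fixture_library(seed = 17)
  truth <- simulate_ground_truth(man, seed = 17)
  sums <- tapply(truth$isoforms$fraction, truth$isoforms$variant_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(truth$isoforms$fraction >= 0))
  expect_true(all(truth$copy_number$copy > 0))
})

test_that("read counts are conserved and proportions follow the truth", {
  man <- fixture_library(seed = 18, n_combinatorial = 2, n_negative = 0,
                         n_natural = 0, two_intron_pool = 0)
  v <- man[1, ]
  truth <- list(copy_number = data.frame(variant_id = man$variant_id,
                                         copy = c(1, 1)),
                isoforms = data.frame(
                  variant_id = rep(man$variant_id, each = 2),
                  isoform = rep(c("unspliced", "designed"), 2),
                  s1 = rep(c(NA, v$i1_start), 2),
                  e1 = c(NA, v$i1_end, NA, man$i1_end[2]),
                  s2 = NA_integer_, e2 = NA_integer_,
                  fraction = rep(c(0.5, 0.5), 2)))
  class(truth) <- "ground_truth"
  sim <- simulate_sample(man, truth, n_reads = 10000, "RNA",
                         error_rate = 0, seed = 5)
  expect_equal(sum(sim$truth_counts$count), 10000) # conservation
  expect_equal(nrow(sim$reads), 10000)
  spl <- sim$truth_counts
  for (id in man$variant_id) {
    n_tot <- sum(spl$count[spl$variant_id == id])
    n_spl <- sum(spl$count[spl$variant_id == id & spl$isoform == "designed"])
    sd3 <- 3 * sqrt(0.25 * n_tot)
    expect_lt(abs(n_spl - n_tot / 2), sd3)
  }
})

test_that("DNA samples never contain spliced reads at zero error rate", {
  man <- fixture_library(seed = 19, n_combinatorial = 4, n_negative = 0,
                         n_natural = 0, two_intron_pool = 0)
  truth <- simulate_ground_truth(man, seed = 19)
  dna <- simulate_sample(man, truth, 2000, "DNA", error_rate = 0, seed = 3)
  expect_true(all(dna$truth_counts$isoform == "unspliced"))
  oligos <- paste0(man$barcode, man$region)
  expect_true(all(dna$reads$seq %in% oligos))
})

test_that("simulation is byte-reproducible under a fixed seed", {
  man <- fixture_library(seed = 20, n_combinatorial = 3, n_negative = 0,
                         n_natural = 0, two_intron_pool = 0)
  truth <- simulate_ground_truth(man, seed = 20)
  s1 <- simulate_sample(man, truth, 500, "RNA", error_rate = 0.01, seed = 9)
  s2 <- simulate_sample(man, truth, 500, "RNA", error_rate = 0.01, seed = 9)
  expect_identical(s1$reads, s2$reads)

  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  write_reads_fastq(s1$reads, f1)
  write_reads_fastq(s2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))

  back <- read_reads_fastq(f1)
  expect_identical(back$seq, s1$reads$seq)
  expect_identical(back$index, s1$reads$index)
})

test_that("inject_cryptic adds a renormalized isoform at a HAG motif", {
  v <- fixture_variant(seed = 21)
  man <- v
  truth <- simulate_ground_truth(man, seed = 21, p_cryptic = 0)
  h <- first_downstream_hag(oligo_seq(v), v$i1_end)
  off <- h + 2L - v$i1_end
  t2 <- inject_cryptic(truth, v, off, 0.2)
  iso <- t2$isoforms[t2$isoforms$variant_id == v$variant_id, ]
  expect_equal(sum(iso$fraction), 1)
  cr <- iso[iso$isoform == "cryptic", ]
  expect_equal(cr$fraction, 0.2)
  expect_equal(cr$e1 - v$i1_end, off) # cryptic intron longer by the offset

  expect_identical(inject_cryptic(truth, v, off, 0), truth)
  expect_error(inject_cryptic(truth, v, 300, 0.1), "outside")
  expect_error(inject_cryptic(truth, v, off + 1, 0.1), "HAG")
})

test_that("invalid simulation inputs are rejected", {
  man <- fixture_library(seed = 22, n_combinatorial = 2, n_negative = 0,
                         n_natural = 0, two_intron_pool = 0)
  truth <- simulate_ground_truth(man, seed = 22)
  expect_error(simulate_sample(man, truth, 0, "RNA"), "positive")
  bad <- truth
  bad$isoforms$fraction <- bad$isoforms$fraction * 2
  expect_error(simulate_sample(man, bad, 10, "RNA"), "sum to 1")
})
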
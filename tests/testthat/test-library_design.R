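test_that("barcode sets respect the pairwise edit-distance rule", {
  bc <- generate_barcodes(4, length = 12, seed = 1)
  expect_length(bc, 4)
  expect_true(all(nchar(bc) == 12))
  d <- utils::adist(bc)
  expect_true(all(d[upper.tri(d)] >= 4))
  expect_false(any(grepl("ATG", bc, fixed = TRUE)))

  expect_length(generate_barcodes(1, length = 12, seed = 2), 1)
})

test_that("every single-edit corruption decodes to its source barcode", {
  bc <- generate_barcodes(6, length = 12, seed = 4)
  for (k in seq_along(bc)) {
    for (corrupt in all_single_edits(bc[k])) {
      d <- utils::adist(corrupt, bc)
      expect_equal(unname(which.min(d)), k)
      expect_lte(min(d), 1)
      expect_equal(sum(d == min(d)), 1) # unique nearest neighbour
    }
  }
})

test_that("infeasible barcode requests fail after bounded rejection", {
  expect_error(generate_barcodes(500, length = 5, min_dist = 4, seed = 1,
                                 max_rounds = 2000),
               "rejection rounds")
})

test_that("start-codon scrubbing removes ATG with minimal edits", {
  out <- scrub_start_codons("CCCATGCCC")
  expect_false(grepl("ATG", out, fixed = TRUE))
  expect_equal(nchar(out), 9)
  ham <- sum(strsplit(out, "")[[1]] != strsplit("CCCATGCCC", "")[[1]])
  expect_lte(ham, 1)

  expect_equal(as.character(scrub_start_codons("AAAA")), "AAAA")

  # property: random sequences come back ATG-free and length-preserved
  set.seed(11)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
    out <- scrub_start_codons(s)
    expect_false(grepl("ATG", out, fixed = TRUE))
    expect_equal(nchar(out), 60)
  }
})

test_that("a protected donor ATG is retained and gains a downstream stop", {
  s <- paste0(strrep("C", 17), "GTATGTA", strrep("C", 40))
  prot <- data.frame(start = 18, end = 23, class = "five_ss")
  out <- as.character(scrub_start_codons(s, prot))
  expect_equal(substr(out, 18, 23), "GTATGT") # site untouched
  # ATG starts at 20; stop codon two codons downstream, in its frame
  expect_true(substr(out, 26, 28) %in% c("TAA", "TAG", "TGA"))
})

test_that("combinatorial placement geometry matches the design arithmetic", {
  v <- fixture_variant(intron_len = 73, bs_to_3ss = 20)
  expect_equal(v$i1_start, 18)
  expect_equal(v$i1_end, 18 + 73 - 1) # = 90
  oligo <- oligo_seq(v)
  expect_equal(nchar(v$region), 158)
  expect_equal(substr(oligo, 18, 23), "GTATGT")
  expect_equal(substr(oligo, 88, 90), "TAG")
  expect_equal(substr(oligo, 64, 70), "TACTAAC") # BS ends at 90 - 20
  expect_true(validate_variant(v))

  # junctions agree with direct slicing at the recorded coordinates
  j <- variant_junctions(v)
  expect_equal(unname(j["exon_exon"]),
               paste0(substr(oligo, 1, 17), substr(oligo, 91, 110)))
  expect_equal(unname(j["exon_intron1"]),
               paste0(substr(oligo, 1, 17), substr(oligo, 18, 37)))
  expect_equal(unname(j["intron1_exon2"]),
               paste0(substr(oligo, 71, 90), substr(oligo, 91, 110)))
})

test_that("negative-control designs keep the geometry under mock sites", {
  cat <- splice_site_catalog(seed = 5)
  f <- design_features(cat$control_sites$five_ss, cat$control_sites$branch,
                       cat$control_sites$three_ss, 89, 30, "TAA",
                       mock = TRUE)
  v <- build_combinatorial_variant(f, random_background(5),
                                   generate_barcodes(1, seed = 9), "n1")
  expect_equal(v$subset, "negative_control")
  expect_equal(v$i1_start, 18)
  expect_equal(v$i1_end, 106)
})

test_that("full designs carry no ATG outside the donor exemption", {
  man <- fixture_library(seed = 13)
  for (i in seq_len(nrow(man))) {
    oligo <- oligo_seq(man[i, ])
    hits <- gregexpr("ATG", oligo, fixed = TRUE)[[1]]
    hits <- hits[hits > 0]
    for (h in hits) {
      # every surviving ATG must sit inside a donor site (positions 3-5
      # of a protected 5'SS at a recorded intron start)
      starts <- c(man$i1_start[i], man$i2_start[i])
      starts <- starts[!is.na(starts)]
      expect_true(any(h >= starts + 1 & h + 2 <= starts + 5),
                  label = sprintf("ATG at %d in %s", h, man$variant_id[i]))
    }
    expect_true(validate_variant(man[i, ]))
  }
})

test_that("natural-intron insertion respects the 148-nt cap and coordinates", {
  bg <- random_background(6)
  bc <- generate_barcodes(1, seed = 6)
  ni <- simulate_natural_intron(len = 148, seed = 1)
  v <- insert_natural_intron(ni$seq, ni$flank5, ni$flank3, bg, bc, "n148")
  expect_equal(nchar(v$region), 158) # exactly fills the region with flanks
  expect_equal(v$i1_end, 17 + 148)

  ni60 <- simulate_natural_intron(len = 60, seed = 2)
  v60 <- insert_natural_intron(ni60$seq, ni60$flank5, ni60$flank3, bg, bc)
  # positions 6-65 of the variable region are intronic
  expect_equal(v60$i1_start - 12, 6)
  expect_equal(v60$i1_end - 12, 65)

  ni149 <- simulate_natural_intron(len = 149, seed = 3)
  expect_error(insert_natural_intron(ni149$seq, ni149$flank5, ni149$flank3,
                                     bg, bc),
               "exceeds the 148")
})

test_that("two-intron layout leaves the arithmetic middle exon", {
  v <- fixture_two_intron(len_a = 56, len_b = 56)
  # exon1 = 5 nt lead, exon3 = 15 nt tail, middle exon fills the rest
  mid_len <- v$i2_start - v$i1_end - 1
  expect_equal(mid_len, 158 - 2 * 56 - 5 - 15)
  expect_equal(v$i1_start, 18)
  expect_equal(v$i2_end, 12 + 158 - 15)
  j <- variant_junctions(v)
  expect_length(j, 8)

  expect_error(build_two_intron_variant(strrep("A", 76), strrep("A", 60),
                                        random_background(1),
                                        generate_barcodes(1, seed = 2)),
               "< 76")
})

test_that("ordered two-intron pairs count as the square of the pool", {
  man <- build_library(n_combinatorial = 1, n_negative = 0, n_natural = 0,
                       two_intron_pool = 3, seed = 8)
  expect_equal(sum(man$subset == "two_intron"), 9)
})

test_that("structure mutants fold the targeted site into a stem", {
  v <- fixture_variant(seed = 9)
  mv <- mutate_for_structure(v, site = "5ss", seed = 5)
  expect_equal(mv$subset, "mutated")
  fold <- attr(mv, "fold")
  mut <- attr(mv, "mutations")
  # acceptance condition: every donor nucleotide base-paired
  win_start <- max(1, v$i1_start - 15)
  expect_true(all(fold$paired[(v$i1_start:(v$i1_start + 5)) - win_start + 1]))
  # mutations never touch the site motifs
  bs_end <- v$i1_end - v$bs_to_3ss
  protected <- c(v$i1_start:(v$i1_start + 5), (bs_end - 6):bs_end,
                 (v$i1_end - 2):v$i1_end)
  expect_length(intersect(mut, protected), 0)
  # determinism under a fixed seed
  mv2 <- mutate_for_structure(v, site = "5ss", seed = 5)
  expect_identical(mv$region, mv2$region)
})

test_that("branch-site templates instantiate their degenerate positions", {
  cat <- splice_site_catalog()
  bs <- instantiate_branch_sites(cat, n_per_template = 2, seed = 3)
  expect_true("TACTAAC" %in% bs)
  expect_true(all(nchar(bs) == 7))
  expect_true(all(substr(bs, 6, 6) == "A"))
  expect_true(all(substr(bs, 3, 7) %in% c("CTAAC", "CTAAT", "TTAAC")))
})
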
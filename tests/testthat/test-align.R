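test_that("smith_waterman matches the three-state recursion oracle", {
  p <- align_params()
  # exhaustive over all sequence pairs up to length 3 over {A, C}
  seqs <- unlist(lapply(1:3, function(L) {
    apply(expand.grid(rep(list(c("A", "C")), L)), 1, paste, collapse = "")
  }))
  for (a in seqs) {
    for (b in seqs) {
      expect_equal(smith_waterman(a, b, p)$score,
                   oracle_sw_score(a, b), label = paste(a, b))
    }
  }
  # random pairs up to length 8 over {A, C}, several parameterizations
  set.seed(42)
  for (prm in list(align_params(), align_params(gap_open = 10, gap_extend = 2),
                   align_params(match = 2, mismatch = -3, gap_open = 5,
                                gap_extend = 5))) {
    for (i in 1:80) {
      a <- paste(sample(c("A", "C"), sample(4:8, 1), replace = TRUE),
                 collapse = "")
      b <- paste(sample(c("A", "C"), sample(4:8, 1), replace = TRUE),
                 collapse = "")
      expect_equal(smith_waterman(a, b, prm)$score,
                   oracle_sw_score(a, b, prm$match, prm$mismatch,
                                   prm$gap_open, prm$gap_extend),
                   label = paste(a, b))
    }
  }
})

test_that("known alignment scores are reproduced", {
  p <- align_params()
  expect_equal(smith_waterman("ACGT", "ACGT", p)$score, 20)
  expect_equal(smith_waterman("ACGT", "AGGT", p)$score, 11)
  expect_equal(smith_waterman("", "ACGT", p)$score, 0)
  expect_equal(smith_waterman("ACGT", "", p)$score, 0)
})

test_that("score is symmetric under argument swap", {
  set.seed(7)
  p <- align_params(gap_open = 6, gap_extend = 6) # non-affine special case
  for (i in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 7, replace = TRUE),
               collapse = "")
    expect_equal(smith_waterman(a, b, p)$score,
                 smith_waterman(b, a, p)$score)
  }
})

test_that("junction scores normalize and threshold correctly", {
  set.seed(8)
  junction <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                    collapse = "")
  read <- paste0("TTAACC", junction, "GGTTAA")
  js <- junction_score(junction, read)
  expect_equal(js$normalized, 1.0)
  expect_true(js$positive)

  # two interior substitutions: (38*5 - 2*4) / 200 = 0.91
  rv <- strsplit(read, "")[[1]]
  pos <- c(16, 30) # interior junction positions 10 and 24
  for (k in pos) rv[k] <- setdiff(c("A", "C", "G", "T"), rv[k])[1]
  js2 <- junction_score(junction, paste(rv, collapse = ""))
  expect_equal(js2$normalized, (38 * 5 - 2 * 4) / 200)
  expect_true(js2$positive)
})

test_that("junction normalized score is scale-invariant in the params", {
  set.seed(9)
  junction <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                    collapse = "")
  read <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")
  base <- junction_score(junction, read)$normalized
  for (cc in c(2, 10)) {
    scaled <- align_params(match = 5 * cc, mismatch = -4 * cc,
                           gap_open = 8 * cc, gap_extend = 8 * cc)
    expect_equal(junction_score(junction, read, scaled)$normalized, base)
  }
})

test_that("unrelated random reads are almost never junction-positive", {
  set.seed(10)
  junction <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                    collapse = "")
  reads <- vapply(1:10000, function(i)
    paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = ""),
    character(1))
  pos_rate <- mean(splicelib:::junction_scores(junction, reads) > 0.8)
  expect_lt(pos_rate, 0.01)
})

test_that("gapped design alignment recovers the excised interval", {
  v <- fixture_variant(seed = 12)
  design <- oligo_seq(v)
  read <- splice_out(design, 18, 90)
  g <- gapped_design_alignment(read, design)
  expect_true(g$call)
  expect_lt(g$normalized, 0.7)
  expect_equal(splicelib:::.canonicalize_gap(design, g$intron[1], g$intron[2], 18),
               c(18, 90))

  intact <- gapped_design_alignment(design, design)
  expect_false(intact$call)
  expect_equal(nrow(intact$gaps), 0)
})

test_that("the mismatch bound on cryptic calls is strict", {
  v <- fixture_variant(seed = 14)
  design <- oligo_seq(v)
  read <- splice_out(design, 18, 90)
  rv <- strsplit(read, "")[[1]]
  pos <- round(seq(3, length(rv) - 2, length.out = 6))
  for (k in pos) rv[k] <- setdiff(c("A", "C", "G", "T"), rv[k])[1]
  g6 <- gapped_design_alignment(paste(rv, collapse = ""), design,
                                max_mismatch = 6)
  expect_equal(g6$mismatches, 6)
  expect_false(g6$call) # "< 6" excludes exactly 6 mismatches
  g7 <- gapped_design_alignment(paste(rv, collapse = ""), design,
                                max_mismatch = 7)
  expect_true(g7$call)
})
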
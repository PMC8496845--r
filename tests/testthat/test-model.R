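test_that("the fold engine matches exhaustive structure enumeration", {
  expect_equal(fold_window("GGGGAAAACCCC")$score, -4)
  expect_equal(fold_window("AAAAAA")$score, 0)
  expect_error(fold_window("ACGTX"), "outside")

  set.seed(41)
  for (i in 1:12) {
    s <- paste(sample(c("A", "C", "G", "U"), 12, replace = TRUE),
               collapse = "")
    f <- fold_window(s)
    expect_equal(-f$score, oracle_max_pairs(s), label = s)
    # the reported pairing is itself a valid optimal structure
    expect_equal(sum(f$paired) / 2, oracle_max_pairs(s))
    expect_true(all(f$partner[f$partner > 0] %in% which(f$paired)))
  }
  # pair count is invariant under reverse complement for these constructs
  for (s in c("GGGGAAAACCCC", "GCGCAAAAGCGC")) {
    expect_equal(fold_window(s)$score, fold_window(revcomp(s))$score)
  }
})

test_that("feature extraction yields the frozen 39-entry schema", {
  sch <- feature_schema()
  expect_equal(nrow(sch), 39)
  v <- fixture_variant(seed = 43)
  fv <- extract_features(v)
  expect_equal(sort(names(fv)), sort(sch$name))
  expect_true(all(!is.na(unlist(fv))))

  # pure function: identical variant, identical vector
  expect_identical(extract_features(v), extract_features(v))

  expect_error(extract_features(fixture_two_intron(seed = 43)),
               "single-intron")
})

test_that("composition features respond to constructed sequence content", {
  # an A/T-only intron has GC content zero
  region <- paste0(strrep("CA", 2), "C", # 5 nt exon lead
                   strrep("AT", 36), "TAA", # 75-nt intron, no G or C
                   strrep("GC", 39)) # exon tail
  v <- handcrafted_variant(region, i1_start = 18L, i1_end = 17L + 75L)
  fv <- extract_features(v)
  expect_equal(fv$intron_gc, 0)
  expect_equal(fv$intron_len, 75)

  # U window of pure T gives U content 1
  region2 <- paste0(strrep("CA", 2), "C",
                    "GTATGT", strrep("CA", 22), strrep("T", 22), "TAG",
                    strrep("GC", 39))
  v2 <- handcrafted_variant(region2, i1_start = 18L, i1_end = 17L + 75L)
  fv2 <- extract_features(v2)
  expect_equal(fv2$u_content_w20, 1.0)
  expect_equal(fv2$y_content_w20, 1.0)
  expect_equal(fv2$c_frac_of_y_w20, 0)
})

test_that("the train/test split reproduces the printed arithmetic", {
  sp <- split_indices(12667, seed = 1)
  expect_length(sp$test, 3167)
  expect_length(sp$train, 9500)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(split_indices(12667, seed = 1), sp)
})

test_that("the model recovers a noiseless function of three features", {
  man <- build_library(n_combinatorial = 450, n_negative = 0, n_natural = 0,
                       seed = 44)
  fm <- extract_feature_matrix(man)
  y <- pmin(1, pmax(0, 0.5 * fm$is_consensus_bs -
                      1.2 * (fm$intron_gc - 0.35) + 0.5 * fm$u_content_w20))
  cfg <- model_config(n_rounds = 200, n_boot = 50)
  m <- train_cv(fm, y, cfg, seed = 4)
  expect_gte(m$r, 0.95)
  expect_true(m$r_ci[1] <= m$r && m$r <= m$r_ci[2])

  # fixed seed: identical fold assignment and predictions
  m2 <- train_cv(fm, y, cfg, seed = 4)
  expect_identical(m$fold, m2$fold)
  expect_identical(m$test_pred, m2$test_pred)

  # leakage check: shuffling the test targets cannot change predictions
  y3 <- y
  y3[m$test_idx] <- sample(y[m$test_idx])
  m3 <- train_cv(fm, y3, cfg, seed = 4)
  expect_identical(m$test_pred, m3$test_pred)
})

test_that("Shapley attributions are additive and expose planted importance", {
  man <- build_library(n_combinatorial = 300, n_negative = 0, n_natural = 0,
                       seed = 45)
  fm <- extract_feature_matrix(man)
  y <- pmin(1, pmax(0, 0.6 * fm$is_consensus_bs -
                      1.5 * (fm$intron_gc - 0.35) + 0.4 * fm$u_content_w20))
  cfg <- model_config(n_rounds = 150, n_boot = 50)
  m <- train_cv(fm, y, cfg, seed = 5)
  sh <- shapley_importance(m, fm, n_boot = 100, seed = 5)

  # local accuracy: attributions + base value sum to the prediction
  expect_lt(sh$local_accuracy_error, 1e-6)

  # a constant feature can carry no attribution
  expect_equal(sh$ranking$mean_abs[sh$ranking$feature == "upstream_exon_len"],
               0)

  # planted drivers dominate the ranking
  top5 <- sh$ranking$feature[1:5]
  expect_true(any(c("bs_seq", "is_consensus_bs") %in% top5))
  expect_true("intron_gc" %in% top5)
  # the top feature separates from the bottom with non-overlapping CI
  expect_gt(sh$ranking$ci_lo[1], max(sh$ranking$ci_hi[30:39]))
})

test_that("predictions for new variants reuse the trained encoder", {
  man <- build_library(n_combinatorial = 120, n_negative = 0, n_natural = 0,
                       seed = 46)
  fm <- extract_feature_matrix(man)
  y <- pmin(1, pmax(0, 0.5 + 0.3 * (fm$u_content_w20 - 0.4)))
  m <- train_cv(fm, y, model_config(n_rounds = 60, n_boot = 20), seed = 6)
  p <- predict(m, fm[1:10, ])
  expect_length(p, 10)
  expect_true(all(is.finite(p)))
})
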
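test_that("motif profiles count planted motifs exactly", {
  set.seed(31)
  # 20 plus-strand introns, every gene carries TAG at offset +5
  n <- 20
  genome <- list()
  introns <- NULL
  for (i in 1:n) {
    s <- paste(sample(c("A", "C"), 400, replace = TRUE), collapse = "")
    end <- 200L
    substr(s, end + 5, end + 7) <- "TAG"
    genome[[paste0("g", i)]] <- s
    introns <- rbind(introns, data.frame(chrom = paste0("g", i),
                                         start = 120L, end = end,
                                         strand = "+"))
  }
  prof <- motif_profile(unlist(genome), introns, window = c(-20L, 20L))
  expect_equal(prof$freq[prof$offsets == 5], 1.0)
  # {A,C} background contains CAG/TAG nowhere else
  expect_true(all(prof$freq[prof$offsets != 5] == 0))

  # planted in 30% of sequences at one offset
  introns30 <- introns
  genome30 <- genome
  for (i in 7:20) substr(genome30[[paste0("g", i)]], 205, 207) <- "ACC"
  prof30 <- motif_profile(unlist(genome30), introns30, window = c(-20L, 20L))
  expect_equal(prof30$freq[prof30$offsets == 5], 6 / 20)
})

test_that("motif profile counts agree with a direct full-scan oracle", {
  g <- simulate_genome(n_introns = 25, chrom_len = 8000, mode = "random",
                       seed = 33)
  win <- c(-30L, 10L)
  prof <- motif_profile(g$genome, g$introns, window = win)
  # oracle: re-extract each window sequence and scan it directly
  total <- 0
  for (r in seq_len(nrow(g$introns))) {
    chrom <- g$genome[[g$introns$chrom[r]]]
    if (g$introns$strand[r] == "+") {
      a <- g$introns$end[r]
      s <- substr(chrom, a + win[1], a + win[2] + 2)
    } else {
      a <- g$introns$start[r]
      s <- revcomp(substr(chrom, a - win[2] - 2, a - win[1]))
    }
    hits <- gregexpr("(CAG|TAG)", s)[[1]]
    total <- total + sum(hits > 0 & hits <= diff(win) + 1)
  }
  expect_equal(sum(prof$freq) * prof$n_introns, total)
})

test_that("avoidance p-values hit the formula edges", {
  g <- simulate_genome(n_introns = 40, chrom_len = 20000, mode = "depleted",
                       seed = 34)
  res <- avoidance_test(g$genome, g$introns, g$cds, n_controls = 500,
                        seed = 1)
  # motif hard-masked around every intron end: below all control sets
  expect_equal(res$p_upstream, 0)
  expect_equal(res$p_downstream, 0)
  expect_warning(avoidance_test(g$genome, g$introns, g$cds, n_controls = 50,
                                seed = 1),
                 "coarse")
})

test_that("null-placed introns give unbiased avoidance p-values", {
  ps <- vapply(1:25, function(i) {
    g <- simulate_genome(n_introns = 40, chrom_len = 15000, mode = "null",
                         seed = 100 + i)
    avoidance_test(g$genome, g$introns, g$cds, n_controls = 200,
                   seed = i)$p_upstream
  }, numeric(1))
  expect_lt(abs(mean(ps) - 0.5), 0.2) # coarse check; calibration is deeper
})

test_that("binned SE analyses recover a planted linear trend", {
  set.seed(35)
  u <- runif(500)
  se <- pmin(1, pmax(0, 0.2 + 0.6 * u + rnorm(500, sd = 0.1)))
  res <- binned_se(se, u, edges = seq(0, 1, by = 0.2))
  expect_gt(res$cor, 0)
  expect_lt(res$p_value, 0.01)
  expect_equal(sum(res$bins$n), 500)

  flat <- binned_se(rep(0.4, 100), runif(100), edges = seq(0, 1, 0.25))
  expect_true(!is.null(flat$flag))
})

test_that("ortholog delta-SE summarizes percent spliced better", {
  tab <- data.frame(gene = rep(c("g1", "g2", "g3"), 2),
                    species = rep(c("S_cerevisiae", "K_lactis"), each = 3),
                    se = c(0.5, 0.4, 0.3, 0.5, 0.5, 0.4))
  d <- delta_se(tab)
  expect_equal(d$pairs$delta_se, c(0, 0.1, 0.1))
  # identical SE does not count as better
  expect_equal(d$percent_better$percent_better, 100 * 2 / 3)

  # all better by 0.1 -> 100%
  tab2 <- tab
  tab2$se[4:6] <- tab2$se[1:3] + 0.1
  expect_equal(delta_se(tab2)$percent_better$percent_better, 100)

  # random pairs: about half are better
  set.seed(36)
  tabr <- data.frame(gene = rep(sprintf("g%03d", 1:400), 2),
                     species = rep(c("S_cerevisiae", "Sp_x"), each = 400),
                     se = runif(800))
  pb <- delta_se(tabr)$percent_better$percent_better
  expect_lt(abs(pb - 50), 3 * 100 * sqrt(0.25 / 400))
})

test_that("Cramer's V matches independent arithmetic and is symmetric", {
  # fixed 3x3 table checked against a hand-computed chi-square
  a <- c(rep(0, 30), runif(40, 0.01, 0.5), runif(30, 0.51, 1))
  b <- c(rep(0, 20), runif(50, 0.01, 0.5), runif(30, 0.51, 1))
  res <- cramers_v(a, b)
  tab <- res$table
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - expected)^2 / expected)
  expect_equal(res$chisq, chi2, tolerance = 1e-9)
  expect_equal(res$phi_c, sqrt(chi2 / (n * 2)), tolerance = 1e-9)

  expect_equal(cramers_v(b, a)$phi_c, res$phi_c)

  # perfectly concordant diagonal table
  conc <- cramers_v(a, a)
  expect_equal(conc$phi_c, 1)

  # independent categories on a large sample
  set.seed(37)
  x <- sample(c(0, 0.3, 0.8), 10000, replace = TRUE)
  y <- sample(c(0, 0.3, 0.8), 10000, replace = TRUE)
  expect_lt(cramers_v(x, y)$phi_c, 0.05)

  # degenerate margin
  deg <- cramers_v(rep(0, 50), runif(50))
  expect_true(is.na(deg$phi_c))
  expect_false(is.null(deg$flag))
})

test_that("barcode-replicate variance control separates real groups", {
  set.seed(38)
  g <- rep(1:30, each = 4)
  se_same <- rep(runif(30, 0.2, 0.9), each = 4) # identical within quartets
  res <- barcode_variance_control(se_same, g, n_shuffles = 500, seed = 2)
  expect_equal(res$observed, 0)
  expect_equal(res$p, 0)

  # randomized group labels: observed sits inside the null
  se_rand <- runif(120)
  res2 <- barcode_variance_control(se_rand, g, n_shuffles = 500, seed = 2)
  expect_gt(res2$p, 0.01)

  res3 <- barcode_variance_control(se_rand, g, n_shuffles = 100, seed = 5)
  res4 <- barcode_variance_control(se_rand, g, n_shuffles = 100, seed = 5)
  expect_identical(res3$null, res4$null)

  expect_error(barcode_variance_control(c(0, 0), c(1, 2), 10), "no multi")
})

test_that("the randomized abundance control is reproducible and guarded", {
  r1 <- randomized_abundance_control(n = 2000, seed = 3)
  r2 <- randomized_abundance_control(n = 2000, seed = 3)
  expect_identical(r1$r, r2$r)
  expect_error(randomized_abundance_control(n = 0), "positive")
})

test_that("SE classes split at zero and the configured midpoint", {
  cls <- se_class(c(0, 0.2, 0.5, 0.7))
  expect_equal(as.character(cls),
               c("unspliced", "intermediate", "intermediate", "high"))
})
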
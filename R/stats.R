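#' Positional 3'SS-motif frequency profile around intron ends
#'
#' Registers all introns at their 3' end (last intron base = position 0,
#' strand-resolved on the coding strand; negative offsets are intronic) and
#' computes, for every offset `i` in the window, the fraction of introns
#' whose 3-mer *starting* at offset `i` matches any of the motifs.
#'
#' @param genome Named character vector of contig sequences.
#' @param introns data.frame with columns `chrom`, `start`, `end` (1-based
#'   closed) and `strand` (`"+"`/`"-"`).
#' @param motifs Character vector of equal-length motifs (default the two
#'   dominant acceptor triplets `CAG`, `TAG`).
#' @param window Integer offsets `c(from, to)` (default -50..30).
#' @return A list: `offsets`, `freq` (per-offset fraction), `n_introns`
#'   used, `n_excluded` (too close to a contig edge).
#' @export
motif_profile <- function(genome, introns, motifs = c("CAG", "TAG"),
                          window = c(-50L, 30L)) {
  k <- nchar(motifs[1])
  stopifnot(all(nchar(motifs) == k))
  W <- window[2] - window[1] + 1L
  counts <- numeric(W)
  used <- 0L
  excluded <- 0L
  for (r in seq_len(nrow(introns))) {
    chrom <- genome[[introns$chrom[r]]]
    n <- nchar(chrom)
    if (introns$strand[r] == "+") {
      a <- introns$end[r]
      lo <- a + window[1]; hi <- a + window[2] + k - 1L
      if (lo < 1L || hi > n) { excluded <- excluded + 1L; next }
      s <- substr(chrom, lo, hi)
    } else {
      a <- introns$start[r]
      lo <- a - window[2] - k + 1L; hi <- a - window[1]
      if (lo < 1L || hi > n) { excluded <- excluded + 1L; next }
      s <- revcomp(substr(chrom, lo, hi))
    }
    tri <- substring(s, 1:W, 1:W + k - 1L)
    counts <- counts + (tri %in% motifs)
    used <- used + 1L
  }
  if (used == 0L) stop("no usable introns in the window")
  list(offsets = window[1]:window[2], freq = counts / used,
       n_introns = used, n_excluded = excluded)
}

# per-contig indicator cumsums of motif starts, on both strands
.motif_index <- function(genome, motifs) {
  k <- nchar(motifs[1])
  lapply(genome, function(chrom) {
    n <- nchar(chrom)
    tri <- substring(chrom, 1:(n - k + 1L), k:n)
    ind_p <- c(tri %in% motifs, rep(FALSE, k - 1L))
    ind_m <- c(revcomp(tri) %in% motifs, rep(FALSE, k - 1L))
    list(cs_p = cumsum(ind_p), cs_m = cumsum(ind_m), n = n)
  })
}

# window sum of motif starts at coding offsets [w1, w2] around anchor `a`
.window_count <- function(idx, a, strand, w1, w2, k) {
  if (strand == "+") {
    lo <- a + w1; hi <- a + w2
    cs <- idx$cs_p
  } else {
    lo <- a - w2 - k + 1L; hi <- a - w1 - k + 1L
    cs <- idx$cs_m
  }
  if (lo < 1L || hi > idx$n) return(NA_real_)
  cs[hi] - if (lo > 1L) cs[lo - 1L] else 0
}

#' Resampling test for 3'SS-motif avoidance near intron ends
#'
#' Compares the summed motif frequency in windows upstream (default
#' offsets -32..-3) and downstream (+1..+30) of intron 3' ends against
#' control sets of N random coding-region positions (N = number of
#' introns). The p-value is the fraction of control sets whose window sum
#' is strictly below the introns' window sum — small p means the motif is
#' depleted around real intron ends.
#'
#' @param genome Named character vector of contig sequences.
#' @param introns Intron annotation data.frame (`chrom`, `start`, `end`,
#'   `strand`).
#' @param cds Coding-region annotation data.frame (same columns); control
#'   anchors are drawn uniformly from these intervals with the interval's
#'   strand.
#' @param motifs Acceptor motifs (default `CAG`, `TAG`).
#' @param n_controls Number of control sets (default 1e5).
#' @param window_upstream,window_downstream Offset windows of the two
#'   tests.
#' @param seed Seed for the control sampling.
#' @return A list of class `avoidance_result`: `p_upstream`,
#'   `p_downstream`, `n_controls`, `n_introns`, the intron window sums,
#'   the control-set mean sums, and the positional `profile`.
#' @export
avoidance_test <- function(genome, introns, cds, motifs = c("CAG", "TAG"),
                           n_controls = 1e5,
                           window_upstream = c(-32L, -3L),
                           window_downstream = c(1L, 30L), seed = 1L) {
  if (n_controls < 100) warning("fewer than 100 control sets: p-values are coarse")
  if (nrow(cds) == 0) stop("coding-region annotation is empty")
  k <- nchar(motifs[1])
  idx <- .motif_index(genome, motifs)

  anchor_sum <- function(chrom, a, strand, win) {
    .window_count(idx[[chrom]], a, strand, win[1], win[2], k)
  }
  up_inr <- dn_inr <- 0
  n_used <- 0L
  for (r in seq_len(nrow(introns))) {
    a <- if (introns$strand[r] == "+") introns$end[r] else introns$start[r]
    u <- anchor_sum(introns$chrom[r], a, introns$strand[r], window_upstream)
    d <- anchor_sum(introns$chrom[r], a, introns$strand[r], window_downstream)
    if (is.na(u) || is.na(d)) next
    up_inr <- up_inr + u; dn_inr <- dn_inr + d
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no usable introns")

  # enumerate candidate coding anchors with precomputed window sums
  # (vectorized cumsum differences per CDS interval)
  range_sum <- function(cs, lo, hi, n) {
    ok <- lo >= 1L & hi <= n
    out <- rep(NA_real_, length(lo))
    out[ok] <- cs[hi[ok]] - ifelse(lo[ok] > 1L, cs[pmax(lo[ok] - 1L, 1L)], 0)
    out
  }
  cand <- list()
  for (r in seq_len(nrow(cds))) {
    p <- cds$start[r]:cds$end[r]
    ix <- idx[[cds$chrom[r]]]
    if (cds$strand[r] == "+") {
      up <- range_sum(ix$cs_p, p + window_upstream[1], p + window_upstream[2],
                      ix$n)
      dn <- range_sum(ix$cs_p, p + window_downstream[1],
                      p + window_downstream[2], ix$n)
    } else {
      up <- range_sum(ix$cs_m, p - window_upstream[2] - k + 1L,
                      p - window_upstream[1] - k + 1L, ix$n)
      dn <- range_sum(ix$cs_m, p - window_downstream[2] - k + 1L,
                      p - window_downstream[1] - k + 1L, ix$n)
    }
    ok <- !is.na(up) & !is.na(dn)
    cand[[r]] <- cbind(up[ok], dn[ok])
  }
  cand <- do.call(rbind, cand)
  n_cand <- nrow(cand)
  if (n_cand == 0L) stop("no valid coding anchors")
  replace <- n_cand < n_used
  if (replace) message("fewer coding positions than introns: sampling with replacement")

  with_seed(derive_seed(seed, "avoidance"), {
    up_ctl <- dn_ctl <- numeric(n_controls)
    for (b in seq_len(n_controls)) {
      j <- sample.int(n_cand, n_used, replace = replace)
      up_ctl[b] <- sum(cand[j, 1])
      dn_ctl[b] <- sum(cand[j, 2])
    }
    structure(list(
      p_upstream = mean(up_ctl < up_inr),
      p_downstream = mean(dn_ctl < dn_inr),
      n_controls = n_controls, n_introns = n_used,
      intron_sum = c(upstream = up_inr, downstream = dn_inr),
      control_mean = c(upstream = mean(up_ctl), downstream = mean(dn_ctl)),
      profile = motif_profile(genome, introns, motifs)),
      class = "avoidance_result")
  })
}

#' Simulate an annotated genome for avoidance analyses
#'
#' Builds random contigs with coding intervals on both strands and intron
#' annotations inside them. Three modes: `"random"` places intron ends at
#' random coding positions with independent sequence (motifs occur at
#' background rates); `"null"` is an alias emphasising that intron anchors
#' follow exactly the control distribution; `"depleted"` additionally
#' rewrites the acceptor motifs out of the upstream and downstream windows
#' of every intron end (a planted avoidance signal). Depleted-mode introns
#' are placed on the plus strand so the rewriting stays on the coding
#' strand.
#'
#' @param n_introns Number of introns.
#' @param chrom_len Contig length (one contig per 100 introns, minimum 1).
#' @param mode `"random"`, `"null"` or `"depleted"`.
#' @param motifs Motifs to deplete in `"depleted"` mode.
#' @param window Depletion window of offsets around intron ends.
#' @param seed Seed.
#' @return A list with `genome`, `introns`, `cds`.
#' @export
simulate_genome <- function(n_introns = 60L, chrom_len = 30000L,
                            mode = c("random", "null", "depleted"),
                            motifs = c("CAG", "TAG"),
                            window = c(-50L, 30L), seed = 1L) {
  mode <- match.arg(mode)
  with_seed(derive_seed(seed, "genome"), {
    n_chrom <- max(1L, ceiling(n_introns / 100L))
    genome <- stats::setNames(
      vapply(seq_len(n_chrom), function(i) random_dna(chrom_len), character(1)),
      paste0("chr", seq_len(n_chrom)))
    margin <- 200L
    cds <- do.call(rbind, lapply(names(genome), function(ch) {
      data.frame(chrom = ch,
                 start = c(margin, margin),
                 end = c(chrom_len - margin, chrom_len - margin),
                 strand = c("+", "-"))
    }))
    if (mode == "depleted") cds <- cds[cds$strand == "+", , drop = FALSE]
    rows <- lapply(seq_len(n_introns), function(i) {
      r <- cds[sample.int(nrow(cds), 1L), ]
      a <- sample(seq.int(r$start + 150L, r$end - 150L), 1L)
      len <- sample(60:140, 1L)
      if (r$strand == "+")
        data.frame(chrom = r$chrom, start = a - len + 1L, end = a,
                   strand = "+")
      else
        data.frame(chrom = r$chrom, start = a, end = a + len - 1L,
                   strand = "-")
    })
    introns <- do.call(rbind, rows)
    if (mode == "depleted") {
      for (r in seq_len(nrow(introns))) {
        ch <- introns$chrom[r]
        a <- introns$end[r]
        lo <- max(1L, a + window[1])
        hi <- min(nchar(genome[[ch]]), a + window[2] + 2L)
        seg <- substr(genome[[ch]], lo, hi)
        # rewrite the middle A of every motif occurrence; C in the middle
        # cannot recreate a [CT]AG triplet in any overlapping frame
        repeat {
          hit <- motif_starts(seg, motifs)
          if (length(hit) == 0) break
          substr(seg, hit[1] + 1L, hit[1] + 1L) <- "C"
        }
        substr(genome[[ch]], lo, hi) <- seg
      }
    }
    list(genome = genome, introns = introns, cds = cds)
  })
}

#' Splicing efficiency binned by a sequence feature
#'
#' Assigns each record to a feature bin, summarizes the SE distribution
#' per bin, and tests the linear trend by Pearson correlation of bin
#' centers against bin means.
#'
#' @param se Numeric vector of splicing efficiencies.
#' @param feature Numeric feature (same length).
#' @param edges Bin edges (left-open, right-closed; lowest edge included).
#' @return A list: `bins` (data.frame with `center`, `n`, `mean_se`,
#'   `median_se`), `cor` (Pearson r of centers vs means), `p_value`,
#'   `flag` (set when the trend is undefined, e.g. constant SE).
#' @export
binned_se <- function(se, feature, edges) {
  stopifnot(length(se) == length(feature))
  bin <- cut(feature, edges, include.lowest = TRUE)
  centers <- (utils::head(edges, -1) + utils::tail(edges, -1)) / 2
  bins <- data.frame(
    bin = levels(bin), center = centers,
    n = as.integer(table(bin)),
    mean_se = as.numeric(tapply(se, bin, mean)),
    median_se = as.numeric(tapply(se, bin, stats::median)))
  nz <- !is.na(bins$mean_se)
  flag <- NULL
  r <- p <- NA_real_
  if (sum(nz) >= 3 && stats::sd(bins$mean_se[nz]) > 0) {
    ct <- stats::cor.test(bins$center[nz], bins$mean_se[nz])
    r <- unname(ct$estimate); p <- ct$p.value
  } else {
    flag <- "trend undefined (constant SE or too few occupied bins)"
  }
  list(bins = bins, cor = r, p_value = p, flag = flag)
}

#' Splicing-efficiency difference of ortholog introns across species
#'
#' For every intron paired with its *S. cerevisiae* ortholog of the same
#' gene, computes `delta_se = SE(ortholog) - SE(cerevisiae)` and, per
#' species, the fraction of introns spliced strictly better than the
#' cerevisiae ortholog.
#'
#' @param se_table data.frame with columns `gene`, `species`, `se`.
#' @param ref_species Reference species name.
#' @return A list: `pairs` (gene, species, delta_se), `percent_better`
#'   (per-species fraction with delta_se > 0, in percent), `n_skipped`
#'   (introns without a reference partner).
#' @export
delta_se <- function(se_table, ref_species = "S_cerevisiae") {
  ref <- se_table[se_table$species == ref_species, ]
  oth <- se_table[se_table$species != ref_species, ]
  m <- match(oth$gene, ref$gene)
  skipped <- sum(is.na(m))
  ok <- !is.na(m)
  pairs <- data.frame(gene = oth$gene[ok], species = oth$species[ok],
                      delta_se = oth$se[ok] - ref$se[m[ok]])
  pb <- 100 * tapply(pairs$delta_se, pairs$species, function(d) mean(d > 0))
  list(pairs = pairs,
       percent_better = data.frame(species = names(pb),
                                   percent_better = as.numeric(pb),
                                   row.names = NULL),
       n_skipped = skipped)
}

#' Three-class splicing-efficiency categories
#'
#' Default classes: unspliced (SE <= `zero`, exactly 0 by default),
#' intermediate (`zero` < SE <= `mid`), high (SE > `mid`). Continuous
#' model predictions never hit 0 exactly, so comparisons against
#' predictions should raise `zero` to a small detection floor.
#'
#' @param se Numeric SE vector.
#' @param mid Boundary between intermediate and high splicing.
#' @param zero Upper bound of the unspliced class.
#' @return Factor with levels `unspliced`, `intermediate`, `high`.
#' @export
se_class <- function(se, mid = 0.5, zero = 0) {
  factor(ifelse(se <= zero, "unspliced",
                ifelse(se <= mid, "intermediate", "high")),
         levels = c("unspliced", "intermediate", "high"))
}

#' Cramer's V agreement between two categorized SE vectors
#'
#' Builds the 3x3 contingency table of SE classes and computes
#' `phi_c = sqrt(chisq / (n * (k - 1)))` with `k = 3` (no continuity
#' correction).
#'
#' @param values_a,values_b Numeric SE vectors of equal length.
#' @param mid,zero Class boundaries passed to [se_class()].
#' @return A list: `table`, `chisq`, `phi_c`, `flag` (set and `phi_c` NA
#'   for degenerate tables with an all-zero margin).
#' @export
cramers_v <- function(values_a, values_b, mid = 0.5, zero = 0) {
  stopifnot(length(values_a) == length(values_b))
  tab <- table(se_class(values_a, mid, zero), se_class(values_b, mid, zero))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(table = tab, chisq = NA_real_, phi_c = NA_real_,
                flag = "degenerate table (empty margin)"))
  chisq <- suppressWarnings(
    stats::chisq.test(tab, correct = FALSE)$statistic)
  n <- sum(tab)
  k <- min(dim(tab))
  list(table = tab, chisq = unname(chisq),
       phi_c = sqrt(unname(chisq) / (n * (k - 1))), flag = NULL)
}

#' Barcode-replicate variance control
#'
#' Compares the mean within-group SE variance of variants sharing a design
#' (different barcodes) against the null distribution obtained by
#' shuffling variants into random groups of the same sizes. Only groups
#' with non-zero SE are considered.
#'
#' @param se Numeric SE vector.
#' @param group Group (design) labels, parallel to `se`.
#' @param n_shuffles Number of random shuffles (default 1e4).
#' @param seed Seed.
#' @return A list: `observed` mean within-group variance, `null` vector,
#'   `p` (fraction of shuffles at or below the observed value).
#' @export
barcode_variance_control <- function(se, group, n_shuffles = 1e4, seed = 1L) {
  keep_groups <- names(which(tapply(se, group, function(x) any(x > 0))))
  sizes <- table(group)
  if (!any(sizes[keep_groups] >= 2))
    stop("no multi-variant groups with non-zero SE")
  mean_var <- function(vals, grp) {
    v <- tapply(vals, grp, function(x) if (length(x) >= 2) stats::var(x) else NA)
    mean(v[keep_groups], na.rm = TRUE)
  }
  obs <- mean_var(se, group)
  with_seed(derive_seed(seed, "bc-variance"), {
    null <- vapply(seq_len(n_shuffles), function(i)
      mean_var(sample(se), group), numeric(1))
    list(observed = obs, null = null, p = mean(null <= obs))
  })
}

#' Randomized SE-abundance control
#'
#' Mock variants receive independent log-normal unspliced and spliced RNA
#' levels; SE and total RNA abundance are computed exactly as in the
#' quantification (SE = spliced / total, abundance = log10 of total over a
#' constant DNA frequency). Under this construction SE and abundance are
#' uncorrelated by the unspliced/spliced exchange symmetry, so the
#' reported correlation is a null control.
#'
#' @param n Number of mock variants.
#' @param meanlog,sdlog Log-normal parameters of both levels.
#' @param seed Seed.
#' @return A list: `r` (Pearson), `p_value`, and the mock `data`.
#' @export
randomized_abundance_control <- function(n = 5000L, meanlog = 0, sdlog = 1,
                                         seed = 1L) {
  if (n <= 0) stop("n must be positive")
  with_seed(derive_seed(seed, "mock-abundance"), {
    unspliced <- stats::rlnorm(n, meanlog, sdlog)
    spliced <- stats::rlnorm(n, meanlog, sdlog)
    se <- spliced / (spliced + unspliced)
    abundance <- log10(spliced + unspliced)
    ct <- stats::cor.test(se, abundance)
    list(r = unname(ct$estimate), p_value = ct$p.value,
         data = data.frame(se = se, abundance = abundance))
  })
}
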
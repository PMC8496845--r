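#' Classify a read against a single-intron variant
#'
#' Applies the three-rule junction decision: *unspliced* if both
#' exon-intron junctions align positively and the exon-exon junction does
#' not; *designed_spliced* if the exon-exon junction aligns positively and
#' neither exon-intron junction does; otherwise *undetermined* (and a
#' candidate for the cryptic-isoform search).
#'
#' @param read Read sequence.
#' @param variant One manifest row.
#' @param params An [align_params()].
#' @param threshold Junction positive-call threshold (default 0.8).
#' @return One of `"unspliced"`, `"designed_spliced"`, `"undetermined"`.
#' @export
classify_single <- function(read, variant, params = align_params(),
                            threshold = 0.8) {
  .classify_single_batch(read, variant, params, threshold)
}

.classify_single_batch <- function(seqs, variant, params = align_params(),
                                   threshold = 0.8) {
  j <- variant_junctions(variant)
  pos <- vapply(j[c("exon_intron1", "intron1_exon2", "exon_exon")],
                function(jx) junction_scores(jx, seqs, params) > threshold,
                logical(length(seqs)))
  if (length(seqs) == 1L) pos <- matrix(pos, nrow = 1)
  ei1 <- pos[, 1]; ie2 <- pos[, 2]; ee <- pos[, 3]
  out <- rep("undetermined", length(seqs))
  out[ei1 & ie2 & !ee] <- "unspliced"
  out[ee & !ei1 & !ie2] <- "designed_spliced"
  out
}

#' Classify a read against a two-intron variant
#'
#' Applies the five positive/negative junction rule-sets for the isoforms
#' of a two-intron design. Rules are evaluated most-specific first (both
#' introns, exon skipping, intron 1, intron 2, unspliced): a read with both
#' introns spliced also satisfies the single-intron conditions whenever the
#' middle exon exceeds the junction flank, so the fully spliced isoform
#' must be tested before the single-intron ones. Reads matching no rule are
#' `"unclassified"`.
#'
#' @param read Read sequence.
#' @param variant One two-intron manifest row.
#' @param params An [align_params()].
#' @param threshold Junction positive-call threshold.
#' @return One of `"both"`, `"exon_skipping"`, `"intron1"`, `"intron2"`,
#'   `"unspliced"`, `"unclassified"`.
#' @export
classify_two_intron <- function(read, variant, params = align_params(),
                                threshold = 0.8) {
  .classify_two_batch(read, variant, params, threshold)
}

.classify_two_batch <- function(seqs, variant, params = align_params(),
                                threshold = 0.8) {
  if (is.na(variant$i2_start))
    stop("variant is not a two-intron design")
  j <- variant_junctions(variant)
  pos <- vapply(j, function(jx)
    junction_scores(jx, seqs, params) > threshold, logical(length(seqs)))
  if (length(seqs) == 1L) pos <- matrix(pos, nrow = 1, dimnames = list(NULL, names(j)))
  g <- function(nm) pos[, nm]
  out <- rep("unclassified", length(seqs))
  both <- g("exon1_exon2_exon3") & !g("exon1_intron1") & !g("intron1_exon2") &
    !g("exon2_intron2") & !g("intron2_exon3")
  skip <- g("exon1_exon3") & !g("exon1_intron1") & !g("intron2_exon3")
  i1 <- g("exon1_exon2") & !g("exon1_intron1") & !g("intron1_exon2")
  i2 <- g("exon2_exon3") & !g("exon2_intron2") & !g("intron2_exon3")
  uns <- g("exon1_intron1") & g("intron1_exon2") & g("exon2_intron2") &
    g("intron2_exon3") & !g("exon1_exon2") & !g("exon2_exon3")
  out[uns] <- "unspliced"
  out[i2] <- "intron2"
  out[i1] <- "intron1"
  out[skip] <- "exon_skipping"
  out[both] <- "both"
  out
}

#' Search undetermined reads for cryptic spliced isoforms
#'
#' Runs the gapped design alignment on each read and clusters the calls by
#' the exact (5' end, 3' end) pair of the inferred intron. A cluster whose
#' ends both equal the designed intron ends is reassigned to the designed
#' isoform.
#'
#' @param seqs Character vector of (unique) undetermined read sequences.
#' @param variant One manifest row.
#' @param params Cryptic-mode alignment parameters.
#' @param score_threshold,max_mismatch,score_cmp See
#'   [gapped_design_alignment()].
#' @return Character vector parallel to `seqs`: `"cryptic:<start>-<end>"`,
#'   `"designed_spliced"` or `"undetermined"`.
#' @export
find_cryptic <- function(seqs, variant,
                         params = cryptic_params(),
                         score_threshold = 0.7, max_mismatch = 6,
                         score_cmp = "lt") {
  if (length(seqs) == 0) return(character(0))
  design <- oligo_seq(variant)
  out <- rep("undetermined", length(seqs))
  for (i in seq_along(seqs)) {
    g <- gapped_design_alignment(seqs[i], design, params, score_threshold,
                                 max_mismatch, score_cmp)
    if (!g$call) next
    g$intron <- .canonicalize_gap(design, g$intron[1], g$intron[2],
                                  variant$i1_start)
    if (!is.na(variant$i1_start) && g$intron[1] == variant$i1_start &&
        g$intron[2] == variant$i1_end) {
      out[i] <- "designed_spliced"
    } else {
      out[i] <- sprintf("cryptic:%d-%d", g$intron[1], g$intron[2])
    }
  }
  out
}

# Equal-score gap placements are ambiguous when the bases flanking the
# gap repeat (design[a-1] == design[b] allows sliding left, design[a] ==
# design[b+1] sliding right). Slide the inferred gap toward the designed
# donor position: biologically the 5'SS is the anchored end.
.canonicalize_gap <- function(design, a, b, target_start) {
  if (is.na(target_start)) return(c(a, b))
  n <- nchar(design)
  while (a > target_start &&
         substr(design, a - 1L, a - 1L) == substr(design, b, b)) {
    a <- a - 1L
    b <- b - 1L
  }
  while (a < target_start && b + 1L <= n &&
         substr(design, a, a) == substr(design, b + 1L, b + 1L)) {
    a <- a + 1L
    b <- b + 1L
  }
  c(a, b)
}

#' Classify all reads of one sample into isoform counts
#'
#' Decodes barcodes, dereplicates, classifies unique reads per variant
#' (single- or two-intron rules as appropriate), forwards undetermined
#' single-intron reads to the cryptic search, and tallies counts per
#' variant x isoform x index x repeat.
#'
#' @param reads Read data.frame (`seq`, `sample`, `rep`, `index`).
#' @param manifest Library manifest.
#' @param index A [barcode_index()]; built from the manifest when NULL.
#' @param params Junction alignment parameters.
#' @param junction_threshold Positive-call threshold.
#' @param cryptic_align_params,cryptic_score_threshold,cryptic_max_mismatch,cryptic_score_cmp
#'   Cryptic-search settings, see [find_cryptic()].
#' @param search_cryptic Run the cryptic search on undetermined reads.
#' @return A list with `counts` (variant_id, isoform, index, rep, count)
#'   and `drop_log` (barcode decoding failures).
#' @export
classify_sample <- function(reads, manifest, index = NULL,
                            params = align_params(),
                            junction_threshold = 0.8,
                            cryptic_align_params = cryptic_params(),
                            cryptic_score_threshold = 0.7,
                            cryptic_max_mismatch = 6,
                            cryptic_score_cmp = "lt",
                            search_cryptic = TRUE) {
  if (is.null(index))
    index <- barcode_index(manifest$barcode, manifest$variant_id)
  dec <- decode_barcodes(reads$seq, index)
  drop_log <- table(dec$drop_reason, useNA = "no")
  keep <- !is.na(dec$variant_id)
  reads <- reads[keep, , drop = FALSE]
  vid <- dec$variant_id[keep]

  res <- list()
  for (v_id in unique(vid)) {
    variant <- manifest[manifest$variant_id == v_id, ]
    sel <- vid == v_id
    rr <- reads[sel, , drop = FALSE]
    u <- dereplicate(rr$seq)
    if (is.na(variant$i2_start)) {
      cls <- .classify_single_batch(u$seq, variant, params,
                                    junction_threshold)
      und <- which(cls == "undetermined")
      if (search_cryptic && length(und) > 0) {
        cls[und] <- find_cryptic(u$seq[und], variant, cryptic_align_params,
                                 cryptic_score_threshold,
                                 cryptic_max_mismatch, cryptic_score_cmp)
      }
      cls[cls == "designed_spliced"] <- "designed"
    } else {
      cls <- .classify_two_batch(u$seq, variant, params, junction_threshold)
    }
    iso_per_read <- cls[match(rr$seq, u$seq)]
    tab <- stats::aggregate(
      list(count = rep(1L, nrow(rr))),
      by = list(isoform = iso_per_read, index = rr$index, rep = rr$rep),
      FUN = sum)
    tab$variant_id <- v_id
    res[[length(res) + 1L]] <- tab
  }
  counts <- do.call(rbind, res)
  counts <- counts[, c("variant_id", "isoform", "index", "rep", "count")]
  rownames(counts) <- NULL
  list(counts = counts, drop_log = drop_log)
}

#' Per-variant splicing efficiencies from isoform counts
#'
#' For each (index, repeat) cell, an isoform's splicing efficiency is its
#' read count over the variant's total read count in that cell (by default
#' including undetermined reads in the denominator). Repeats within an
#' index are combined by a read-count-weighted mean, indices by the median
#' over indices with data. A variant with fewer than `min_reads` total
#' reads in the sample is flagged `low_reads` and its efficiencies are
#' undefined (NA), not zero.
#'
#' @param counts Counts data.frame from [classify_sample()].
#' @param min_reads Read floor per variant (default 10).
#' @param denominator `"all"` (default) or `"classified"` (excludes
#'   undetermined/unclassified reads from the totals).
#' @return A data.frame: `variant_id`, `isoform`, `se`, `n_reads`,
#'   `low_reads`.
#' @export
splicing_efficiency <- function(counts, min_reads = 10L,
                                denominator = c("all", "classified")) {
  denominator <- match.arg(denominator)
  out <- list()
  for (v_id in unique(counts$variant_id)) {
    cc <- counts[counts$variant_id == v_id, , drop = FALSE]
    cells <- unique(cc[, c("index", "rep")])
    tot <- vapply(seq_len(nrow(cells)), function(i) {
      ci <- cc$index == cells$index[i] & cc$rep == cells$rep[i]
      if (denominator == "classified")
        ci <- ci & !cc$isoform %in% c("undetermined", "unclassified")
      sum(cc$count[ci])
    }, numeric(1))
    n_total <- sum(cc$count)
    low <- n_total < min_reads
    isoforms <- setdiff(unique(cc$isoform), character(0))
    for (iso in isoforms) {
      if (low) {
        se <- NA_real_
      } else {
        per_index <- vapply(unique(cells$index), function(ix) {
          rws <- which(cells$index == ix & tot > 0)
          if (length(rws) == 0) return(NA_real_)
          se_ir <- vapply(rws, function(i) {
            cnt <- cc$count[cc$index == cells$index[i] &
                            cc$rep == cells$rep[i] & cc$isoform == iso]
            if (length(cnt) == 0) 0 else cnt / tot[i]
          }, numeric(1))
          sum(se_ir * tot[rws]) / sum(tot[rws])
        }, numeric(1))
        se <- stats::median(per_index, na.rm = TRUE)
      }
      out[[length(out) + 1L]] <- data.frame(
        variant_id = v_id, isoform = iso, se = se,
        n_reads = n_total, low_reads = low)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Suppress low-level cryptic isoform clusters
#'
#' Cryptic clusters are reported only when their aggregated splicing
#' efficiency exceeds `floor` (default 0.01, strict).
#'
#' @param se_table Output of [splicing_efficiency()].
#' @param floor Reporting floor.
#' @return The filtered table.
#' @export
suppress_low_cryptic <- function(se_table, floor = 0.01) {
  cr <- startsWith(se_table$isoform, "cryptic:")
  drop <- cr & (!is.na(se_table$se) & se_table$se <= floor)
  se_table[!drop, , drop = FALSE]
}

#' Total RNA abundance of a variant
#'
#' `log10(RNA frequency / DNA frequency)` of the variant's within-sample
#' relative read frequencies.
#'
#' @param rna_freq,dna_freq Relative frequencies (> 0).
#' @return Numeric abundance; NA (with a warning) when a frequency is 0.
#' @export
rna_abundance <- function(rna_freq, dna_freq) {
  out <- ifelse(rna_freq > 0 & dna_freq > 0,
                log10(rna_freq / dna_freq), NA_real_)
  if (anyNA(out)) warning("zero frequencies yield undefined abundance")
  out
}

#' Zero out isoforms that also appear in the DNA control
#'
#' An intended or cryptic isoform with splicing efficiency above
#' `threshold` in the DNA sample is a synthesis or alignment artifact; its
#' RNA value is set to zero and flagged.
#'
#' @param se_rna RNA-sample SE table.
#' @param se_dna DNA-sample SE table (same pipeline).
#' @param threshold DNA SE above which (strictly) the isoform is zeroed.
#' @return `se_rna` with an added `dna_artifact` flag column.
#' @export
dna_artifact_filter <- function(se_rna, se_dna, threshold = 0.05) {
  spliced_dna <- se_dna[!se_dna$isoform %in%
                          c("unspliced", "undetermined", "unclassified") &
                          !is.na(se_dna$se) & se_dna$se > threshold, ]
  key_rna <- paste(se_rna$variant_id, se_rna$isoform)
  key_bad <- paste(spliced_dna$variant_id, spliced_dna$isoform)
  hit <- key_rna %in% key_bad
  se_rna$dna_artifact <- hit
  se_rna$se[hit] <- 0
  se_rna
}

#' End-to-end quantification of a simulated or real experiment
#'
#' Splits reads by sample, classifies RNA and DNA with the identical
#' pipeline, aggregates splicing efficiencies, suppresses low cryptic
#' clusters, applies the DNA artifact filter, and computes total RNA
#' abundance per variant.
#'
#' @param reads Combined read data.frame (`seq`, `sample`, `rep`, `index`).
#' @param manifest Library manifest.
#' @param min_reads Read floor per variant and sample.
#' @param cryptic_floor Cryptic reporting floor.
#' @param dna_threshold DNA artifact threshold.
#' @param ... Further arguments to [classify_sample()].
#' @return A list with `se` (RNA SE table with artifact flags),
#'   `se_dna`, `abundance` (per variant), `counts`, `drop_log`.
#' @export
quantify_experiment <- function(reads, manifest, min_reads = 10L,
                                cryptic_floor = 0.01, dna_threshold = 0.05,
                                ...) {
  rna <- reads[reads$sample == "RNA", , drop = FALSE]
  dna <- reads[reads$sample == "DNA", , drop = FALSE]
  index <- barcode_index(manifest$barcode, manifest$variant_id)
  cls_rna <- classify_sample(rna, manifest, index, ...)
  se_rna <- splicing_efficiency(cls_rna$counts, min_reads)
  se_rna <- suppress_low_cryptic(se_rna, cryptic_floor)

  se_dna <- NULL
  abundance <- NULL
  if (nrow(dna) > 0) {
    cls_dna <- classify_sample(dna, manifest, index, ...)
    se_dna <- splicing_efficiency(cls_dna$counts, min_reads)
    se_rna <- dna_artifact_filter(se_rna, se_dna, dna_threshold)
    rna_n <- tapply(cls_rna$counts$count, cls_rna$counts$variant_id, sum)
    dna_n <- tapply(cls_dna$counts$count, cls_dna$counts$variant_id, sum)
    ids <- union(names(rna_n), names(dna_n))
    rf <- ifelse(is.na(rna_n[ids]), 0, rna_n[ids]) / sum(rna_n)
    df <- ifelse(is.na(dna_n[ids]), 0, dna_n[ids]) / sum(dna_n)
    abundance <- data.frame(variant_id = ids,
                            abundance = suppressWarnings(rna_abundance(rf, df)),
                            row.names = NULL)
  } else {
    warning("no DNA sample: abundance and DNA artifact filter skipped")
  }
  list(se = se_rna, se_dna = se_dna, abundance = abundance,
       counts = cls_rna$counts, drop_log = cls_rna$drop_log)
}
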
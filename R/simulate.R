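#' Ground-truth isoform mixtures and copy numbers for a library
#'
#' Draws the latent state the simulator generates reads from: a per-variant
#' copy number (log-normal, emulating the wide abundance distribution of a
#' pooled library) and a per-variant isoform mixture. Single-intron
#' variants get a bimodal designed-spliced fraction (most variants are
#' either mostly spliced or hardly spliced), an optional low-level cryptic
#' isoform at the first HAG motif downstream of the designed 3'SS, and the
#' remainder unspliced; negative controls are essentially unspliced;
#' two-intron variants get a Dirichlet mixture over the five isoform
#' classes (unspliced, intron 1 only, intron 2 only, exon skipping, both).
#'
#' @param manifest Library manifest (data.frame of variant rows).
#' @param seed Seed.
#' @param copy_meanlog,copy_sdlog Log-normal copy-number parameters.
#' @param se_mode `"sequence"` (default): the designed-spliced fraction is
#'   a noisy logistic function of the variant's regulatory features
#'   (consensus branch site, donor and acceptor, intronic GC, U content
#'   upstream of the 3'SS, BS-to-3'SS distance), emulating
#'   sequence-determined splicing; `"random"`: a bimodal mixture
#'   independent of sequence.
#' @param p_dead In `"random"` mode, probability that a single-intron
#'   variant is essentially unspliced.
#' @param p_cryptic Probability that a single-intron variant carries a
#'   cryptic isoform (given a downstream HAG motif exists).
#' @param two_intron_alpha Dirichlet concentration over the five two-intron
#'   isoform classes.
#' @param nmd_strength Coupling of steady-state RNA level to splicing:
#'   the RNA-sample copy number is the DNA copy number times
#'   `exp(nmd_strength * total spliced fraction)`, emulating the faster
#'   turnover of unspliced transcripts; 0 disables the coupling (the DNA
#'   sample always uses the raw copy number).
#' @param rna_noise Log-scale standard deviation of multiplicative
#'   expression noise on the RNA-sample copy number, independent of
#'   splicing; keeps the SE-abundance correlation away from 1.
#' @return A list of class `ground_truth` with `copy_number` and `isoforms`
#'   data.frames. Isoform rows carry explicit excision coordinates
#'   (`s1`,`e1`,`s2`,`e2`, oligo 1-based closed; NA when absent).
#' @export
simulate_ground_truth <- function(manifest, seed = 1L,
                                  copy_meanlog = 0, copy_sdlog = 1,
                                  se_mode = c("sequence", "random"),
                                  p_dead = 0.35, p_cryptic = 0.25,
                                  two_intron_alpha = c(3, 1, 1, 0.4, 0.8),
                                  nmd_strength = 1.2, rna_noise = 0.7) {
  se_mode <- match.arg(se_mode)
  with_seed(derive_seed(seed, "ground-truth"), {
    n <- nrow(manifest)
    copy <- data.frame(variant_id = manifest$variant_id,
                       copy = stats::rlnorm(n, copy_meanlog, copy_sdlog))
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      v <- manifest[i, ]
      if (!is.na(v$i2_start)) {
        a <- stats::rgamma(5, shape = two_intron_alpha)
        fr <- a / sum(a)
        rows[[i]] <- data.frame(
          variant_id = v$variant_id,
          isoform = c("unspliced", "intron1", "intron2", "exon_skipping",
                      "both"),
          s1 = c(NA, v$i1_start, NA, v$i1_start, v$i1_start),
          e1 = c(NA, v$i1_end, NA, v$i2_end, v$i1_end),
          s2 = c(NA, NA, v$i2_start, NA, v$i2_start),
          e2 = c(NA, NA, v$i2_end, NA, v$i2_end),
          fraction = fr)
      } else {
        designed <- if (v$subset == "negative_control") {
          stats::rbeta(1, 0.5, 30)
        } else if (se_mode == "sequence") {
          .sequence_determined_se(v, seed)
        } else if (stats::runif(1) < p_dead) {
          stats::rbeta(1, 0.5, 30)
        } else {
          stats::rbeta(1, 2, 1.3)
        }
        cr <- 0
        cr_end <- NA_integer_
        if (v$subset != "negative_control" && stats::runif(1) < p_cryptic) {
          h <- first_downstream_hag(oligo_seq(v), v$i1_end)
          if (!is.na(h)) {
            cr <- stats::rbeta(1, 1, 25)
            cr_end <- h + 2L
          }
        }
        tot <- designed + cr
        if (tot > 0.98) {
          designed <- designed / tot * 0.98
          cr <- cr / tot * 0.98
        }
        rows[[i]] <- data.frame(
          variant_id = v$variant_id,
          isoform = c("unspliced", "designed",
                      if (cr > 0) "cryptic" else NULL),
          s1 = c(NA, v$i1_start, if (cr > 0) v$i1_start else NULL),
          e1 = c(NA, v$i1_end, if (cr > 0) cr_end else NULL),
          s2 = NA_integer_, e2 = NA_integer_,
          fraction = c(1 - designed - cr, designed,
                       if (cr > 0) cr else NULL))
      }
    }
    iso <- do.call(rbind, rows)
    iso <- iso[iso$fraction > 0, , drop = FALSE]
    spliced_frac <- tapply(iso$fraction[iso$isoform != "unspliced"],
                           iso$variant_id[iso$isoform != "unspliced"], sum)
    sf <- spliced_frac[copy$variant_id]
    sf[is.na(sf)] <- 0
    copy$rna_copy <- copy$copy *
      exp(nmd_strength * as.numeric(sf) + stats::rnorm(n, 0, rna_noise))
    structure(list(copy_number = copy, isoforms = iso),
              class = "ground_truth")
  })
}

# Designed-spliced fraction as a noisy logistic of regulatory features:
# the consensus branch site dominates, intronic GC represses, the U tract
# upstream of the 3'SS and a short BS-to-3'SS distance activate. A
# score-dependent dead mode (designs whose weak sites fail outright)
# makes the realized distribution bimodal: most variants end up mostly
# spliced or hardly spliced. The noise term is calibrated so that
# predictability from features is capped near the assay's replicate
# reproducibility (barcode-replicate r ~ 0.76). The stochastic draws are
# seeded from the variable-region sequence, so variants sharing a design
# (barcode replicates) share the same latent splicing state.
.sequence_determined_se <- function(v, seed = 1L) {
  oligo <- oligo_seq(v)
  intron <- substr(oligo, v$i1_start, v$i1_end)
  u20 <- base_content(substr(oligo, max(v$i1_start, v$i1_end - 22L),
                             v$i1_end - 3L), "T")
  # BS-to-3'SS distance: recorded for combinatorial designs, located by
  # the consensus-match scan for natural-intron insertions
  d3 <- v$bs_to_3ss
  if (is.na(d3)) {
    bs <- .find_branch_site(intron)
    if (!is.null(bs)) d3 <- nchar(intron) - bs$end
  }
  det <- -1.4 +
    1.8 * (!is.na(v$branch) && v$branch == "TACTAAC") +
    0.9 * isTRUE(is.na(v$branch)) + # natural introns carry a working BS
    0.7 * (!is.na(v$five_ss) && v$five_ss == "GTATGT") +
    0.3 * (!is.na(v$three_ss) && v$three_ss %in% c("TAG", "CAG")) -
    4.0 * (gc_content(intron) - 0.4) +
    1.5 * u20 +
    0.5 * (!is.na(d3) && d3 <= 30L)
  with_seed(derive_seed(seed, paste0("se:", v$region)), {
    if (stats::runif(1) < stats::plogis(-det - 0.8))
      stats::rbeta(1, 0.5, 50)
    else
      stats::plogis(det + stats::rnorm(1, sd = 0.65))
  })
}

#' First HAG motif start strictly downstream of a position
#'
#' @param oligo Oligo sequence.
#' @param after Last intron base; the scan starts so the motif's final G
#'   lies beyond it.
#' @param min_exon Minimal exonic tail to leave after the motif (default
#'   20: a shorter tail cannot anchor the gapped alignment that detects
#'   the cryptic intron, so such sites are undetectable by construction).
#' @return Start offset of the first `[ACT]AG` motif, or NA.
#' @export
first_downstream_hag <- function(oligo, after, min_exon = 20L) {
  n <- nchar(oligo)
  hits <- motif_starts(oligo, c("AAG", "CAG", "TAG"))
  hits <- hits[hits > after & hits + 2L <= n - min_exon]
  if (length(hits) == 0) NA_integer_ else hits[1]
}

#' Add a cryptic isoform to a ground truth
#'
#' Adds an isoform using the designed 5'SS with a 3' end shifted by
#' `alt_3ss_offset` nt; existing fractions are scaled down by
#' `1 - fraction` so the mixture still sums to one.
#'
#' @param truth A `ground_truth`.
#' @param variant One manifest row.
#' @param alt_3ss_offset Signed shift of the 3' intron end in nt.
#' @param fraction Fraction of the new isoform.
#' @param override Skip the check that the shifted end lies on a HAG motif.
#' @return The updated `ground_truth`.
#' @export
inject_cryptic <- function(truth, variant, alt_3ss_offset, fraction,
                           override = FALSE) {
  if (fraction == 0) return(truth)
  stopifnot(fraction > 0, fraction < 1)
  oligo <- oligo_seq(variant)
  new_end <- variant$i1_end + as.integer(alt_3ss_offset)
  if (new_end <= variant$i1_start + 5L || new_end > nchar(oligo) - 1L)
    stop("shifted 3' end falls outside the variable region")
  if (!override) {
    triplet <- substr(oligo, new_end - 2L, new_end)
    if (!triplet %in% c("AAG", "CAG", "TAG"))
      stop(sprintf("shifted 3' end does not land on a HAG motif (%s); use override = TRUE",
                   triplet))
  }
  iso <- truth$isoforms
  sel <- iso$variant_id == variant$variant_id
  iso$fraction[sel] <- iso$fraction[sel] * (1 - fraction)
  iso <- rbind(iso, data.frame(variant_id = variant$variant_id,
                               isoform = "cryptic",
                               s1 = variant$i1_start, e1 = new_end,
                               s2 = NA_integer_, e2 = NA_integer_,
                               fraction = fraction))
  truth$isoforms <- iso
  truth
}

.isoform_seq <- function(oligo, iso_row) {
  starts <- c(iso_row$s1, iso_row$s2)
  ends <- c(iso_row$e1, iso_row$e2)
  keep <- !is.na(starts)
  if (!any(keep)) return(oligo)
  splice_out(oligo, starts[keep], ends[keep])
}

#' Simulate one merged-amplicon sample
#'
#' Reads are drawn multinomially across variants by copy number, then
#' across isoforms by the truth fractions (DNA samples are always
#' unspliced). Spliced reads have the intron(s) excised at the truth
#' coordinates; i.i.d. substitution errors are applied. Reads are emitted
#' pre-merged and adapter-trimmed, starting at the barcode.
#'
#' @param manifest Library manifest.
#' @param truth A `ground_truth`.
#' @param n_reads Total reads to draw.
#' @param sample_type `"RNA"` or `"DNA"`.
#' @param error_rate Per-base substitution probability.
#' @param n_index Number of control indexes reads are split across.
#' @param repeat_id Biological repeat label.
#' @param seed Seed.
#' @return A list with `reads` (data.frame: `seq`, `sample`, `rep`,
#'   `index`) and `truth_counts` (realized reads per variant x isoform).
#' @export
simulate_sample <- function(manifest, truth, n_reads,
                            sample_type = c("RNA", "DNA"),
                            error_rate = 0.001, n_index = 4L, repeat_id = 1L,
                            seed = 1L) {
  sample_type <- match.arg(sample_type)
  if (n_reads <= 0) stop("n_reads must be positive")
  iso <- truth$isoforms
  bad <- tapply(iso$fraction, iso$variant_id, function(f)
    any(f < 0) || abs(sum(f) - 1) > 1e-8)
  if (any(bad)) stop("isoform fraction vectors must be nonnegative and sum to 1")
  with_seed(derive_seed(seed, paste0("sample-", sample_type, repeat_id)), {
    cn <- truth$copy_number
    m <- match(cn$variant_id, manifest$variant_id)
    stopifnot(!anyNA(m))
    wt <- if (sample_type == "RNA" && !is.null(cn$rna_copy))
      cn$rna_copy else cn$copy
    v_draw <- stats::rmultinom(1, n_reads, wt)[, 1]

    out_seq <- character(0)
    tc <- list()
    for (k in which(v_draw > 0)) {
      vid <- cn$variant_id[k]
      v <- manifest[m[k], ]
      oligo <- oligo_seq(v)
      if (sample_type == "DNA") {
        grp <- data.frame(variant_id = vid, isoform = "unspliced",
                          count = v_draw[k])
        out_seq <- c(out_seq, rep(oligo, v_draw[k]))
      } else {
        vi <- iso[iso$variant_id == vid, , drop = FALSE]
        cnts <- stats::rmultinom(1, v_draw[k], vi$fraction)[, 1]
        seqs <- vapply(seq_len(nrow(vi)), function(j)
          .isoform_seq(oligo, vi[j, ]), character(1))
        out_seq <- c(out_seq, rep(seqs, cnts))
        grp <- data.frame(variant_id = vid, isoform = vi$isoform,
                          count = cnts)
      }
      tc[[length(tc) + 1L]] <- grp
    }
    out_seq <- .apply_substitutions(out_seq, error_rate)
    n <- length(out_seq)
    reads <- data.frame(seq = out_seq, sample = sample_type,
                        rep = as.integer(repeat_id),
                        index = sample.int(n_index, n, replace = TRUE),
                        stringsAsFactors = FALSE)
    reads <- reads[sample.int(n), , drop = FALSE]
    rownames(reads) <- NULL
    truth_counts <- do.call(rbind, tc)
    truth_counts <- truth_counts[truth_counts$count > 0, , drop = FALSE]
    rownames(truth_counts) <- NULL
    list(reads = reads, truth_counts = truth_counts)
  })
}

.apply_substitutions <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0) return(seqs)
  L <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), L, error_rate)
  for (i in which(nerr > 0)) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(L[i], nerr[i])
    for (p in pos) s[p] <- sample(setdiff(DNA_BASES, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Simulate a full experiment (RNA repeats plus a DNA control)
#'
#' @param manifest Library manifest.
#' @param truth A `ground_truth`.
#' @param n_reads_rna Reads per RNA repeat.
#' @param n_reads_dna Reads for the DNA sample (default: `n_reads_rna / 5`,
#'   mirroring the lower depth of DNA controls).
#' @param n_repeats Number of biological RNA repeats.
#' @param error_rate Per-base substitution probability.
#' @param seed Seed.
#' @return A list with `reads` (all samples row-bound) and `truth_counts`.
#' @export
simulate_experiment <- function(manifest, truth, n_reads_rna,
                                n_reads_dna = max(1L, round(n_reads_rna / 5)),
                                n_repeats = 2L, error_rate = 0.001,
                                seed = 1L) {
  parts <- lapply(seq_len(n_repeats), function(r)
    simulate_sample(manifest, truth, n_reads_rna, "RNA", error_rate,
                    repeat_id = r, seed = derive_seed(seed, 100L + r)))
  dna <- simulate_sample(manifest, truth, n_reads_dna, "DNA", error_rate,
                         repeat_id = 1L, seed = derive_seed(seed, 200L))
  reads <- rbind(do.call(rbind, lapply(parts, `[[`, "reads")), dna$reads)
  rownames(reads) <- NULL
  tc <- do.call(rbind, c(lapply(seq_along(parts), function(r)
    cbind(parts[[r]]$truth_counts, sample = "RNA", rep = r)),
    list(cbind(dna$truth_counts, sample = "DNA", rep = 1L))))
  rownames(tc) <- NULL
  list(reads = reads, truth_counts = tc)
}

#' Write simulated reads as FASTQ
#'
#' Sample, repeat and index labels are encoded in the read headers
#' (`sample=RNA rep=1 idx=2`); base qualities are constant. With
#' `index_prefix = TRUE` the index is instead prepended to the read as a
#' literal 8-nt sequence tag.
#'
#' @param reads Read data.frame from [simulate_sample()].
#' @param path Output path.
#' @param index_prefix Emit the control index as an 8-nt read prefix.
#' @param index_tags Character vector of index tag sequences (used when
#'   `index_prefix = TRUE`).
#' @return The path, invisibly.
#' @export
write_reads_fastq <- function(reads, path, index_prefix = FALSE,
                              index_tags = c("ACGTACGT", "TGCATGCA",
                                             "GATCGATC", "CTAGCTAG")) {
  seqs <- reads$seq
  if (index_prefix) seqs <- paste0(index_tags[reads$index], seqs)
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- sprintf("read%06d sample=%s rep=%d idx=%d",
                      seq_along(seqs), reads$sample, reads$rep, reads$index)
  q <- Biostrings::PhredQuality(vapply(nchar(seqs), function(L)
    paste(rep("I", L), collapse = ""), character(1)))
  qx <- Biostrings::QualityScaledDNAStringSet(x, q)
  Biostrings::writeQualityScaledXStringSet(qx, path)
  invisible(path)
}

#' Read simulated FASTQ back into a read table
#'
#' @param path FASTQ path written by [write_reads_fastq()].
#' @return A read data.frame (`seq`, `sample`, `rep`, `index`).
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  h <- names(x)
  grab <- function(key) sub(sprintf(".*%s=([A-Za-z0-9]+).*", key), "\\1", h)
  data.frame(seq = as.character(x), sample = grab("sample"),
             rep = as.integer(grab("rep")), index = as.integer(grab("idx")),
             stringsAsFactors = FALSE)
}
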
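#' Alignment scoring parameters
#'
#' Match/mismatch scores plus affine gap costs in the Matlab `swalign`
#' convention: a gap of length L costs `gap_open + (L - 1) * gap_extend`.
#' Defaults are the nucleotide defaults implicitly used for junction
#' scoring (match +5, mismatch -4, gap penalty 8). The cryptic-intron
#' search uses [cryptic_params()].
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (negative).
#' @param gap_open Cost of the first gap position (positive).
#' @param gap_extend Cost of each additional gap position (positive).
#' @return A list of class `align_params`.
#' @export
align_params <- function(match = 5, mismatch = -4, gap_open = 8,
                         gap_extend = 8) {
  stopifnot(match > 0, gap_open > 0, gap_extend > 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "align_params")
}

#' Default parameters for the cryptic-intron gapped alignment
#'
#' A moderate gap-opening cost with a cheap extension. The opening must
#' stay below the alignment benefit of the 17-nt exon upstream of the
#' intron (85 points at match +5), otherwise the optimizer drops or
#' misaligns the 5' prefix instead of opening the intron gap, and no gap
#' is ever reported; with open 12 / extend 0.25, gaps up to ~290 nt are
#' bridgeable while a single-base gap still costs more than a mismatch,
#' so isolated sequencing errors remain substitutions and the spliced-out
#' segment surfaces as one long uninterrupted gap.
#'
#' @param gap_open,gap_extend Gap costs (see [align_params()]).
#' @return An [align_params()] object.
#' @export
cryptic_params <- function(gap_open = 12, gap_extend = 0.25) {
  align_params(gap_open = gap_open, gap_extend = gap_extend)
}

# substitution matrix over A/C/G/T/N where N matches nothing
.sub_matrix <- function(params) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(params$mismatch, 5, 5, dimnames = list(b, b))
  diag(m)[1:4] <- params$match
  m
}

# Biostrings charges gapOpening + L * gapExtension for a gap of length L;
# the swalign convention charges gap_open + (L - 1) * gap_extend
.pa <- function(pattern, subject, params, type = "local", score_only = FALSE) {
  Biostrings::pairwiseAlignment(
    pattern = pattern, subject = subject, type = type,
    substitutionMatrix = .sub_matrix(params),
    gapOpening = params$gap_open - params$gap_extend,
    gapExtension = params$gap_extend,
    scoreOnly = score_only)
}

#' Local Smith-Waterman alignment
#'
#' Maximal local alignment under affine gap costs. `N` matches nothing.
#' Empty input yields score 0.
#'
#' @param a,b DNA sequences.
#' @param params An [align_params()].
#' @return A list with `score`, `a_range` and `b_range` (1-based closed
#'   intervals of the aligned region in each input) and `mismatches`.
#' @export
smith_waterman <- function(a, b, params = align_params()) {
  if (nchar(a) == 0L || nchar(b) == 0L)
    return(list(score = 0, a_range = c(NA, NA), b_range = c(NA, NA),
                mismatches = 0L))
  aln <- .pa(a, b, params)
  sc <- Biostrings::score(aln)
  if (sc <= 0)
    return(list(score = 0, a_range = c(NA, NA), b_range = c(NA, NA),
                mismatches = 0L))
  pr <- aln@pattern@range
  sr <- aln@subject@range
  list(score = sc,
       a_range = c(BiocGenerics::start(pr), BiocGenerics::end(pr)),
       b_range = c(BiocGenerics::start(sr), BiocGenerics::end(sr)),
       mismatches = Biostrings::nmismatch(aln))
}

#' Normalized junction alignment score
#'
#' `SW(junction, read) / SW(junction, junction)`: 1 when the read contains
#' the junction verbatim, and `> threshold` (default 0.8) flags the
#' junction as positively aligned. Junction windows truncated at oligo ends
#' are automatically renormalized through the self-score.
#'
#' @param junction Reference junction sequence (typically 40 nt).
#' @param read Read sequence.
#' @param params An [align_params()].
#' @param threshold Positive-call threshold on the normalized score.
#' @return A list with `raw`, `self`, `normalized` and `positive`.
#' @export
junction_score <- function(junction, read, params = align_params(),
                           threshold = 0.8) {
  stopifnot(nchar(junction) > 0L)
  self <- .pa(junction, junction, params, score_only = TRUE)
  raw <- if (nchar(read) == 0L) 0 else
    .pa(read, junction, params, score_only = TRUE)
  raw <- max(raw, 0)
  norm <- raw / self
  list(raw = raw, self = self, normalized = norm,
       positive = norm > threshold)
}

# vectorized normalized junction scores for many reads against one junction
junction_scores <- function(junction, reads, params = align_params()) {
  self <- .pa(junction, junction, params, score_only = TRUE)
  raw <- .pa(Biostrings::DNAStringSet(reads), junction, params,
             score_only = TRUE)
  pmax(raw, 0) / self
}

#' Gapped alignment of a read against its full unspliced design
#'
#' Fits the read end-to-end against the design (global on the read, local
#' on the design, i.e. free end gaps on the design) with a high gap-opening
#' cost and a cheap extension, so that a spliced-out segment shows up as a
#' single long uninterrupted gap on the reference. A read whose normalized
#' score (raw score over the design self-score) falls on the configured
#' side of `score_threshold` with fewer than `max_mismatch` mismatches is
#' called a cryptic spliced isoform, its intron being the longest
#' uninterrupted reference gap (ties broken toward the 5' end).
#'
#' Note the direction of the score test: under this fit alignment an
#' unspliced read scores ~1, while a spliced read pays the long-gap
#' penalty and scores low, so the call condition is score *below* the
#' threshold (`score_cmp = "lt"`, the default).
#'
#' @param read Read sequence.
#' @param design Full unspliced oligo sequence.
#' @param params Alignment parameters; default [cryptic_params()].
#' @param score_threshold Normalized-score call threshold (default 0.7).
#' @param max_mismatch Mismatch bound; the call requires strictly fewer
#'   mismatches than this (default 6).
#' @param score_cmp `"lt"` (default) or `"gt"`: side of `score_threshold`
#'   on which a read is called cryptic.
#' @param denominator `"design"` (default) or `"read"`: self-score used to
#'   normalize.
#' @return A list of class `gap_alignment`: `normalized`, `mismatches`,
#'   `gaps` (data.frame of reference gap intervals, 1-based closed),
#'   `intron` (the candidate intron interval or NULL) and `call`.
#' @export
gapped_design_alignment <- function(read, design,
                                    params = cryptic_params(),
                                    score_threshold = 0.7, max_mismatch = 6,
                                    score_cmp = c("lt", "gt"),
                                    denominator = c("design", "read")) {
  score_cmp <- match.arg(score_cmp)
  denominator <- match.arg(denominator)
  aln <- .pa(read, design, params, type = "global-local")
  self_seq <- if (denominator == "design") design else read
  self <- .pa(self_seq, self_seq, align_params(match = params$match,
                                               mismatch = params$mismatch),
              score_only = TRUE)
  norm <- Biostrings::score(aln) / self
  mm <- Biostrings::nmismatch(aln)

  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  s_start <- BiocGenerics::start(aln@subject@range)
  ref_pos <- s_start - 1L + cumsum(s != "-")
  gap_col <- p == "-" & s != "-"
  gaps <- data.frame(start = integer(0), end = integer(0))
  if (any(gap_col)) {
    r <- rle(gap_col)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gi <- which(r$values)
    gaps <- data.frame(start = ref_pos[starts[gi]], end = ref_pos[ends[gi]])
    gaps <- gaps[order(gaps$start), , drop = FALSE]
  }
  intron <- NULL
  if (nrow(gaps) > 0) {
    len <- gaps$end - gaps$start + 1L
    k <- which(len == max(len))[1] # ties toward 5'
    intron <- c(gaps$start[k], gaps$end[k])
  }
  score_ok <- if (score_cmp == "lt") norm < score_threshold else
    norm > score_threshold
  structure(list(normalized = norm, mismatches = mm, gaps = gaps,
                 intron = intron,
                 call = score_ok && mm < max_mismatch && !is.null(intron)),
            class = "gap_alignment")
}
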
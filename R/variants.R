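REGION_LEN <- 158L
BARCODE_LEN <- 12L
FIVE_SS_START <- 18L   # oligo coordinate (1-based from barcode start)
JUNCTION_FLANK <- 20L
NATURAL_INTRON_MAX <- 148L
TWO_INTRON_TAIL <- 15L # 3' exon of two-intron designs

#' Combinatorial design features of a synthetic intron
#'
#' @param five_ss 6-nt donor site.
#' @param branch 7-nt branch site (concrete, catalytic A at position 6
#'   unless `mock = TRUE`).
#' @param three_ss 3-nt acceptor site (ends in AG unless `mock = TRUE`).
#' @param intron_len Intron length in nt (library set: 73, 89, 105, 121, 137).
#' @param bs_to_3ss Distance from the first base after the branch-site motif
#'   through the last intron base, inclusive of the 3'SS triplet (library
#'   set: 20, 30, 40, 50).
#' @param u_element U-rich element placed immediately upstream of the 3'SS.
#' @param background_id Identifier of the background sequence.
#' @param mock `TRUE` for negative-control (mock site) designs, which relax
#'   the motif-content checks.
#' @return A list of class `design_features`.
#' @export
design_features <- function(five_ss, branch, three_ss, intron_len, bs_to_3ss,
                            u_element, background_id = "MUD1", mock = FALSE) {
  stopifnot(nchar(five_ss) == 6L, nchar(branch) == 7L, nchar(three_ss) == 3L)
  if (!mock) {
    if (substr(branch, 6L, 6L) != "A")
      stop("branch site must carry A at motif position 6")
    if (substr(three_ss, 2L, 3L) != "AG")
      stop("3'SS must end in AG")
  }
  if (intron_len < 6L + 7L + bs_to_3ss)
    stop("intron too short to fit donor, branch site and BS-to-3'SS distance")
  if (bs_to_3ss < nchar(u_element) + 3L)
    stop("U element does not fit between branch site and 3'SS")
  structure(list(five_ss = five_ss, branch = branch, three_ss = three_ss,
                 intron_len = as.integer(intron_len),
                 bs_to_3ss = as.integer(bs_to_3ss),
                 u_element = u_element, background_id = background_id,
                 mock = isTRUE(mock)),
            class = "design_features")
}

.variant_row <- function(variant_id, barcode, region, subset,
                         i1_start = NA_integer_, i1_end = NA_integer_,
                         i2_start = NA_integer_, i2_end = NA_integer_,
                         five_ss = NA_character_, branch = NA_character_,
                         three_ss = NA_character_, intron_len = NA_integer_,
                         bs_to_3ss = NA_integer_, u_element = NA_character_,
                         background_id = NA_character_) {
  region <- as.vector(region) # drop helper attributes (e.g. edit counts)
  data.frame(variant_id = variant_id, barcode = barcode, region = region,
             subset = subset, i1_start = i1_start, i1_end = i1_end,
             i2_start = i2_start, i2_end = i2_end, five_ss = five_ss,
             branch = branch, three_ss = three_ss, intron_len = intron_len,
             bs_to_3ss = bs_to_3ss, u_element = u_element,
             background_id = background_id, stringsAsFactors = FALSE)
}

#' Full oligo sequence (barcode + variable region)
#' @param variant One manifest row (data.frame or list).
#' @return Character scalar.
#' @export
oligo_seq <- function(variant) paste0(variant$barcode, variant$region)

#' Build one combinatorial synthetic-intron variant
#'
#' Places the donor site at oligo positions 18-23 (1-based from the barcode
#' start), the intron spanning positions 18 to `18 + intron_len - 1`, the
#' acceptor triplet as the last three intron bases, the branch-site motif
#' ending `bs_to_3ss` nt before the intron end, and the U element
#' immediately upstream of the acceptor. All other positions carry the
#' background sequence. Start codons outside the placed motifs are scrubbed.
#'
#' @param features A [design_features()] object.
#' @param background 158-nt background variable-region sequence.
#' @param barcode 12-nt barcode.
#' @param variant_id Identifier for the manifest row.
#' @return A one-row manifest data.frame.
#' @export
build_combinatorial_variant <- function(features, background, barcode,
                                        variant_id = "v1") {
  stopifnot(inherits(features, "design_features"),
            nchar(background) == REGION_LEN, nchar(barcode) == BARCODE_LEN)
  L <- features$intron_len
  s <- FIVE_SS_START
  e <- s + L - 1L
  if (e > BARCODE_LEN + REGION_LEN)
    stop("intron extends past the variable region")
  oligo <- strsplit(paste0(barcode, background), "", fixed = TRUE)[[1]]

  put <- function(seq, at) {
    oligo[at:(at + nchar(seq) - 1L)] <<- strsplit(seq, "", fixed = TRUE)[[1]]
  }
  bs_end <- e - features$bs_to_3ss
  bs_start <- bs_end - 6L
  if (bs_start <= s + 5L) stop("branch site overlaps donor site")
  u_len <- nchar(features$u_element)
  u_start <- e - 2L - u_len
  if (u_start <= bs_end) stop("U element overlaps branch site")

  put(features$five_ss, s)
  put(features$branch, bs_start)
  put(features$u_element, u_start)
  put(features$three_ss, e - 2L)

  prot <- data.frame(
    start = c(s, bs_start, u_start, e - 2L),
    end = c(s + 5L, bs_end, u_start + u_len - 1L, e),
    class = c("five_ss", "branch", "u_element", "three_ss"))
  scrubbed <- scrub_start_codons(paste(oligo, collapse = ""), prot)
  .variant_row(variant_id, barcode,
               substr(scrubbed, BARCODE_LEN + 1L, BARCODE_LEN + REGION_LEN),
               subset = if (features$mock) "negative_control" else "combinatorial",
               i1_start = s, i1_end = e,
               five_ss = features$five_ss, branch = features$branch,
               three_ss = features$three_ss, intron_len = L,
               bs_to_3ss = features$bs_to_3ss,
               u_element = features$u_element,
               background_id = features$background_id)
}

#' Insert a natural intron into the reporter background
#'
#' The intron plus 5-nt flanks from its genomic context replaces the 5' end
#' of the background variable region, so the intron starts at oligo position
#' 18 like the combinatorial designs.
#'
#' @param intron_seq Natural intron sequence (<= 148 nt).
#' @param flank5,flank3 5-nt genomic flanking sequences.
#' @param background 158-nt background region.
#' @param barcode 12-nt barcode.
#' @param variant_id Identifier.
#' @param background_id Background label recorded in the manifest.
#' @return A one-row manifest data.frame.
#' @export
insert_natural_intron <- function(intron_seq, flank5, flank3, background,
                                  barcode, variant_id = "v1",
                                  background_id = "MUD1") {
  L <- nchar(intron_seq)
  if (L > NATURAL_INTRON_MAX)
    stop(sprintf("intron of %d nt exceeds the %d nt limit (158-nt region minus 5-nt flanks)",
                 L, NATURAL_INTRON_MAX))
  stopifnot(nchar(flank5) == 5L, nchar(flank3) == 5L,
            nchar(background) == REGION_LEN, nchar(barcode) == BARCODE_LEN)
  region <- paste0(flank5, intron_seq, flank3,
                   substr(background, 10L + L + 1L, REGION_LEN))
  s <- FIVE_SS_START
  e <- s + L - 1L
  prot <- data.frame(start = c(s, e - 2L), end = c(s + 5L, e),
                     class = c("five_ss", "three_ss"))
  scrubbed <- scrub_start_codons(paste0(barcode, region), prot)
  .variant_row(variant_id, barcode,
               substr(scrubbed, BARCODE_LEN + 1L, BARCODE_LEN + REGION_LEN),
               subset = "natural", i1_start = s, i1_end = e,
               five_ss = substr(intron_seq, 1L, 6L),
               three_ss = substr(intron_seq, L - 2L, L),
               intron_len = L, background_id = background_id)
}

#' Build a two-intron variant
#'
#' The first intron sits at the 5' end of the variable region after a fixed
#' 5-nt exonic lead (mirroring the natural-intron flank convention), the
#' second intron ends 15 nt before the region end, and the middle exon is
#' background sequence whose length varies with the two intron lengths.
#' The 15-nt third exon keeps the intron2-exon3 reference junction wide
#' enough (35 nt) to discriminate it from the U-rich tail of the first
#' intron; a shorter tail makes intron2-only isoforms unclassifiable.
#'
#' @param intron_a,intron_b Intron sequences, each < 76 nt.
#' @param background 158-nt background region.
#' @param barcode 12-nt barcode.
#' @param variant_id Identifier.
#' @return A one-row manifest data.frame.
#' @export
build_two_intron_variant <- function(intron_a, intron_b, background, barcode,
                                     variant_id = "v1") {
  La <- nchar(intron_a); Lb <- nchar(intron_b)
  if (La >= 76L || Lb >= 76L) stop("two-intron designs require introns < 76 nt")
  if (5L + TWO_INTRON_TAIL + La + Lb + 10L > REGION_LEN)
    stop("introns too long: no room left for the middle exon")
  stopifnot(nchar(background) == REGION_LEN, nchar(barcode) == BARCODE_LEN)
  region <- strsplit(background, "", fixed = TRUE)[[1]]
  region[6L:(5L + La)] <- strsplit(intron_a, "", fixed = TRUE)[[1]]
  region[(REGION_LEN - TWO_INTRON_TAIL - Lb + 1L):
           (REGION_LEN - TWO_INTRON_TAIL)] <-
    strsplit(intron_b, "", fixed = TRUE)[[1]]
  s1 <- FIVE_SS_START
  e1 <- s1 + La - 1L
  e2 <- BARCODE_LEN + REGION_LEN - TWO_INTRON_TAIL
  s2 <- e2 - Lb + 1L
  prot <- data.frame(start = c(s1, e1 - 2L, s2, e2 - 2L),
                     end = c(s1 + 5L, e1, s2 + 5L, e2),
                     class = c("five_ss", "three_ss", "five_ss", "three_ss"))
  scrubbed <- scrub_start_codons(paste0(barcode, paste(region, collapse = "")),
                                 prot)
  .variant_row(variant_id, barcode,
               substr(scrubbed, BARCODE_LEN + 1L, BARCODE_LEN + REGION_LEN),
               subset = "two_intron", i1_start = s1, i1_end = e1,
               i2_start = s2, i2_end = e2,
               five_ss = substr(intron_a, 1L, 6L),
               three_ss = substr(intron_a, La - 2L, La),
               intron_len = La)
}

#' Reference junction sequences of a variant
#'
#' Returns the 40-nt (20 nt each side, truncated only at the oligo ends)
#' reference junctions used for read classification. Single-intron variants
#' yield `exon_intron1`, `intron1_exon2` and `exon_exon`; two-intron
#' variants yield the four exon-intron junctions, the three pairwise
#' exon-exon junctions and the concatenated `exon1_exon2_exon3` junction.
#'
#' @param variant One manifest row.
#' @param flank Flank width on each side of a boundary (default 20).
#' @return Named character vector of junction sequences.
#' @export
variant_junctions <- function(variant, flank = JUNCTION_FLANK) {
  oligo <- oligo_seq(variant)
  n <- nchar(oligo)
  left <- function(pos) substr(oligo, max(1L, pos - flank), pos - 1L)
  right <- function(pos) substr(oligo, pos + 1L, min(n, pos + flank))
  seg <- function(a, b) substr(oligo, max(1L, a), min(n, b))
  s1 <- variant$i1_start; e1 <- variant$i1_end
  if (is.na(variant$i2_start)) {
    c(exon_intron1 = paste0(left(s1), seg(s1, s1 + flank - 1L)),
      intron1_exon2 = paste0(seg(e1 - flank + 1L, e1), right(e1)),
      exon_exon = paste0(left(s1), right(e1)))
  } else {
    s2 <- variant$i2_start; e2 <- variant$i2_end
    exon2 <- seg(e1 + 1L, s2 - 1L)
    c(exon1_intron1 = paste0(left(s1), seg(s1, s1 + flank - 1L)),
      intron1_exon2 = paste0(seg(e1 - flank + 1L, e1), right(e1)),
      exon2_intron2 = paste0(left(s2), seg(s2, s2 + flank - 1L)),
      intron2_exon3 = paste0(seg(e2 - flank + 1L, e2), right(e2)),
      exon1_exon2 = paste0(left(s1), right(e1)),
      exon2_exon3 = paste0(left(s2), right(e2)),
      exon1_exon3 = paste0(left(s1), right(e2)),
      exon1_exon2_exon3 = paste0(left(s1), exon2, right(e2)))
  }
}

#' Excise intron segments from an oligo sequence
#'
#' @param oligo Full oligo sequence.
#' @param starts,ends Parallel vectors of 1-based closed intron intervals.
#' @return The spliced sequence.
#' @export
splice_out <- function(oligo, starts, ends) {
  keep <- rep(TRUE, nchar(oligo))
  for (k in seq_along(starts)) keep[starts[k]:ends[k]] <- FALSE
  paste(strsplit(oligo, "", fixed = TRUE)[[1]][keep], collapse = "")
}

#' Check that a manifest row's recorded features match its sequence
#'
#' Round-trip validation: slices the oligo at the recorded intron
#' coordinates and compares the motifs found there with the recorded design
#' features.
#'
#' @param variant One manifest row.
#' @return `TRUE` (invisibly) or an error describing the first mismatch.
#' @export
validate_variant <- function(variant) {
  oligo <- oligo_seq(variant)
  if (nchar(variant$region) != REGION_LEN)
    stop("variable region is not 158 nt")
  s <- variant$i1_start; e <- variant$i1_end
  if (!is.na(s)) {
    if (!is.na(variant$five_ss) &&
        substr(oligo, s, s + 5L) != variant$five_ss)
      stop("recorded 5'SS does not match sequence")
    if (!is.na(variant$three_ss) &&
        substr(oligo, e - 2L, e) != variant$three_ss)
      stop("recorded 3'SS does not match sequence")
    if (!is.na(variant$branch) && !is.na(variant$bs_to_3ss)) {
      bs_end <- e - variant$bs_to_3ss
      if (substr(oligo, bs_end - 6L, bs_end) != variant$branch)
        stop("recorded branch site does not match sequence")
    }
    if (!is.na(variant$u_element) && !is.na(variant$bs_to_3ss)) {
      u_len <- nchar(variant$u_element)
      if (substr(oligo, e - 2L - u_len, e - 3L) != variant$u_element)
        stop("recorded U element does not match sequence")
    }
  }
  invisible(TRUE)
}
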
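#' The 39-feature schema of the splicing-efficiency model
#'
#' The frozen list of per-variant features: splice-site sequences and the
#' U element as categorical features, length and distance parameters,
#' base-composition features of the intron and its subregions, the U/Y
#' window upstream of the 3'SS, predicted local secondary structure at
#' each site (free-energy proxy and paired fraction), positional features,
#' and HAG-motif context around the 3'SS. Any change here is a schema
#' update, not a code change.
#'
#' @return data.frame with `name` and `type` (`"categorical"` /
#'   `"numeric"`); exactly 39 rows.
#' @export
feature_schema <- function() {
  cat_f <- c("five_ss_seq", "bs_seq", "three_ss_seq", "u_element_seq",
             "background_id")
  num_f <- c("intron_len", "bs_to_3ss_len", "five_to_bs_len",
             "upstream_exon_len", "downstream_exon_len",
             "intron_gc", "intron_a_frac", "bs_to_3ss_gc", "five_to_bs_gc",
             "u_content_w20", "y_content_w20", "c_frac_of_y_w20",
             "max_u_run_w20", "region_gc", "barcode_gc",
             "upstream_exon_gc", "downstream_exon_gc",
             "dg_5ss_w30", "dg_bs_w30", "dg_3ss_w30",
             "paired_frac_5ss", "paired_frac_bs", "paired_frac_3ss",
             "dg_intron", "is_consensus_5ss", "is_consensus_bs",
             "is_consensus_3ss", "n_consensus_sites",
             "intron_start_pos", "intron_end_pos",
             "n_hag_in_intron", "n_hag_downstream",
             "dist_first_hag_after_3ss", "u_element_len")
  data.frame(name = c(cat_f, num_f),
             type = c(rep("categorical", length(cat_f)),
                      rep("numeric", length(num_f))),
             stringsAsFactors = FALSE)
}

# best match to the consensus branch site inside an intron; requires the
# catalytic A, ties broken toward the 3' end where yeast branch sites sit
.find_branch_site <- function(intron_seq) {
  L <- nchar(intron_seq)
  if (L < 7L) return(NULL)
  cons <- strsplit("TACTAAC", "", fixed = TRUE)[[1]]
  best <- NULL
  best_score <- -1L
  for (p in seq_len(L - 6L)) {
    w <- strsplit(substr(intron_seq, p, p + 6L), "", fixed = TRUE)[[1]]
    if (w[6] != "A") next
    sc <- sum(w == cons)
    if (sc >= best_score) {
      best_score <- sc
      best <- p
    }
  }
  if (is.null(best)) return(NULL)
  list(start = best, end = best + 6L,
       seq = substr(intron_seq, best, best + 6L))
}

.max_run <- function(s, ch) {
  r <- rle(strsplit(s, "", fixed = TRUE)[[1]] == ch)
  if (any(r$values)) max(r$lengths[r$values]) else 0L
}

.fold_dg <- function(seq, engine) {
  if (nchar(seq) < 8L) return(list(score = 0, paired = rep(FALSE, nchar(seq))))
  fold_window(seq, engine = engine)
}

#' Extract the 39-feature vector of a single-intron variant
#'
#' Deterministic: the same variant always yields the identical vector.
#' Designs without a recorded branch site (natural-intron insertions) get
#' their branch site located as the best consensus match with a catalytic
#' A; missing U elements are encoded as `"none"` with length 0; a missing
#' downstream HAG distance is imputed as the downstream exon length + 1.
#'
#' @param variant One manifest row (single-intron).
#' @param engine Fold engine for the structure features.
#' @return A one-row data.frame following [feature_schema()].
#' @export
extract_features <- function(variant, engine = "nussinov") {
  if (is.na(variant$i1_start) || !is.na(variant$i2_start))
    stop("feature extraction requires a single-intron variant")
  oligo <- oligo_seq(variant)
  n <- nchar(oligo)
  s <- variant$i1_start
  e <- variant$i1_end
  intron <- substr(oligo, s, e)
  L <- e - s + 1L

  if (!is.na(variant$branch) && !is.na(variant$bs_to_3ss)) {
    bs_end <- e - variant$bs_to_3ss
    bs_seq <- variant$branch
  } else {
    bs <- .find_branch_site(intron)
    bs_end <- if (is.null(bs)) NA_integer_ else s + bs$end - 1L
    bs_seq <- if (is.null(bs)) "none" else bs$seq
  }
  bs_to_3ss_len <- if (is.na(bs_end)) round(L / 3) else e - bs_end
  five_to_bs_len <- if (is.na(bs_end)) round(L / 3) else (bs_end - 6L) - (s + 6L)

  w20 <- substr(oligo, max(s, e - 22L), e - 3L)
  u <- base_content(w20, "T")
  y <- base_content(w20, c("C", "T"))
  c_of_y <- if (!is.na(y) && y > 0) base_content(w20, "C") / y else 0

  win30 <- function(center) {
    substr(oligo, max(1L, center - 15L), min(n, center + 14L))
  }
  f5 <- .fold_dg(win30(s + 3L), engine)
  fb <- if (is.na(bs_end)) list(score = 0, paired = logical(30)) else
    .fold_dg(win30(bs_end - 3L), engine)
  f3 <- .fold_dg(win30(e - 1L), engine)
  fi <- .fold_dg(intron, engine)
  paired_at <- function(fold, center, iv) {
    wstart <- max(1L, center - 15L)
    pos <- (iv[1]:iv[2]) - wstart + 1L
    pos <- pos[pos >= 1L & pos <= length(fold$paired)]
    if (length(pos) == 0) 0 else mean(fold$paired[pos])
  }

  hag_in <- sum(motif_starts(intron, c("AAG", "CAG", "TAG")) > 6L)
  down <- substr(oligo, e + 1L, n)
  hag_down_pos <- motif_starts(down, c("AAG", "CAG", "TAG"))
  cons5 <- as.integer(!is.na(variant$five_ss) && variant$five_ss == "GTATGT")
  consb <- as.integer(bs_seq == "TACTAAC")
  cons3 <- as.integer(!is.na(variant$three_ss) &&
                        variant$three_ss %in% c("TAG", "CAG"))

  data.frame(
    five_ss_seq = if (is.na(variant$five_ss)) substr(intron, 1, 6) else variant$five_ss,
    bs_seq = bs_seq,
    three_ss_seq = if (is.na(variant$three_ss)) substr(intron, L - 2L, L) else variant$three_ss,
    u_element_seq = if (is.na(variant$u_element)) "none" else variant$u_element,
    background_id = if (is.na(variant$background_id)) "none" else variant$background_id,
    intron_len = L,
    bs_to_3ss_len = bs_to_3ss_len,
    five_to_bs_len = five_to_bs_len,
    upstream_exon_len = s - 1L,
    downstream_exon_len = n - e,
    intron_gc = gc_content(intron),
    intron_a_frac = base_content(intron, "A"),
    bs_to_3ss_gc = if (is.na(bs_end)) gc_content(w20) else
      gc_content(substr(oligo, bs_end + 1L, e)),
    five_to_bs_gc = if (is.na(bs_end)) gc_content(intron) else
      gc_content(substr(oligo, s + 6L, bs_end - 7L)),
    u_content_w20 = u,
    y_content_w20 = y,
    c_frac_of_y_w20 = c_of_y,
    max_u_run_w20 = .max_run(w20, "T"),
    region_gc = gc_content(variant$region),
    barcode_gc = gc_content(variant$barcode),
    upstream_exon_gc = gc_content(substr(oligo, 1L, s - 1L)),
    downstream_exon_gc = gc_content(down),
    dg_5ss_w30 = f5$score,
    dg_bs_w30 = fb$score,
    dg_3ss_w30 = f3$score,
    paired_frac_5ss = paired_at(f5, s + 3L, c(s, s + 5L)),
    paired_frac_bs = if (is.na(bs_end)) 0 else
      paired_at(fb, bs_end - 3L, c(bs_end - 6L, bs_end)),
    paired_frac_3ss = paired_at(f3, e - 1L, c(e - 2L, e)),
    dg_intron = fi$score,
    is_consensus_5ss = cons5,
    is_consensus_bs = consb,
    is_consensus_3ss = cons3,
    n_consensus_sites = cons5 + consb + cons3,
    intron_start_pos = s,
    intron_end_pos = e,
    n_hag_in_intron = hag_in,
    n_hag_downstream = length(hag_down_pos),
    dist_first_hag_after_3ss = if (length(hag_down_pos) > 0)
      hag_down_pos[1] else nchar(down) + 1L,
    stringsAsFactors = FALSE,
    u_element_len = if (is.na(variant$u_element)) 0L else
      nchar(variant$u_element))
}

#' Feature matrix for all single-intron variants of a manifest
#'
#' @param manifest Library manifest.
#' @param engine Fold engine.
#' @return data.frame with `variant_id` plus the 39 schema columns.
#' @export
extract_feature_matrix <- function(manifest, engine = "nussinov") {
  single <- manifest[!is.na(manifest$i1_start) & is.na(manifest$i2_start), ]
  rows <- lapply(seq_len(nrow(single)), function(i)
    extract_features(single[i, ], engine))
  out <- cbind(variant_id = single$variant_id, do.call(rbind, rows))
  sch <- feature_schema()$name
  stopifnot(identical(sort(setdiff(names(out), "variant_id")), sort(sch)))
  out[, c("variant_id", sch)]
}
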
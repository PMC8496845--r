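#' Predicted local RNA structure score of a sequence window
#'
#' The default engine is a Nussinov maximum base-pairing dynamic program
#' (Watson-Crick plus G:U pairs, minimum hairpin loop of 3 unpaired bases);
#' its score is minus the pair count, a dependency-free free-energy proxy: 0
#' for an unpairable sequence, more negative for more paired windows. The
#' `"vienna"` engine shells out to `RNAfold` when available and returns the
#' true minimum free energy in kcal/mol; any function taking a sequence and
#' returning `list(score, paired)` can also be supplied.
#'
#' @param seq Sequence window (<= a few hundred nt; A/C/G/T/U).
#' @param engine `"nussinov"` (default), `"vienna"`, or a function.
#' @param min_loop Minimum hairpin loop size for the default engine.
#' @return A list of class `structure_score` with elements `seq`, `score`
#'   (<= 0) and `paired` (logical mask over positions).
#' @export
fold_window <- function(seq, engine = "nussinov", min_loop = 3L) {
  stopifnot(length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGTU]", seq))
    stop("sequence contains characters outside A/C/G/T/U")
  if (is.function(engine)) {
    out <- engine(seq)
    return(structure(list(seq = seq, score = out$score, paired = out$paired),
                     class = "structure_score"))
  }
  engine <- match.arg(engine, c("nussinov", "vienna"))
  if (engine == "vienna") {
    if (Sys.which("RNAfold") == "")
      stop("RNAfold binary not found; use engine = 'nussinov'")
    out <- system2("RNAfold", c("--noPS"), input = seq, stdout = TRUE)
    db <- strsplit(out[2], " ", fixed = TRUE)[[1]][1]
    mfe <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", out[2]))
    paired <- strsplit(db, "", fixed = TRUE)[[1]] != "."
    return(structure(list(seq = seq, score = mfe, paired = paired),
                     class = "structure_score"))
  }
  res <- .nussinov_cpp(seq, as.integer(min_loop))
  structure(list(seq = seq, score = -res$score, paired = res$partner > 0L,
                 partner = res$partner),
            class = "structure_score")
}

#' Mutate a variant so a splice site folds into a stem
#'
#' Introduces random substitutions near (but never inside) the splice-site
#' motifs of a combinatorial variant and accepts the first mutant for which
#' the fold engine predicts every nucleotide of the targeted site to be
#' base-paired within a local window. Emulates in-silico selection of
#' structure mutants that render a site inaccessible.
#'
#' @param variant One combinatorial manifest row.
#' @param site `"5ss"`, `"bs"` or `"3ss"`.
#' @param engine Fold engine passed to [fold_window()].
#' @param max_tries Number of random mutants to try before failing.
#' @param n_mut Number of substitutions per try (1 to `n_mut` drawn).
#' @param window_pad Window half-extension around the site for folding.
#' @param seed Seed.
#' @return The mutated manifest row (subset `"mutated"`) with attributes
#'   `mutations` (oligo positions changed) and `fold` (the accepted
#'   structure score).
#' @export
mutate_for_structure <- function(variant, site = c("5ss", "bs", "3ss"),
                                 engine = "nussinov", max_tries = 500L,
                                 n_mut = 6L, window_pad = 15L, seed = 1L) {
  site <- match.arg(site)
  s <- variant$i1_start; e <- variant$i1_end
  if (is.na(s)) stop("structure mutants require a single-intron variant")
  bs_end <- e - variant$bs_to_3ss
  site_iv <- switch(site,
                    "5ss" = c(s, s + 5L),
                    "bs" = c(bs_end - 6L, bs_end),
                    "3ss" = c(e - 2L, e))
  u_len <- nchar(variant$u_element)
  protected <- c(s:(s + 5L), (bs_end - 6L):bs_end,
                 (e - 2L - u_len):(e - 3L), (e - 2L):e)
  oligo <- strsplit(oligo_seq(variant), "", fixed = TRUE)[[1]]
  win <- max(1L, site_iv[1] - window_pad):min(length(oligo),
                                              site_iv[2] + window_pad)
  editable <- setdiff(win, protected)
  editable <- editable[editable > BARCODE_LEN]
  site_in_win <- match(site_iv[1]:site_iv[2], win)

  with_seed(derive_seed(seed, paste0("structmut-", variant$variant_id, site)), {
    for (try in seq_len(max_tries)) {
      cand <- oligo
      k <- sample(seq_len(n_mut), 1L)
      pos <- sample(editable, min(k, length(editable)))
      for (p in pos) cand[p] <- sample(setdiff(DNA_BASES, cand[p]), 1L)
      cand_str <- paste(cand, collapse = "")
      if (grepl("ATG", substr(cand_str, max(1L, min(pos) - 2L),
                              min(nchar(cand_str), max(pos) + 2L)),
                fixed = TRUE)) next
      fold <- fold_window(paste(cand[win], collapse = ""), engine = engine)
      if (all(fold$paired[site_in_win])) {
        out <- variant
        out$region <- substr(cand_str, BARCODE_LEN + 1L,
                             BARCODE_LEN + REGION_LEN)
        out$subset <- "mutated"
        attr(out, "mutations") <- pos
        attr(out, "fold") <- fold
        return(out)
      }
    }
    stop(sprintf(paste0("no accepted structure mutant for site %s within %d ",
                        "tries (window %d-%d, %d editable positions)"),
                 site, max_tries, min(win), max(win), length(editable)))
  })
}
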
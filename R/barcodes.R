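#' Generate an error-correcting barcode set
#'
#' Draws random DNA barcodes by rejection sampling so that every pair of
#' accepted barcodes is at Levenshtein (edit) distance at least `min_dist`
#' and no barcode contains an `ATG` start codon. With `min_dist = 4` every
#' single substitution, insertion or deletion is uniquely correctable by
#' nearest-neighbour decoding.
#'
#' @param n Number of barcodes.
#' @param length Barcode length in nucleotides.
#' @param min_dist Minimal pairwise Levenshtein distance.
#' @param seed Seed for the rejection sampler.
#' @param max_rounds Maximum number of candidate draws before giving up.
#' @return Character vector of `n` distinct barcodes.
#' @export
generate_barcodes <- function(n, length = 12L, min_dist = 4L, seed = 1L,
                              max_rounds = 200L * n + 1000L) {
  bc_len <- as.integer(length)
  stopifnot(n >= 1L, bc_len >= min_dist)
  with_seed(derive_seed(seed, "barcodes"), {
    accepted <- character(0)
    rounds <- 0L
    while (base::length(accepted) < n) {
      rounds <- rounds + 1L
      if (rounds > max_rounds)
        stop(sprintf(paste0("could not place %d barcodes of length %d at edit ",
                            "distance >= %d within %d rejection rounds"),
                     n, bc_len, min_dist, max_rounds))
      cand <- random_dna(bc_len)
      if (grepl("ATG", cand, fixed = TRUE)) next
      if (base::length(accepted) > 0 &&
          any(utils::adist(cand, accepted) < min_dist)) next
      accepted <- c(accepted, cand)
    }
    accepted
  })
}

#' Build a barcode-to-variant decoding index
#'
#' @param barcodes Character vector of barcodes.
#' @param variant_ids Variant identifiers, parallel to `barcodes`.
#' @param max_dist Maximal Levenshtein distance for an assignment; a read is
#'   assigned only if a *single* barcode lies within this distance
#'   (distance < 3 in the strict sense, i.e. `max_dist = 2`).
#' @return An object of class `barcode_index`.
#' @export
barcode_index <- function(barcodes, variant_ids, max_dist = 2L) {
  stopifnot(length(barcodes) == length(variant_ids),
            !anyDuplicated(barcodes))
  structure(list(barcodes = barcodes,
                 variant_ids = as.character(variant_ids),
                 barcode_length = nchar(barcodes[1]),
                 max_dist = as.integer(max_dist)),
            class = "barcode_index")
}

#' Decode read prefixes to variants by nearest barcode
#'
#' Each read's leading window (barcode length +/- 1 nt, to tolerate
#' insertions or deletions inside the barcode) is compared with every
#' library barcode by Levenshtein distance. A read is assigned when exactly
#' one barcode attains the minimal distance and that distance does not
#' exceed `index$max_dist`; ties and over-distance reads are dropped and
#' logged.
#'
#' @param reads Character vector of read sequences.
#' @param index A [barcode_index()].
#' @return A list with `variant_id` (character, NA for dropped reads) and
#'   `drop_reason` (NA, "ambiguous" or "no_match").
#' @export
decode_barcodes <- function(reads, index) {
  L <- index$barcode_length
  prefix <- substr(reads, 1L, L + 1L)
  uniq <- unique(prefix)
  assign_u <- rep(NA_character_, length(uniq))
  reason_u <- rep(NA_character_, length(uniq))

  # fast path: exact barcode prefix
  exact <- match(substr(uniq, 1L, L), index$barcodes)
  hit <- !is.na(exact)
  assign_u[hit] <- index$variant_ids[exact[hit]]

  todo <- which(!hit)
  if (length(todo) > 0) {
    windows <- lapply((L - 1L):(L + 1L), function(w) substr(uniq[todo], 1L, w))
    d <- Reduce(pmin, lapply(windows, function(ws)
      utils::adist(ws, index$barcodes)))
    dmin <- apply(d, 1L, min)
    nmin <- rowSums(d == dmin)
    ok <- dmin <= index$max_dist & nmin == 1L
    amb <- dmin <= index$max_dist & nmin > 1L
    best <- apply(d, 1L, which.min)
    assign_u[todo[ok]] <- index$variant_ids[best[ok]]
    reason_u[todo[amb]] <- "ambiguous"
    reason_u[todo[!ok & !amb]] <- "no_match"
  }
  i <- match(prefix, uniq)
  list(variant_id = assign_u[i], drop_reason = reason_u[i])
}

#' Collapse identical read sequences
#'
#' Exact-sequence dereplication; total counts are conserved.
#'
#' @param reads Character vector of read sequences.
#' @return A data.frame with columns `seq` and `count`.
#' @export
dereplicate <- function(reads) {
  t <- table(reads)
  data.frame(seq = names(t), count = as.integer(t),
             stringsAsFactors = FALSE, row.names = NULL)
}
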
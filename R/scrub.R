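#' Remove start codons from a designed sequence
#'
#' The library is a non-coding RNA library: every `ATG` at any offset is
#' mutated, so no reading frame can initiate translation. Splice-site motifs
#' are protected from editing; when a protected 5'SS itself contains an
#' `ATG` (e.g. the consensus donor `GTATGT`), the codon two codons
#' downstream of that `ATG` (offset +6, in the `ATG`'s frame) is replaced by
#' a stop codon instead. Length is always preserved.
#'
#' Repairs are deterministic: the sequence is scanned 5' to 3'; within an
#' `ATG` the `G` is mutated first (then the `T`, then the `A` if earlier
#' positions are protected), choosing the first substitution from a fixed
#' base order that does not create a new `ATG` in the local context.
#'
#' @param seq A single DNA string.
#' @param protected_intervals `NULL` or a data.frame with columns `start`,
#'   `end` (1-based, closed) and optionally `class` (`"five_ss"` marks donor
#'   sites eligible for the stop-codon exemption).
#' @return The scrubbed sequence (same length). Attribute `n_edits` records
#'   the number of substituted positions.
#' @export
scrub_start_codons <- function(seq, protected_intervals = NULL) {
  stopifnot(length(seq) == 1L)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(s)
  prot <- rep(FALSE, n)
  pclass <- rep(NA_character_, n)
  if (!is.null(protected_intervals) && nrow(protected_intervals) > 0) {
    cls <- if ("class" %in% names(protected_intervals))
      protected_intervals$class else rep(NA_character_, nrow(protected_intervals))
    for (k in seq_len(nrow(protected_intervals))) {
      idx <- protected_intervals$start[k]:protected_intervals$end[k]
      idx <- idx[idx >= 1 & idx <= n]
      prot[idx] <- TRUE
      pclass[idx] <- cls[k]
    }
  }
  n_edits <- 0L
  p <- 1L
  while (p <= n - 2L) {
    if (s[p] == "A" && s[p + 1L] == "T" && s[p + 2L] == "G") {
      mutable <- c(p + 2L, p + 1L, p)[!prot[c(p + 2L, p + 1L, p)]]
      fixed <- FALSE
      for (pos in mutable) {
        for (b in setdiff(c("T", "C", "A", "G"), s[pos])) {
          cand <- s
          cand[pos] <- b
          lo <- max(1L, p - 2L)
          hi <- min(n, p + 4L)
          win <- paste(cand[lo:hi], collapse = "")
          if (!grepl("ATG", win, fixed = TRUE)) {
            s <- cand
            n_edits <- n_edits + 1L
            fixed <- TRUE
            break
          }
        }
        if (fixed) break
      }
      if (!fixed) {
        # fully protected ATG: exempt; a protected donor site additionally
        # receives a stop codon two codons downstream, in the ATG's frame
        if (any(pclass[p:(p + 2L)] == "five_ss", na.rm = TRUE)) {
          st <- p + 6L
          if (st + 2L > n || any(prot[st:(st + 2L)]))
            stop("cannot place stop codon downstream of protected donor ATG")
          s[st:(st + 2L)] <- c("T", "A", "A")
          n_edits <- n_edits + 3L
        }
      }
    }
    p <- p + 1L
  }
  out <- paste(s, collapse = "")
  attr(out, "n_edits") <- n_edits
  out
}
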
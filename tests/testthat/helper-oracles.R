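# Independent oracles, written against the definitions rather than the
# package's implementation path.

# Affine-gap local alignment score by direct three-state recursion over
# the score tables (gap of length L costs open + (L - 1) * extend).
oracle_sw_score <- function(a, b, match = 5, mismatch = -4, open = 8,
                            extend = 8) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av)
  m <- length(bv)
  if (n == 0 || m == 0) return(0)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1, j + 1] <- s + max(0, M[i, j], Ix[i, j], Iy[i, j])
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open, Ix[i, j + 1] - extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open, Iy[i + 1, j] - extend)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Maximum base pairing by exhaustive recursion (no memoization): every
# admissible structure of the interval is enumerated.
oracle_max_pairs <- function(seq, min_loop = 3) {
  s <- chartr("T", "U", toupper(seq))
  sv <- strsplit(s, "", fixed = TRUE)[[1]]
  ok <- function(x, y) {
    paste0(x, y) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      if (!ok(sv[i], sv[k])) next
      inner <- if (k > i + 1) rec(i + 1, k - 1) else 0
      outer <- if (k < j) rec(k + 1, j) else 0
      best <- max(best, 1 + inner + outer)
    }
    best
  }
  rec(1, length(sv))
}

# All single-edit corruptions (substitution, insertion, deletion at every
# position) of a barcode.
all_single_edits <- function(bc) {
  v <- strsplit(bc, "", fixed = TRUE)[[1]]
  n <- length(v)
  out <- character(0)
  for (i in 1:n) { # substitutions
    for (b in c("A", "C", "G", "T")) {
      if (b != v[i]) out <- c(out, paste(replace(v, i, b), collapse = ""))
    }
  }
  for (i in 0:n) { # insertions
    for (b in c("A", "C", "G", "T")) {
      out <- c(out, paste(c(v[seq_len(i)], b, v[seq_len(n - i) + i]),
                          collapse = ""))
    }
  }
  for (i in 1:n) out <- c(out, paste(v[-i], collapse = "")) # deletions
  unique(out)
}
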
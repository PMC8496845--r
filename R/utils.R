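#' @useDynLib splicelib, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Derive a reproducible sub-seed from a master seed
#'
#' Stages of the pipeline draw their own seeds from one global seed so that
#' each stage is independently reproducible. The derivation is a fixed
#' multiplicative hash of the master seed and a stage key, kept inside the
#' 32-bit signed integer range.
#'
#' @param seed Master seed (single integer).
#' @param key Stage key (single integer or character; characters are hashed
#'   by their byte values).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, length(key) == 1L)
  if (is.character(key)) key <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  m <- 2147483647 # 2^31 - 1, prime
  x <- (as.double(seed) %% m) + 1
  k <- (as.double(key) %% m) + 1
  s <- (x * 48271 + k * 16807) %% m
  as.integer(if (s < 1) 1 else s)
}

random_dna <- function(n, alphabet = DNA_BASES) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Reverse complement of a DNA string
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' GC content of DNA strings
#' @param x Character vector of DNA sequences.
#' @return Numeric vector of GC fractions (NA for empty strings).
#' @export
gc_content <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GCgc]", "", x))
  ifelse(n > 0, gc / n, NA_real_)
}

base_content <- function(x, bases) {
  n <- nchar(x)
  k <- nchar(gsub(sprintf("[^%s]", paste(bases, collapse = "")), "", toupper(x)))
  ifelse(n > 0, k / n, NA_real_)
}

# all start offsets (1-based) of a fixed-length pattern in subject
find_all <- function(subject, pattern) {
  out <- integer(0)
  from <- 1L
  repeat {
    i <- regexpr(pattern, substr(subject, from, nchar(subject)), fixed = TRUE)
    if (i < 0) break
    out <- c(out, from + as.integer(i) - 1L)
    from <- from + as.integer(i)
  }
  out
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  expr
}

# positions (1-based) where any of `motifs` (same length) starts in `x`
motif_starts <- function(x, motifs) {
  sort(unique(unlist(lapply(motifs, function(m) find_all(x, m)))))
}
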
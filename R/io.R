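#' Write a library manifest as TSV (with companion FASTA)
#'
#' @param manifest Manifest data.frame.
#' @param path Output TSV path.
#' @param fasta Optional path for a FASTA of the full oligo sequences.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path, fasta = NULL) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(fasta)) {
    x <- Biostrings::DNAStringSet(paste0(manifest$barcode, manifest$region))
    names(x) <- manifest$variant_id
    Biostrings::writeXStringSet(x, fasta)
  }
  invisible(path)
}

#' Read a library manifest TSV
#' @param path Manifest path written by [write_manifest()].
#' @return Manifest data.frame.
#' @export
read_manifest <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c(variant_id = "character",
                                   barcode = "character",
                                   region = "character",
                                   subset = "character"),
                    stringsAsFactors = FALSE)
}

#' Read genome contigs from FASTA
#' @param path FASTA path.
#' @return Named character vector of contig sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*", "", names(x)))
}

#' Write genome contigs to FASTA
#' @param genome Named character vector of contig sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read BED6 annotations into a 1-based closed-interval data.frame
#'
#' @param path BED path (0-based half-open, 6 columns, strand honored).
#' @return data.frame with `chrom`, `start`, `end` (1-based closed),
#'   `name`, `score`, `strand`.
#' @export
read_bed6 <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(b)[1:3] <- c("chrom", "start", "end")
  if (ncol(b) >= 6) names(b)[4:6] <- c("name", "score", "strand")
  else b$strand <- "+"
  b$start <- b$start + 1L # BED is 0-based half-open
  b
}

#' Write 1-based closed intervals as BED6
#'
#' @param df data.frame with `chrom`, `start`, `end`, `strand` (1-based
#'   closed).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(df, path) {
  out <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end,
                    name = if ("name" %in% names(df)) df$name else ".",
                    score = 0L, strand = df$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
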
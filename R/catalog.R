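#' Splice-site catalog for combinatorial intron design
#'
#' Holds the building blocks of the combinatorial library: donor (5'SS)
#' hexamers, branch-site (BS) heptamers or degenerate templates, acceptor
#' (3'SS) triplets, short U-rich elements placed upstream of the 3'SS, and
#' one mock sequence per site class used for negative-control designs.
#'
#' Defaults follow the splice sites observed in the *S. cerevisiae* genome:
#' five 5'SS hexamers (consensus `GTATGT`), the consensus branch site
#' `TACTAAC` plus three templates with two degenerate leading positions
#' (`NNCTAAC`, `NNCTAAT`, `NNTTAAC`), the three genomic 3'SS triplets
#' (`TAG`, `CAG`, `AAG`), and U elements `ATTTTTAA`, `TTTAA`, `TAA`
#' (DNA alphabet).
#'
#' @param five_prime_sites Character vector of 6-nt donor sites.
#' @param branch_sites Character vector of 7-nt branch sites; `N` marks a
#'   degenerate position to be instantiated at build time.
#' @param three_prime_sites Character vector of 3-nt acceptor sites ending
#'   in `AG`.
#' @param u_elements Character vector of short U-rich elements.
#' @param seed Seed used to draw the mock (negative-control) site sequences,
#'   which are generated once per catalog and recorded.
#' @return An object of class `splice_site_catalog` (a list).
#' @export
splice_site_catalog <- function(five_prime_sites = c("GTATGT", "GTAAGT", "GTATGA",
                                                     "GTACGT", "GTATGC"),
                                branch_sites = c("TACTAAC", "NNCTAAC", "NNCTAAT",
                                                 "NNTTAAC"),
                                three_prime_sites = c("TAG", "CAG", "AAG"),
                                u_elements = c("ATTTTTAA", "TTTAA", "TAA"),
                                seed = 1L) {
  stopifnot(all(nchar(five_prime_sites) == 6L),
            all(nchar(branch_sites) == 7L),
            all(nchar(three_prime_sites) == 3L))
  if (!all(substr(branch_sites, 6L, 6L) == "A"))
    stop("every branch site must carry the catalytic A at motif position 6")
  if (!all(substr(three_prime_sites, 2L, 3L) == "AG"))
    stop("every 3'SS must end in AG")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "mock-sites"))
  mock <- list(
    five_ss  = .draw_mock(6L, avoid = five_prime_sites),
    branch   = .draw_mock(7L, avoid = branch_sites),
    three_ss = .draw_mock(3L, avoid = three_prime_sites, no_ag = TRUE)
  )
  structure(list(five_prime_sites = five_prime_sites,
                 branch_sites = branch_sites,
                 three_prime_sites = three_prime_sites,
                 u_elements = u_elements,
                 control_sites = mock),
            class = "splice_site_catalog")
}

# mock sites must not contain ATG, must differ from any real site, and (for
# the 3' class) must not end in AG, so a mock design carries no functional
# acceptor
.draw_mock <- function(len, avoid, no_ag = FALSE) {
  for (i in 1:1000) {
    s <- random_dna(len)
    if (grepl("ATG", s, fixed = TRUE)) next
    if (s %in% avoid) next
    if (no_ag && substr(s, len - 1L, len) == "AG") next
    return(s)
  }
  stop("could not draw a mock site")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Instantiate degenerate branch-site templates
#'
#' Positions marked `N` are drawn uniformly from A/C/G/T. Each template is
#' instantiated `n_per_template` times (distinct instances).
#'
#' @param catalog A [splice_site_catalog()].
#' @param n_per_template Number of instantiations per degenerate template.
#' @param seed Seed for the uniform draws.
#' @return Character vector of concrete 7-nt branch sites.
#' @export
instantiate_branch_sites <- function(catalog, n_per_template = 3L, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "bs-templates"))
  out <- character(0)
  for (tmpl in catalog$branch_sites) {
    if (!grepl("N", tmpl, fixed = TRUE)) {
      out <- c(out, tmpl)
      next
    }
    got <- character(0)
    tries <- 0L
    while (length(got) < n_per_template && tries < 1000L) {
      tries <- tries + 1L
      s <- strsplit(tmpl, "")[[1]]
      s[s == "N"] <- sample(DNA_BASES, sum(s == "N"), replace = TRUE)
      cand <- paste(s, collapse = "")
      if (!cand %in% c(got, out)) got <- c(got, cand)
    }
    out <- c(out, got)
  }
  unique(out)
}
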
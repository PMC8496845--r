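#' Random ATG-free background variable region
#'
#' The reporter background of the real assay derives from an endogenous
#' intron-containing gene; for simulation we draw a synthetic 158-nt
#' background (ATG-scrubbed, labelled synthetic) from the seed.
#'
#' @param seed Seed.
#' @param id Background identifier.
#' @return A single 158-nt DNA string with attribute `background_id`.
#' @export
random_background <- function(seed = 1L, id = "bg_synthetic") {
  with_seed(derive_seed(seed, paste0("background-", id)), {
    s <- scrub_start_codons(random_dna(REGION_LEN))
    attr(s, "background_id") <- id
    s
  })
}

#' Simulate a natural-like intron sequence
#'
#' Consensus-like donor, a branch site near the 3' end, a U-rich stretch
#' and an acceptor triplet over random interior sequence - the anatomy of
#' a short yeast intron. Used to emulate the natural-intron subsets.
#'
#' @param len Intron length; drawn uniformly from `len_range` when NULL.
#' @param len_range Length range for the draw.
#' @param bs_to_3ss_range Range of the branch-site-to-3'SS distance;
#'   species whose machinery tolerates long distances (U2AF1-bearing
#'   architectures) use larger values.
#' @param catalog A [splice_site_catalog()].
#' @param seed Seed.
#' @return A list: `seq`, `flank5`, `flank3`.
#' @export
simulate_natural_intron <- function(len = NULL, len_range = c(60L, 140L),
                                    bs_to_3ss_range = c(15L, 45L),
                                    catalog = splice_site_catalog(),
                                    seed = 1L) {
  with_seed(derive_seed(seed, "natural-intron"), {
    if (is.null(len)) len <- sample(len_range[1]:len_range[2], 1L)
    stopifnot(len >= 30L)
    d <- sample(bs_to_3ss_range[1]:min(bs_to_3ss_range[2], len - 20L), 1L)
    five <- sample(catalog$five_prime_sites, 1L,
                   prob = c(0.6, rep(0.4 / (length(catalog$five_prime_sites) - 1L),
                                     length(catalog$five_prime_sites) - 1L)))
    three <- sample(c("TAG", "CAG"), 1L)
    s <- strsplit(random_dna(len), "", fixed = TRUE)[[1]]
    s[1:6] <- strsplit(five, "", fixed = TRUE)[[1]]
    bs_end <- len - d
    s[(bs_end - 6L):bs_end] <- strsplit("TACTAAC", "", fixed = TRUE)[[1]]
    u_len <- sample(4:8, 1L)
    s[(len - 2L - u_len):(len - 3L)] <-
      sample(c("T", "A"), u_len, replace = TRUE, prob = c(0.8, 0.2))
    s[(len - 2L):len] <- strsplit(three, "", fixed = TRUE)[[1]]
    list(seq = paste(s, collapse = ""), flank5 = random_dna(5L),
         flank3 = random_dna(5L))
  })
}

#' Assemble a designed oligo library manifest
#'
#' Builds the library subsets: the combinatorial synthetic introns
#' (cartesian product of catalog sites, intron lengths, BS-to-3'SS
#' distances and U elements), matching negative controls with mock sites,
#' natural-intron insertions, and two-intron designs from all ordered
#' pairs of a short-intron pool. Barcodes come from one error-correcting
#' code spanning the whole library.
#'
#' @param catalog A [splice_site_catalog()].
#' @param intron_lens Intron lengths of the combinatorial subset.
#' @param bs_to_3ss BS-to-3'SS distances.
#' @param bs_instances Instantiations per degenerate branch-site template.
#' @param n_combinatorial Cap on combinatorial variants (NULL = all
#'   combinations).
#' @param n_negative Number of negative-control variants (mock sites over
#'   sampled length combinations).
#' @param n_natural Number of simulated natural-intron insertions.
#' @param two_intron_pool Number of short introns in the two-intron pool
#'   (all ordered pairs are built); 0 disables the subset.
#' @param background A 158-nt background, by default drawn from the seed.
#' @param seed Seed.
#' @return A manifest data.frame (one row per variant).
#' @export
build_library <- function(catalog = splice_site_catalog(),
                          intron_lens = c(73L, 89L, 105L, 121L, 137L),
                          bs_to_3ss = c(20L, 30L, 40L, 50L),
                          bs_instances = 1L,
                          n_combinatorial = NULL, n_negative = 12L,
                          n_natural = 0L, two_intron_pool = 0L,
                          background = NULL, seed = 1L) {
  if (is.null(background)) background <- random_background(seed)
  bg_id <- attr(background, "background_id")
  if (is.null(bg_id)) bg_id <- "bg"

  branch_sites <- instantiate_branch_sites(catalog, bs_instances, seed)
  grid <- expand.grid(five_ss = catalog$five_prime_sites,
                      branch = branch_sites,
                      three_ss = catalog$three_prime_sites,
                      intron_len = intron_lens, bs_to_3ss = bs_to_3ss,
                      u_element = catalog$u_elements,
                      stringsAsFactors = FALSE)
  if (!is.null(n_combinatorial) && n_combinatorial < nrow(grid)) {
    grid <- with_seed(derive_seed(seed, "comb-sample"),
                      grid[sample.int(nrow(grid), n_combinatorial), ])
  }

  neg_grid <- expand.grid(intron_len = intron_lens, bs_to_3ss = bs_to_3ss,
                          u_element = catalog$u_elements,
                          stringsAsFactors = FALSE)
  if (n_negative < nrow(neg_grid)) {
    neg_grid <- with_seed(derive_seed(seed, "neg-sample"),
                          neg_grid[sample.int(nrow(neg_grid), n_negative), ])
  }

  pool <- if (two_intron_pool > 0L) {
    lapply(seq_len(two_intron_pool), function(i)
      simulate_natural_intron(len_range = c(52L, 62L), catalog = catalog,
                              seed = derive_seed(seed, 7000L + i))$seq)
  } else list()
  n_pairs <- length(pool)^2

  n_total <- nrow(grid) + nrow(neg_grid) + n_natural + n_pairs
  barcodes <- generate_barcodes(n_total, seed = derive_seed(seed, "bc"))
  bi <- 0L
  next_bc <- function() {
    bi <<- bi + 1L
    barcodes[bi]
  }

  rows <- vector("list", n_total)
  ri <- 0L
  add <- function(row) {
    ri <<- ri + 1L
    rows[[ri]] <<- row
  }
  for (i in seq_len(nrow(grid))) {
    f <- design_features(grid$five_ss[i], grid$branch[i], grid$three_ss[i],
                         grid$intron_len[i], grid$bs_to_3ss[i],
                         grid$u_element[i], background_id = bg_id)
    add(build_combinatorial_variant(f, background, next_bc(),
                                    sprintf("comb%05d", i)))
  }
  mock <- catalog$control_sites
  for (i in seq_len(nrow(neg_grid))) {
    f <- design_features(mock$five_ss, mock$branch, mock$three_ss,
                         neg_grid$intron_len[i], neg_grid$bs_to_3ss[i],
                         neg_grid$u_element[i], background_id = bg_id,
                         mock = TRUE)
    add(build_combinatorial_variant(f, background, next_bc(),
                                    sprintf("neg%05d", i)))
  }
  for (i in seq_len(n_natural)) {
    ni <- simulate_natural_intron(catalog = catalog,
                                  seed = derive_seed(seed, 8000L + i))
    add(insert_natural_intron(ni$seq, ni$flank5, ni$flank3, background,
                              next_bc(), sprintf("nat%05d", i),
                              background_id = bg_id))
  }
  if (n_pairs > 0L) {
    pij <- expand.grid(a = seq_along(pool), b = seq_along(pool))
    for (i in seq_len(nrow(pij))) {
      add(build_two_intron_variant(pool[[pij$a[i]]], pool[[pij$b[i]]],
                                   background, next_bc(),
                                   sprintf("two%05d", i)))
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  attr(manifest, "two_intron_pool") <- pool
  manifest
}
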
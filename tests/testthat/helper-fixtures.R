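# Fixtures are generated in code from fixed seeds.

fixture_variant <- function(seed = 3L, intron_len = 73L, bs_to_3ss = 20L,
                            five_ss = "GTATGT", branch = "TACTAAC",
                            three_ss = "TAG", u_element = "TTTAA") {
  bg <- random_background(seed)
  f <- design_features(five_ss, branch, three_ss, intron_len, bs_to_3ss,
                       u_element)
  build_combinatorial_variant(f, bg, generate_barcodes(1, seed = seed), "v1")
}

fixture_two_intron <- function(seed = 3L, len_a = 56L, len_b = 60L) {
  bg <- random_background(seed)
  ia <- simulate_natural_intron(len = len_a, seed = derive_seed(seed, 1))$seq
  ib <- simulate_natural_intron(len = len_b, seed = derive_seed(seed, 2))$seq
  build_two_intron_variant(ia, ib, bg, generate_barcodes(1, seed = seed + 1),
                           "t1")
}

# a bare manifest row with handcrafted sequence content (for feature
# edge cases the builders cannot produce)
handcrafted_variant <- function(region, i1_start, i1_end,
                                barcode = strrep("CA", 6),
                                variant_id = "h1") {
  data.frame(variant_id = variant_id, barcode = barcode, region = region,
             subset = "combinatorial", i1_start = i1_start, i1_end = i1_end,
             i2_start = NA_integer_, i2_end = NA_integer_,
             five_ss = NA_character_, branch = NA_character_,
             three_ss = NA_character_, intron_len = i1_end - i1_start + 1L,
             bs_to_3ss = NA_integer_, u_element = NA_character_,
             background_id = NA_character_, stringsAsFactors = FALSE)
}

fixture_library <- function(seed = 7L, n_combinatorial = 16L,
                            n_negative = 4L, n_natural = 4L,
                            two_intron_pool = 2L) {
  build_library(n_combinatorial = n_combinatorial, n_negative = n_negative,
                n_natural = n_natural, two_intron_pool = two_intron_pool,
                seed = seed)
}
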
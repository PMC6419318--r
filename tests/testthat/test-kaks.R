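test_that("per-codon site counts match single-mutant enumeration", {
  # TTT (Phe): only the third-position T->C change is synonymous
  expect_equal(count_sites("TTT"), c(syn = 1 / 3, nonsyn = 8 / 3))
  # GGG (Gly): third position fully synonymous
  expect_equal(count_sites("GGG"), c(syn = 1, nonsyn = 2))
  # ATG (Met): single-codon amino acid
  expect_equal(count_sites("ATG"), c(syn = 0, nonsyn = 3))
  expect_error(count_sites("TAA"), "stop codon")
  expect_error(count_sites("AXG"), "invalid codon")
  # sites always sum to 3
  code <- as.character(Biostrings::GENETIC_CODE)
  sense <- names(Biostrings::GENETIC_CODE)[code != "*"]
  sums <- vapply(sense, function(c0) sum(count_sites(c0)), 0)
  expect_true(all(abs(sums - 3) < 1e-12))
})

test_that("codon alignments validate structure", {
  a <- codon_alignment("x", "y", "ATGGCT", "ATGGCA")
  expect_length(a$codons_a, 2)
  # gapped codons are dropped pairwise
  g <- codon_alignment("x", "y", "ATG---GCT", "ATGAAAGCA")
  expect_length(g$codons_a, 2)
  expect_error(codon_alignment("x", "y", "ATGG", "ATGG"), "divisible")
  expect_error(codon_alignment("x", "y", "ATG", "ATGA"), "length")
  expect_error(codon_alignment("x", "y", "ATGTAAGCT", "ATGTAAGCA"),
               "internal stop")
})

test_that("zero-difference and single-difference cases behave", {
  same <- compute_kaks(codon_alignment("a", "b", strrep("ATGGCT", 50),
                                       strrep("ATGGCT", 50)))
  expect_equal(same$Ka, 0)
  expect_equal(same$Ks, 0)
  expect_true(is.na(same$ratio))

  # one synonymous third-position change in 100 codons
  s1 <- paste0("GGG", strrep("ATGCTG", 50))
  s2 <- paste0("GGA", strrep("ATGCTG", 50))
  r <- compute_kaks(codon_alignment("a", "b", s1, s2))
  expect_equal(r$Ka, 0)
  expect_gt(r$Ks, 0)
  expect_equal(r$ratio, 0)
  expect_equal(r$Nd, 0)
  expect_equal(r$Sd, 1)
})

test_that("results are symmetric in sequence order", {
  set.seed(14)
  al <- random_codon_alignment(40)
  f <- compute_kaks(codon_alignment("a", "b",
                                    paste(al$a, collapse = ""),
                                    paste(al$b, collapse = "")))
  r <- compute_kaks(codon_alignment("b", "a",
                                    paste(al$b, collapse = ""),
                                    paste(al$a, collapse = "")))
  expect_equal(f$Ka, r$Ka)
  expect_equal(f$Ks, r$Ks)
  expect_equal(f$Sd, r$Sd)
})

test_that("site totals partition the alignment length", {
  set.seed(8)
  for (i in 1:10) {
    al <- random_codon_alignment(25)
    r <- compute_kaks(codon_alignment("a", "b",
                                      paste(al$a, collapse = ""),
                                      paste(al$b, collapse = "")))
    expect_equal(r$N_sites + r$S_sites, 3 * 25)
    expect_lte(r$Nd, 3 * 25)
  }
})

test_that("adding a synonymous substitution never increases Ka", {
  set.seed(77)
  al <- random_codon_alignment(30)
  base <- compute_kaks(codon_alignment("a", "b",
                                       paste(al$a, collapse = ""),
                                       paste(al$b, collapse = "")))
  # append a purely synonymous codon pair
  ext <- compute_kaks(codon_alignment(
    "a", "b",
    paste(c(al$a, "GGG"), collapse = ""),
    paste(c(al$b, "GGA"), collapse = "")))
  expect_lte(ext$Ka, base$Ka + 1e-12)
  expect_gte(ext$Sd, base$Sd)
})

test_that("saturated proportions are flagged, not corrected", {
  # maximally diverged short alignment drives p towards saturation
  r <- compute_kaks(codon_alignment("a", "b",
                                    strrep("GGG", 4), strrep("CAT", 4)))
  if (r$saturated) {
    expect_true(is.na(r$ratio))
  } else {
    expect_true(is.finite(r$ratio) || is.na(r$ratio))
  }
})

test_that("kaks_table computes one row per pair", {
  cfg <- simulation_config(seed = 2, kaks = list(n_pairs = 4, n_codons = 60))
  sim <- simulate_cds_pairs(cfg)
  tab <- kaks_table(sim$pairs, sim$cds)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$Ka >= 0 & tab$Ks >= 0, na.rm = TRUE))
  expect_error(kaks_table(data.frame(gene_a = "nope", gene_b = "pair01_a"),
                          sim$cds), "missing")
})
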
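test_that("motif compilation follows the degenerate pattern grammar", {
  # wildcard column is exactly the background (log-odds 0)
  m <- compile_motif("x")
  expect_equal(m$length, 1)
  expect_equal(unname(m$pwm[, 1]), rep(0, 20))

  # (L/V/M) with uniform background and no pseudocount: allowed residues
  # log2((1/3)/(1/20)), all others at the -30 bit cap
  m2 <- compile_motif("(L/V/M)")
  expect_equal(unname(m2$pwm[c("L", "V", "M"), 1]), rep(log2(20 / 3), 3))
  expect_equal(unname(m2$pwm["A", 1]), -30)

  expect_equal(compile_motif("GTxx(W/Y)MAPE")$length, 9)
  expect_equal(compile_motif("GTPEFMAPE(L/V/M)(Y/F/L)")$length, 11)
  expect_equal(compile_motif("G(T/S)Px(F/Y/W)MAPEV")$length, 10)

  expect_error(compile_motif("G(/)A"), "empty alternation")
  expect_error(compile_motif(""), "empty motif")
  expect_error(compile_motif("G(TS"), "unclosed")
})

test_that("single-column exact p-values match direct enumeration", {
  # a column allowing 2 of 20 residues under uniform background: the
  # maximum score has tail probability 2/20
  m <- compile_motif("(W/Y)")
  null <- exact_score_pvalues(m)
  expect_equal(null$tail[null$max_int + 1], 2 / 20)
  # all-wildcard motif: score 0 has p-value 1
  mw <- compile_motif("xx")
  nw <- exact_score_pvalues(mw)
  expect_equal(nw$tail[1], 1)
  expect_equal(nw$max_int, 0)
})

test_that("null tail probabilities are monotone and mass sums to one", {
  for (pat in c("G(T/S)x", "GTxx(W/Y)MAPE")) {
    null <- exact_score_pvalues(compile_motif(pat))
    expect_equal(sum(null$pmf), 1, tolerance = 1e-12)
    expect_true(all(diff(null$tail) <= 1e-15))
    expect_true(all(null$tail > 0 & null$tail <= 1 + 1e-15))
  }
})

test_that("dinucleotide DP equals brute force over all 400 dipeptides", {
  bg <- stats::setNames(rep(1 / 20, 20), genefamkit:::AA_ALPHABET)
  bg["L"] <- 3 / 20; bg["A"] <- 1 / 60; bg <- bg / sum(bg)
  m <- compile_motif("G(L/V)", background = bg)
  null <- exact_score_pvalues(m)
  pmf_bf <- oracle_motif_pmf(null, m$background, 2)
  expect_equal(null$pmf, pmf_bf, tolerance = 1e-13)
})

test_that("a consensus sequence attains the model maximum score", {
  for (pat in c("GTPEFMAPE(L/V/M)(Y/F/L)", "G(T/S)Px(F/Y/W)MAPEV",
                "GTxx(W/Y)MAPE")) {
    m <- compile_motif(pat)
    null <- exact_score_pvalues(m)
    hit <- scan_protein(m, m$consensus, pvalue_threshold = 1, null = null,
                        protein_id = "cons")
    expect_equal(hit$pvalue, null$tail[null$max_int + 1])
  }
})

test_that("scanning returns the best window and honors the threshold", {
  m <- compile_motif("GTPEFMAPE(L/V/M)(Y/F/L)")
  null <- exact_score_pvalues(m)
  prot <- paste0(strrep("A", 40), "GTPEFMAPEVF", strrep("K", 25))
  hit <- scan_protein(m, prot, 1e-4, null = null, protein_id = "p")
  expect_equal(hit$offset, 41)
  expect_equal(hit$window, "GTPEFMAPEVF")
  expect_lt(hit$pvalue, 1e-4)

  # protein shorter than the motif: no hit
  expect_equal(nrow(scan_protein(m, "GTPEF", 1, null = null)), 0)
})

test_that("random proteins rarely pass the primary threshold", {
  m <- compile_motif("GTPEFMAPE(L/V/M)(Y/F/L)")
  null <- exact_score_pvalues(m)
  set.seed(99)
  hits <- vapply(1:100, function(i) {
    prot <- paste(sample(genefamkit:::AA_ALPHABET, 50, replace = TRUE),
                  collapse = "")
    nrow(scan_protein(m, prot, 1e-4, null = null)) > 0
  }, TRUE)
  expect_lte(mean(hits), 0.01)
})

test_that("relaxing the threshold admits a superset of hits", {
  m <- compile_motif("G(T/S)Px(F/Y/W)MAPEV")
  null <- exact_score_pvalues(m)
  set.seed(123)
  prots <- c(
    vapply(1:30, function(i)
      paste(sample(genefamkit:::AA_ALPHABET, 80, replace = TRUE),
            collapse = ""), ""),
    # partially degraded motif instances near the decision boundary
    vapply(1:30, function(i) {
      inst <- strsplit("GTPAFMAPEV", "")[[1]]
      k <- sample(0:3, 1)
      if (k > 0) inst[sample(10, k)] <- sample(genefamkit:::AA_ALPHABET, k,
                                               replace = TRUE)
      paste0(strrep("A", 20), paste(inst, collapse = ""), strrep("A", 20))
    }, ""))
  hit_at <- function(thr) which(vapply(prots, function(p)
    nrow(scan_protein(m, p, thr, null = null)) > 0, TRUE))
  h4 <- hit_at(1e-4); h3 <- hit_at(1e-3)
  expect_true(all(h4 %in% h3))
  expect_gt(length(h3), 0)
})

test_that("conservation report flags per-protein best hits at both thresholds", {
  models <- list(ZIK = compile_motif("GTPEFMAPE(L/V/M)(Y/F/L)"))
  prots <- data.frame(
    id = c("z1.1", "z2.1"),
    sequence = c(paste0(strrep("A", 30), "GTPEFMAPELY", strrep("A", 30)),
                 paste(rep("K", 60), collapse = "")),
    stringsAsFactors = FALSE)
  rep <- motif_conservation_report(prots, c(z1.1 = "ZIK", z2.1 = "ZIK"),
                                   models)
  expect_true(rep$conserved_primary[rep$protein_id == "z1.1"])
  expect_false(rep$conserved_relaxed[rep$protein_id == "z2.1"])
  summ <- attr(rep, "summary")
  expect_equal(summ$conserved_primary[summ$subfamily == "ZIK"], 1)
  expect_equal(summ$n[summ$subfamily == "ZIK"], 2)
})
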
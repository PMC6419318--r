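make_hits <- function(ids, evalues, subfamily = "FAM") {
  o <- order(evalues)
  data.frame(target_id = ids[o], subfamily = subfamily, evalue = evalues[o],
             bitscore = -log10(evalues[o]), rank = seq_along(ids),
             stringsAsFactors = FALSE)
}

test_that("threshold anchors on the worst-scoring reference member", {
  # reference genes scattered among stronger non-reference hits; the worst
  # reference first-instance sets the cutoff
  hits <- make_hits(
    c("X1.1", "AT5G28080.1", "X2.1", "AT2G40500.1", "AT5G07140.1", "D1.1"),
    c(1e-120, 3.40e-107, 1e-90, 4.3e-86, 4.10e-79, 1e-20))
  refs <- reference_set(list(RAF = c("AT5G28080.1", "AT2G40500.1",
                                     "AT5G07140.1")))
  th <- determine_threshold(hits, refs, "RAF")
  expect_equal(th$anchor_id, "AT5G07140.1")
  expect_equal(th$evalue_cutoff, 4.10e-79)
  # the anchor itself is above threshold (inclusive comparison)
  expect_true("AT5G07140" %in% genes_above_threshold(hits, th$evalue_cutoff))
  expect_false("D1" %in% genes_above_threshold(hits, th$evalue_cutoff))
})

test_that("a single reference member with one hit defines the cutoff", {
  hits <- make_hits(c("R1.1", "other.1"), c(1e-50, 1e-30))
  refs <- reference_set(list(FAM = "R1.1"))
  th <- determine_threshold(hits, refs, "FAM")
  expect_equal(th$evalue_cutoff, 1e-50)
  expect_equal(th$anchor_id, "R1.1")
})

test_that("multi-variant reference genes use the first-occurring variant", {
  # variants .1 (rank 7, 1e-60) and .2 (rank 9, 1e-55): the representative
  # hit is .1, so the cutoff is 1e-60 even though .2 scores worse
  ids <- c(paste0("F", 1:6, ".1"), "R1.1", "F7.1", "R1.2", "F8.1")
  evs <- c(10^-(100:95), 1e-60, 1e-58, 1e-55, 1e-40)
  hits <- make_hits(ids, evs)
  refs <- reference_set(list(FAM = c("R1.1", "R1.2")))
  th <- determine_threshold(hits, refs, "FAM")
  expect_equal(th$anchor_id, "R1.1")
  expect_equal(th$evalue_cutoff, 1e-60)
})

test_that("threshold is an error when no reference member has a hit", {
  hits <- make_hits(c("a.1", "b.1"), c(1e-5, 1e-3))
  refs <- reference_set(list(FAM = "missing.1"))
  expect_error(determine_threshold(hits, refs, "FAM"), "threshold undefined")
})

test_that("threshold ties break by later output position", {
  hits <- make_hits(c("R1.1", "R2.1", "x.1"), c(1e-50, 1e-50, 1e-10))
  refs <- reference_set(list(FAM = c("R1.1", "R2.1")))
  th <- determine_threshold(hits, refs, "FAM")
  expect_equal(th$anchor_id, "R2.1")  # same E-value, larger rank
})

test_that("cluster assessment types and completion ratios", {
  a <- assess_cluster(c("g1", "g2", "g3", "g4"), c("g1", "g2"), group_id = "og")
  expect_equal(a$cluster_type, "partial")
  expect_equal(a$completion_ratio, 0.5)

  s <- assess_cluster("g1", "g1")
  expect_equal(s$cluster_type, "singleton")
  expect_equal(s$completion_ratio, 1)

  comp <- assess_cluster(c("g1", "g2", "g3"), c("g1", "g2", "g3"))
  expect_equal(comp$cluster_type, "complete")

  ab <- assess_cluster(c("g1", "g2"), character(0))
  expect_equal(ab$cluster_type, "absent")

  # transcript variants collapse to genes before counting
  v <- assess_cluster(c("g1.1", "g1.2", "g2.1"), "g1")
  expect_equal(v$n_genes, 2)
  expect_equal(v$completion_ratio, 0.5)

  expect_error(assess_cluster(character(0), "g1"), "empty")
})

test_that("known clusters mark via previously identified members", {
  a <- assess_cluster(c("g1", "REF9"), c("g1", "REF9"), known_ids = "REF9.1")
  expect_true(a$is_known)
  b <- assess_cluster(c("g1", "g2"), "g1", known_ids = "REF9.1")
  expect_false(b$is_known)
})

test_that("genes hitting two subfamilies are emitted twice and flagged", {
  hitsA <- make_hits(c("R1.1", "dual.1"), c(1e-80, 1e-70), "A")
  hitsB <- make_hits(c("R2.1", "dual.1"), c(1e-90, 1e-75), "B")
  groups <- data.frame(group_id = c("o1", "o1", "o2"),
                       species = "s",
                       gene_id = c("R1", "dual", "R2"),
                       transcript_id = c("R1.1", "dual.1", "R2.1"),
                       stringsAsFactors = FALSE)
  refs <- reference_set(list(A = "R1.1", B = "R2.1"))
  dec <- decide(groups, list(A = hitsA, B = hitsB), refs)
  dualrows <- dec[dec$gene_id == "dual", ]
  expect_equal(nrow(dualrows), 2)
  expect_true(all(dualrows$ambiguous))
  expect_false(any(dec$ambiguous[dec$gene_id %in% c("R1", "R2")]))
})

test_that("unclustered candidates behave as their own singleton cluster", {
  hits <- make_hits(c("R1.1", "lone.1"), c(1e-50, 1e-60))
  refs <- reference_set(list(FAM = "R1.1"))
  groups <- data.frame(group_id = "o1", species = "s", gene_id = "R1",
                       transcript_id = "R1.1", stringsAsFactors = FALSE)
  dec <- decide(groups, list(FAM = hits), refs)
  lone <- dec[dec$gene_id == "lone", ]
  expect_equal(lone$verdict, "keep")
  expect_equal(lone$reason_code, "SINGLETON_ABOVE")
})

test_that("keeping decisions are monotone in the tuning knobs", {
  # random scenarios: raising the completion threshold never adds kept
  # genes; loosening the E-value cutoff never removes kept genes
  set.seed(42)
  for (rep in 1:20) {
    n <- 30
    genes <- sprintf("G%02d", 1:n)
    evs <- 10^stats::runif(n, -100, -5)
    ids <- paste0(genes, ".1")
    hits <- make_hits(c("R1.1", ids), c(1e-55, evs))
    groups <- data.frame(group_id = sample(sprintf("og%d", 1:8), n + 1,
                                           replace = TRUE),
                         species = "s", gene_id = c("R1", genes),
                         transcript_id = c("R1.1", ids),
                         stringsAsFactors = FALSE)
    refs <- reference_set(list(FAM = "R1.1"))
    kept <- function(ct, cutoff_mult = 1) {
      th <- determine_threshold(hits, refs, "FAM")
      th$evalue_cutoff <- th$evalue_cutoff * cutoff_mult
      d <- decide(groups, list(FAM = hits), refs, completion_threshold = ct,
                  thresholds = list(FAM = th))
      d$gene_id[d$verdict == "keep"]
    }
    expect_true(all(kept(0.75) %in% kept(0.5)))
    expect_true(all(kept(0.5) %in% kept(0.25)))
    expect_true(all(kept(0.5) %in% kept(0.5, cutoff_mult = 1e10)))
  }
})

test_that("every kept gene outside the forced list is above threshold", {
  set.seed(7)
  n <- 40
  genes <- sprintf("G%02d", 1:n)
  hits <- make_hits(c("R1.1", paste0(genes, ".1")),
                    c(1e-50, 10^stats::runif(n, -90, -10)))
  groups <- data.frame(group_id = sample(sprintf("og%d", 1:10), n + 1,
                                         replace = TRUE),
                       species = "s", gene_id = c("R1", genes),
                       transcript_id = c("R1.1", paste0(genes, ".1")),
                       stringsAsFactors = FALSE)
  refs <- reference_set(list(FAM = "R1.1"), force_include = c("R1", "G01"))
  dec <- decide(groups, list(FAM = hits), refs)
  above <- genes_above_threshold(hits, 1e-50)
  kept <- dec[dec$verdict == "keep", ]
  expect_true(all(kept$gene_id %in% c(above, "R1", "G01")))
  expect_true(all(c("R1", "G01") %in% kept$gene_id))
})

test_that("species summary splits published from new members", {
  dec <- data.frame(gene_id = c("a1", "a2", "b1"), subfamily = "FAM",
                    verdict = c("keep", "keep", "keep"),
                    stringsAsFactors = FALSE)
  sp <- c(a1 = "spA", a2 = "spA", b1 = "spB")
  s <- summarize_by_species(dec, sp, published_ids = "a1.1")
  rowA <- s[s$species == "spA", ]
  expect_equal(rowA$n_kept, 2)
  expect_equal(rowA$n_published, 1)
  expect_equal(rowA$n_new, 1)
})

test_that("identical inputs give identical decisions and report bytes", {
  cfg <- simulation_config(seed = 5)
  sim <- simulate_family(cfg)
  run <- function() {
    d <- decide(sim$groups, sim$hits, sim$refs)
    f <- tempfile(fileext = ".tsv")
    write_classification_report(d, f)
    on.exit(unlink(f))
    list(d = d, md5 = unname(tools::md5sum(f)))
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$d, r2$d)
  expect_identical(r1$md5, r2$md5)
})
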
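toy_loci <- function(n_per_chrom, chroms = c("c1", "c2")) {
  do.call(rbind, lapply(chroms, function(ch)
    data.frame(gene_id = sprintf("%s_g%02d", ch, 1:n_per_chrom),
               chromosome = ch, start = (1:n_per_chrom) * 100L,
               end = (1:n_per_chrom) * 100L + 50L, strand = "+",
               order_index = 1:n_per_chrom, stringsAsFactors = FALSE)))
}

test_that("ordered homolog runs chain into a single same-orientation block", {
  loci <- toy_loci(20)
  pairs <- data.frame(gene_a = sprintf("c1_g%02d", 3:7),
                      gene_b = sprintf("c2_g%02d", 11:15))
  blocks <- chain_collinear_blocks(loci, pairs)
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$orientation, "same")
  expect_equal(nrow(blocks[[1]]$anchors), 5)

  # reversed second-chromosome order: one inverted block
  pairs_inv <- data.frame(gene_a = sprintf("c1_g%02d", 3:7),
                          gene_b = sprintf("c2_g%02d", 15:11))
  blocks_inv <- chain_collinear_blocks(loci, pairs_inv)
  expect_length(blocks_inv, 1)
  expect_equal(blocks_inv[[1]]$orientation, "inverted")

  # four ordered pairs stay below the size floor
  blocks4 <- chain_collinear_blocks(loci, pairs[1:4, ])
  expect_length(blocks4, 0)
})

test_that("gap constraint splits distant anchor runs", {
  loci <- toy_loci(100)
  # two runs of 5 anchors separated by a 40-rank gap on both chromosomes
  pairs <- data.frame(gene_a = sprintf("c1_g%02d", c(1:5, 46:50)),
                      gene_b = sprintf("c2_g%02d", c(1:5, 46:50)))
  blocks <- chain_collinear_blocks(loci, pairs, max_gap = 25)
  expect_length(blocks, 2)
  # with the gap allowed and a mild penalty the two runs merge
  blocks_loose <- chain_collinear_blocks(loci, pairs, max_gap = 50,
                                         gap_penalty = 0.05)
  expect_length(blocks_loose, 1)
  expect_equal(nrow(blocks_loose[[1]]$anchors), 10)
})

test_that("pairs lacking placement are excluded with a warning", {
  loci <- toy_loci(10)
  pairs <- data.frame(gene_a = c("c1_g01", "scaffold_g1"),
                      gene_b = c("c2_g01", "c2_g02"))
  expect_warning(blocks <- chain_collinear_blocks(loci, pairs),
                 "without placement")
  expect_length(blocks, 0)
})

test_that("DP chain score equals exhaustive search on small instances", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(2:10, 1)
    pos_a <- sample(1:40, n)
    pos_b <- sample(1:40, n)
    mg <- sample(c(5, 25), 1)
    dp <- genefamkit:::best_chain(pos_a, pos_b, mg, 0.25)
    bf <- oracle_best_chain_score(pos_a, pos_b, mg, 0.25)
    expect_equal(dp$score, bf, tolerance = 1e-9)
  }
})

test_that("duplication typing follows the five-way precedence", {
  loci <- toy_loci(30)
  pairs <- data.frame(
    gene_a = c("c1_g07", "c1_g20", "c1_g01", sprintf("c1_g%02d", 10:14)),
    gene_b = c("c1_g08", "c1_g25", "c2_g09", sprintf("c2_g%02d", 20:24)))
  blocks <- chain_collinear_blocks(loci, pairs)
  dup <- classify_duplications(loci, pairs, blocks)
  type_of <- stats::setNames(dup$dup_type, dup$gene_id)
  expect_equal(unname(type_of[c("c1_g07", "c1_g08")]), rep("tandem", 2))
  expect_equal(unname(type_of[c("c1_g20", "c1_g25")]), rep("proximal", 2))
  expect_equal(unname(type_of[c("c1_g01", "c2_g09")]), rep("dispersed", 2))
  expect_equal(unname(type_of["c1_g12"]), "wgd_segmental")
  expect_equal(unname(type_of["c2_g22"]), "wgd_segmental")
  expect_equal(unname(type_of["c1_g03"]), "singleton")
})

test_that("planted duplication structure is fully recovered without noise", {
  cfg <- simulation_config(seed = 21)
  g <- simulate_genome(cfg)
  blocks <- chain_collinear_blocks(g$loci, g$pairs)
  dup <- classify_duplications(g$loci, g$pairs, blocks,
                               genes = g$truth$gene_id)
  m <- merge(dup, g$truth, by = "gene_id")
  expect_equal(mean(m$dup_type.x == m$dup_type.y), 1)
  # WGD/segmental and dispersed dominate this WGD-style plan
  planted <- table(g$truth$dup_type)
  expect_gt(planted[["wgd_segmental"]], max(planted[["tandem"]],
                                            planted[["proximal"]]))
})

test_that("subgenome summary partitions blocks", {
  loci <- toy_loci(20, chroms = c("A1", "D1", "D2"))
  mkpairs <- function(ca, cb, a0, b0) {
    data.frame(gene_a = sprintf("%s_g%02d", ca, a0:(a0 + 4)),
               gene_b = sprintf("%s_g%02d", cb, b0:(b0 + 4)))
  }
  pairs <- rbind(mkpairs("A1", "D1", 1, 1), mkpairs("D1", "D2", 10, 10))
  blocks <- chain_collinear_blocks(loci, pairs)
  s <- subgenome_collinearity_summary(blocks, c(A1 = "A", D1 = "D", D2 = "D"))
  expect_equal(s$between, 1L)
  expect_equal(unname(s$within["D"]), 1L)
  expect_equal(s$fraction_between, 0.5)
})

test_that("collinearity files list every anchor", {
  loci <- toy_loci(20)
  pairs <- data.frame(gene_a = sprintf("c1_g%02d", 1:6),
                      gene_b = sprintf("c2_g%02d", 1:6))
  blocks <- chain_collinear_blocks(loci, pairs)
  f <- withr::local_tempfile(fileext = ".txt")
  write_collinearity(blocks, f)
  txt <- readLines(f)
  expect_length(grep("^## Alignment", txt), 1)
  expect_length(grep("c1_g", txt), 6)
})
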
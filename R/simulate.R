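# Synthetic fixtures with planted ground truth.
#
# Every downstream stage is validated against data whose truth is known by
# construction: proteomes where family members carry the subfamily's
# diagnostic motif in a randomized kinase-like backbone and decoys do not;
# ranked hit tables with a configurable E-value separation (orders of
# magnitude) between members and decoys; orthogroups mirroring the true
# families, optionally contaminated with decoy genes; genomes with planted
# segmental blocks, tandem/proximal neighbors and dispersed duplicates;
# codon alignments evolved under a configured omega; and FPKM tables with
# planted fold-change classes.
#
# Hit tables are generated directly rather than by running a search binary:
# member E-values are drawn log-uniformly from a member band and decoys
# from a band at least `evalue_separation` orders of magnitude weaker, an
# explicit stand-in model documented in the package vignette. Each output
# file draws from its own random stream derived from the master seed, so
# adding a fixture type never perturbs existing ones.

#' Simulation configuration
#'
#' @param seed Master seed; fixes every output byte-identically.
#' @param species Species tags; the first is the anchor species holding the
#'   reference members.
#' @param family_sizes Named integer vector: subfamily -> number of
#'   orthogroups (one member gene per species each).
#' @param n_singleton_members Per subfamily, how many of those orthogroups
#'   are reduced to a single (non-anchor) member, exercising the singleton
#'   rule.
#' @param decoy_count Number of decoy proteins.
#' @param evalue_separation Orders of magnitude between the weakest member
#'   E-value and the strongest decoy E-value.
#' @param cluster_contamination_rate Probability that a family orthogroup
#'   is contaminated by adding enough decoy genes to push its completion
#'   ratio below 0.5.
#' @param motifs Named character vector: subfamily -> diagnostic consensus
#'   pattern (defaults: the kinase subdomain VIII motifs of the ZIK, MEKK
#'   and RAF subfamilies).
#' @param genome Genome-simulation settings (list): \code{chromosomes}
#'   (named by subgenome), \code{genes_per_chrom},
#'   \code{n_segmental_blocks}, \code{block_size}, \code{n_tandem},
#'   \code{n_proximal}, \code{n_dispersed}, \code{noise_rate}.
#' @param kaks Ka/Ks simulation settings: \code{n_pairs}, \code{n_codons},
#'   \code{omega}, \code{ks_depth}.
#' @param expression Expression settings: \code{fold_classes},
#'   \code{conditions}, \code{control}, \code{noise_sd} (multiplicative
#'   log-normal sd; 0 = noise-free).
#' @return A \code{simulation_config} list.
#' @export
simulation_config <- function(seed = 1L,
                              species = c("Ath", "Ghi", "Zma"),
                              family_sizes = c(ZIK = 6L, MEKK = 8L, RAF = 10L),
                              n_singleton_members = 1L,
                              decoy_count = 30L,
                              evalue_separation = 10,
                              cluster_contamination_rate = 0,
                              motifs = c(ZIK = "GTPEFMAPE(L/V/M)(Y/F/L)",
                                         MEKK = "G(T/S)Px(F/Y/W)MAPEV",
                                         RAF = "GTxx(W/Y)MAPE"),
                              genome = list(),
                              kaks = list(),
                              expression = list()) {
  if (cluster_contamination_rate < 0 || cluster_contamination_rate > 1)
    stop_validation("contamination rate must be in [0, 1]")
  genome <- utils::modifyList(list(
    chromosomes = c(A01 = "A", A02 = "A", D01 = "D", D02 = "D"),
    genes_per_chrom = 120L, n_segmental_blocks = 3L, block_size = 8L,
    n_tandem = 6L, n_proximal = 6L, n_dispersed = 6L, noise_rate = 0), genome)
  kaks <- utils::modifyList(list(n_pairs = 20L, n_codons = 300L,
                                 omega = 0.2, ks_depth = 0.3), kaks)
  expression <- utils::modifyList(list(
    fold_classes = c(2, 1.3, 1, 0.7, 0.4),
    conditions = c("cold", "heat", "drought", "salt"),
    control = "CK", noise_sd = 0), expression)
  structure(list(seed = as.integer(seed), species = species,
                 family_sizes = family_sizes,
                 n_singleton_members = as.integer(n_singleton_members),
                 decoy_count = as.integer(decoy_count),
                 evalue_separation = evalue_separation,
                 cluster_contamination_rate = cluster_contamination_rate,
                 motifs = motifs, genome = genome, kaks = kaks,
                 expression = expression),
            class = "simulation_config")
}

#' @keywords internal
random_protein <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

#' @keywords internal
instantiate_motif <- function(pattern) {
  cols <- parse_motif_pattern(pattern)
  paste(vapply(cols, function(a) {
    if (identical(a, "x")) sample(AA_ALPHABET, 1) else sample(a, 1)[1]
  }, ""), collapse = "")
}

#' Simulate family-identification fixtures
#'
#' Generates a proteome, an orthogroup clustering, per-subfamily ranked hit
#' tables, a reference set and the planted truth. When \code{out_dir} is
#' given, files are written (\code{proteome.faa}, \code{groups.txt},
#' \code{<subfamily>.tbl}, \code{truth_family.tsv}) and their paths
#' returned.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional output directory.
#' @return List with \code{proteins}, \code{groups}, \code{hits} (named
#'   list per subfamily), \code{refs} ([reference_set()]), \code{truth}
#'   (data frame \code{gene_id}, \code{species}, \code{subfamily},
#'   \code{is_member}) and, if written, \code{paths}.
#' @export
simulate_family <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, "family"))
  anchor <- config$species[1]
  subfams <- names(config$family_sizes)

  members <- list(); groups <- list(); gidx <- 0
  for (sf in subfams) {
    n_groups <- config$family_sizes[[sf]]
    n_single <- min(config$n_singleton_members, n_groups - 1)
    for (g in seq_len(n_groups)) {
      gidx <- gidx + 1
      singleton <- g > n_groups - n_single
      sps <- if (singleton) config$species[2] else config$species
      genes <- paste0(sps, "_", sf, sprintf("%02d", g))
      tx <- paste0(genes, ".1")
      # the anchor gene of group 1 gets a second transcript variant
      if (!singleton && g == 1) {
        genes <- c(genes, genes[1]); sps <- c(sps, sps[1])
        tx <- c(tx, paste0(genes[1], ".2"))
      }
      members[[length(members) + 1]] <- data.frame(
        group_id = sprintf("OG%04d", gidx), species = sps,
        gene_id = genes, transcript_id = tx, subfamily = sf,
        stringsAsFactors = FALSE)
    }
  }
  fam <- do.call(rbind, members)

  decoys <- data.frame(
    group_id = NA_character_,
    species = sample(config$species, config$decoy_count, replace = TRUE),
    gene_id = sprintf("DEC%03d", seq_len(config$decoy_count)),
    stringsAsFactors = FALSE)
  decoys$transcript_id <- paste0(decoys$gene_id, ".1")
  # decoy clusters: groups of three, remainder singletons
  n3 <- config$decoy_count %/% 3
  decoys$group_id <- c(rep(sprintf("DG%03d", seq_len(n3)), each = 3),
                       sprintf("DS%03d", seq_len(config$decoy_count - 3 * n3)))

  # contamination: push a family group's completion ratio below 0.5 by
  # moving decoys into it
  contaminated <- character(0)
  if (config$cluster_contamination_rate > 0) {
    pool <- decoys$gene_id
    for (gid in unique(fam$group_id)) {
      if (stats::runif(1) < config$cluster_contamination_rate) {
        n_mem <- length(unique(fam$gene_id[fam$group_id == gid]))
        need <- n_mem + 1
        if (length(pool) >= need) {
          take <- pool[seq_len(need)]
          pool <- setdiff(pool, take)
          decoys$group_id[decoys$gene_id %in% take] <- gid
          contaminated <- c(contaminated, gid)
        }
      }
    }
  }

  # proteins: members carry their subfamily motif, decoys do not
  prot_rows <- list()
  for (i in seq_len(nrow(fam))) {
    if (grepl("\\.2$", fam$transcript_id[i])) next  # variant shares the gene product
    len <- sample(250:350, 1)
    motif <- instantiate_motif(config$motifs[[fam$subfamily[i]]])
    pos <- sample(20:(len - nchar(motif) - 20), 1)
    backbone <- random_protein(len)
    seqs <- paste0(substr(backbone, 1, pos - 1), motif,
                   substr(backbone, pos + nchar(motif), len))
    prot_rows[[length(prot_rows) + 1]] <- data.frame(
      id = fam$transcript_id[i], species = fam$species[i], sequence = seqs,
      is_longest_variant = TRUE, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(decoys))) {
    prot_rows[[length(prot_rows) + 1]] <- data.frame(
      id = decoys$transcript_id[i], species = decoys$species[i],
      sequence = random_protein(sample(200:400, 1)),
      is_longest_variant = TRUE, stringsAsFactors = FALSE)
  }
  proteins <- do.call(rbind, prot_rows)

  # ranked hit tables: per-gene base E-values for members, worst forced onto
  # an anchor-species reference gene so the threshold rule recovers truth
  hits <- list()
  set.seed(derive_seed(config$seed, "hits"))
  for (sf in subfams) {
    sub <- fam[fam$subfamily == sf, ]
    genes <- unique(sub$gene_id)
    base_log10 <- stats::runif(length(genes), -150, -60)
    names(base_log10) <- genes
    worst <- names(which.max(base_log10))
    anchor_genes <- unique(sub$gene_id[sub$species == anchor])
    if (!worst %in% anchor_genes) {
      swap_with <- sample(anchor_genes, 1)
      tmp <- base_log10[worst]
      base_log10[worst] <- base_log10[swap_with]
      base_log10[swap_with] <- tmp
    }
    rows <- data.frame(target_id = sub$transcript_id,
                       evalue = 10^(base_log10[sub$gene_id]),
                       stringsAsFactors = FALSE)
    # secondary variants score slightly worse than the first transcript
    rows$evalue[grepl("\\.2$", rows$target_id)] <-
      rows$evalue[grepl("\\.2$", rows$target_id)] * 2
    max_member_log10 <- max(base_log10)
    dec_log10 <- stats::runif(nrow(decoys),
                              max_member_log10 + config$evalue_separation,
                              max_member_log10 + config$evalue_separation + 30)
    dec_log10 <- pmin(dec_log10, -0.5)
    rows <- rbind(rows, data.frame(target_id = decoys$transcript_id,
                                   evalue = 10^dec_log10,
                                   stringsAsFactors = FALSE))
    rows <- rows[order(rows$evalue, rows$target_id), ]
    rows$bitscore <- round(-log10(rows$evalue) * 2.2 + 20, 1)
    rows$subfamily <- sf
    rows$rank <- seq_len(nrow(rows))
    rownames(rows) <- NULL
    hits[[sf]] <- rows[, c("target_id", "subfamily", "evalue", "bitscore", "rank")]
  }

  ref_members <- lapply(stats::setNames(subfams, subfams), function(sf) {
    sub <- fam[fam$subfamily == sf & fam$species == anchor, ]
    sub$transcript_id
  })
  refs <- reference_set(ref_members,
                        force_include = unique(fam$gene_id[fam$species == anchor]))

  groups_df <- rbind(fam[, c("group_id", "species", "gene_id", "transcript_id")],
                     decoys[, c("group_id", "species", "gene_id", "transcript_id")])
  truth <- rbind(
    unique(data.frame(gene_id = fam$gene_id, species = fam$species,
                      subfamily = fam$subfamily, is_member = TRUE,
                      stringsAsFactors = FALSE)),
    data.frame(gene_id = decoys$gene_id, species = decoys$species,
               subfamily = NA_character_, is_member = FALSE,
               stringsAsFactors = FALSE))

  out <- list(proteins = proteins, groups = groups_df, hits = hits,
              refs = refs, truth = truth, contaminated_groups = contaminated)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(proteome = file.path(out_dir, "proteome.faa"),
                  groups = file.path(out_dir, "groups.txt"),
                  truth = file.path(out_dir, "truth_family.tsv"))
    write_fasta(proteins, paths$proteome)
    write_orthogroups(groups_df, paths$groups)
    for (sf in subfams) {
      paths[[paste0("tblout_", sf)]] <- file.path(out_dir, paste0(sf, ".tbl"))
      write_hmm_tblout(hits[[sf]], paths[[paste0("tblout_", sf)]], query = sf)
    }
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}

#' Simulate a genome with planted duplication structure
#'
#' Chromosomes carry ordered gene loci; homolog pairs are planted as
#' segmental blocks (order-preserving runs across chromosomes, at least one
#' inverted), tandem neighbors (adjacent ranks), proximal pairs (2 to 10
#' ranks apart) and dispersed cross-chromosome pairs, plus optional random
#' noise pairs. No planted gene takes part in two features.
#'
#' @param config A [simulation_config()] (see its \code{genome} entry).
#' @param out_dir Optional output directory (\code{genome.gff3},
#'   \code{pairs.tsv}, \code{truth_genome.tsv}).
#' @return List with \code{loci}, \code{pairs}, \code{truth} (data frame
#'   \code{gene_id}, \code{dup_type}) and, if written, \code{paths}.
#' @export
simulate_genome <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  g <- config$genome
  set.seed(derive_seed(config$seed, "genome"))
  chroms <- names(g$chromosomes)
  loci <- do.call(rbind, lapply(chroms, function(ch) {
    n <- g$genes_per_chrom
    data.frame(gene_id = sprintf("%s_G%03d", ch, seq_len(n)),
               chromosome = ch,
               start = seq_len(n) * 1000L,
               end = seq_len(n) * 1000L + 500L,
               strand = "+", order_index = seq_len(n),
               stringsAsFactors = FALSE)
  }))
  used <- stats::setNames(lapply(chroms, function(x) integer(0)), chroms)
  claim_run <- function(ch, len) {
    for (tries in 1:200) {
      s <- sample(seq_len(g$genes_per_chrom - len + 1), 1)
      run <- s:(s + len - 1)
      if (!any(run %in% used[[ch]])) {
        used[[ch]] <<- c(used[[ch]], run)
        return(run)
      }
    }
    stop_data("could not place a feature; genome too small for the plan")
  }
  gene_at <- function(ch, ranks) sprintf("%s_G%03d", ch, ranks)
  pairs <- list(); truth <- list()
  add_truth <- function(genes, type) {
    truth[[length(truth) + 1]] <<- data.frame(gene_id = genes, dup_type = type,
                                              stringsAsFactors = FALSE)
  }
  # segmental blocks across chromosomes; every other block inverted
  for (b in seq_len(g$n_segmental_blocks)) {
    cs <- sample(chroms, 2)
    ra <- claim_run(cs[1], g$block_size)
    rb <- claim_run(cs[2], g$block_size)
    if (b %% 2 == 0) rb <- rev(rb)
    pairs[[length(pairs) + 1]] <- data.frame(gene_a = gene_at(cs[1], ra),
                                             gene_b = gene_at(cs[2], rb),
                                             stringsAsFactors = FALSE)
    add_truth(c(gene_at(cs[1], ra), gene_at(cs[2], rb)), "wgd_segmental")
  }
  for (i in seq_len(g$n_tandem)) {
    ch <- sample(chroms, 1)
    run <- claim_run(ch, 2)
    pairs[[length(pairs) + 1]] <- data.frame(gene_a = gene_at(ch, run[1]),
                                             gene_b = gene_at(ch, run[2]),
                                             stringsAsFactors = FALSE)
    add_truth(gene_at(ch, run), "tandem")
  }
  for (i in seq_len(g$n_proximal)) {
    ch <- sample(chroms, 1)
    d <- sample(2:10, 1)
    run <- claim_run(ch, d + 1)
    # interior ranks released: only the endpoints are the duplicate pair
    used[[ch]] <- setdiff(used[[ch]], run[c(-1, -length(run))])
    pairs[[length(pairs) + 1]] <- data.frame(gene_a = gene_at(ch, run[1]),
                                             gene_b = gene_at(ch, run[length(run)]),
                                             stringsAsFactors = FALSE)
    add_truth(gene_at(ch, run[c(1, length(run))]), "proximal")
  }
  for (i in seq_len(g$n_dispersed)) {
    cs <- sample(chroms, 2)
    ra <- claim_run(cs[1], 1)
    rb <- claim_run(cs[2], 1)
    pairs[[length(pairs) + 1]] <- data.frame(gene_a = gene_at(cs[1], ra),
                                             gene_b = gene_at(cs[2], rb),
                                             stringsAsFactors = FALSE)
    add_truth(c(gene_at(cs[1], ra), gene_at(cs[2], rb)), "dispersed")
  }
  pairs <- do.call(rbind, pairs)
  truth <- do.call(rbind, truth)
  n_noise <- round(g$noise_rate * nrow(pairs))
  if (n_noise > 0) {
    free <- setdiff(loci$gene_id, c(truth$gene_id))
    noise <- data.frame(gene_a = sample(free, n_noise),
                        gene_b = sample(setdiff(free, character(0)), n_noise),
                        stringsAsFactors = FALSE)
    noise <- noise[noise$gene_a != noise$gene_b, , drop = FALSE]
    pairs <- rbind(pairs, noise)
  }
  pairs$score <- 1
  out <- list(loci = loci, pairs = pairs, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(gff = file.path(out_dir, "genome.gff3"),
                  pairs = file.path(out_dir, "pairs.tsv"),
                  truth = file.path(out_dir, "truth_genome.tsv"))
    write_gene_loci_gff3(loci, paths$gff)
    utils::write.table(pairs, paths$pairs, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}

#' Simulate aligned codon pairs under a configured omega
#'
#' Each pair starts from a random sense-codon ancestor; the second copy
#' accrues point mutations (uniform proposals over sites and alternative
#' nucleotides) where mutations creating stop codons are rejected,
#' synonymous changes are always accepted and nonsynonymous changes are
#' accepted with probability omega. The proposal count is scaled so the
#' expected synonymous substitutions per synonymous site equal
#' \code{ks_depth}.
#'
#' @param config A [simulation_config()] (see its \code{kaks} entry).
#' @param out_dir Optional output directory (\code{cds_pairs.fna},
#'   \code{truth_kaks.tsv}).
#' @return List with \code{cds} (named vector of sequences), \code{pairs}
#'   (data frame \code{gene_a}, \code{gene_b}), \code{truth} (per-pair
#'   \code{omega} and accepted substitution counts) and, if written,
#'   \code{paths}.
#' @export
simulate_cds_pairs <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  k <- config$kaks
  set.seed(derive_seed(config$seed, "cds"))
  code <- genetic_code()
  sense <- names(code)[code != "*"]
  nts <- c("A", "C", "G", "T")
  cds <- character(0); prs <- list(); truth <- list()
  for (p in seq_len(k$n_pairs)) {
    a_codons <- sample(sense, k$n_codons, replace = TRUE)
    b_codons <- a_codons
    n_prop <- round(3 * k$n_codons * k$ks_depth)
    acc_syn <- 0L; acc_non <- 0L
    for (m in seq_len(n_prop)) {
      ci <- sample(k$n_codons, 1)
      pos <- sample(3L, 1)
      cur <- b_codons[ci]
      alt <- sample(setdiff(nts, substr(cur, pos, pos)), 1)
      mut <- cur
      substr(mut, pos, pos) <- alt
      if (code[mut] == "*") next
      if (code[mut] == code[cur]) {
        b_codons[ci] <- mut; acc_syn <- acc_syn + 1L
      } else if (stats::runif(1) < k$omega) {
        b_codons[ci] <- mut; acc_non <- acc_non + 1L
      }
    }
    ida <- sprintf("pair%02d_a", p); idb <- sprintf("pair%02d_b", p)
    cds[ida] <- paste(a_codons, collapse = "")
    cds[idb] <- paste(b_codons, collapse = "")
    prs[[p]] <- data.frame(gene_a = ida, gene_b = idb, stringsAsFactors = FALSE)
    truth[[p]] <- data.frame(gene_a = ida, gene_b = idb, omega = k$omega,
                             accepted_syn = acc_syn, accepted_nonsyn = acc_non,
                             stringsAsFactors = FALSE)
  }
  out <- list(cds = cds, pairs = do.call(rbind, prs),
              truth = do.call(rbind, truth))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(cds = file.path(out_dir, "cds_pairs.fna"),
                  pairs = file.path(out_dir, "cds_pairs.tsv"),
                  truth = file.path(out_dir, "truth_kaks.tsv"))
    writeLines(paste0(">", names(out$cds), "\n", out$cds), paths$cds)
    utils::write.table(out$pairs, paths$pairs, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(out$truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}

#' Simulate an FPKM table with planted fold-change classes
#'
#' Control FPKM is log-normal, shifted away from zero so every planted
#' down-fold stays realizable; the treatment value realizes a planted fold
#' change on the shifted (FPKM + 1) scale — treatment = fc * (control + 1)
#' - 1 — so that noise-free labels recover the planted classes exactly,
#' optionally times multiplicative log-normal noise.
#'
#' @param config A [simulation_config()] (see its \code{expression} entry).
#' @param gene_ids Gene identifiers to simulate (default 40 synthetic ids).
#' @param out_dir Optional output directory (\code{fpkm.tsv},
#'   \code{truth_expression.tsv}).
#' @return List with \code{table} (an [expression_table()]), \code{truth}
#'   (per gene x condition planted fold class and expected label) and, if
#'   written, \code{paths}.
#' @export
simulate_expression <- function(config, gene_ids = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  e <- config$expression
  set.seed(derive_seed(config$seed, "expression"))
  if (is.null(gene_ids)) gene_ids <- sprintf("GENE%03d", 1:40)
  n <- length(gene_ids)
  # shifted log-normal: keeps every planted down-fold above zero FPKM so the
  # planted class is realized exactly (no clamping)
  min_ctrl <- 1 / min(e$fold_classes) - 1
  ctrl <- round(min_ctrl + exp(stats::rnorm(n, mean = 2.5, sd = 0.8)), 3)
  mat <- matrix(0, nrow = n, ncol = length(e$conditions) + 1,
                dimnames = list(gene_ids, c(e$control, e$conditions)))
  mat[, e$control] <- ctrl
  truth <- list()
  for (cond in e$conditions) {
    fc <- sample(e$fold_classes, n, replace = TRUE)
    treat <- pmax(0, fc * (ctrl + 1) - 1)
    if (e$noise_sd > 0) {
      treat <- pmax(0, (treat + 1) * exp(stats::rnorm(n, 0, e$noise_sd)) - 1)
    }
    mat[, cond] <- round(treat, 6)
    truth[[cond]] <- data.frame(gene_id = gene_ids, condition = cond,
                                planted_fold = fc,
                                expected_label = de_label(fc),
                                stringsAsFactors = FALSE)
  }
  tbl <- expression_table(gene_ids, colnames(mat), e$control, mat)
  out <- list(table = tbl, truth = do.call(rbind, truth))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(fpkm = file.path(out_dir, "fpkm.tsv"),
                  truth = file.path(out_dir, "truth_expression.tsv"))
    write_expression_tsv(tbl, paths$fpkm)
    utils::write.table(out$truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}
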
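# Collinearity chaining and duplication typing.
#
# Homologous gene pairs are mapped to gene-rank coordinates (order index
# along each chromosome) and chained, per chromosome pair and orientation,
# into collinear blocks by dynamic programming: an anchor scores 1 and
# consecutive anchors pay a per-rank gap penalty, with gaps capped at
# max_gap ranks on both chromosomes. Chains of at least min_block_size
# anchors are extracted greedily (best chain first, anchors removed, repeat)
# so blocks never share anchors on the same chromosome pair.
#
# Duplication types then follow the usual five-way precedence:
#   wgd_segmental > tandem > proximal > dispersed > singleton
# a gene in any block anchor is WGD/segmental; else a same-chromosome pair
# at adjacent ranks makes it tandem; else within proximal_rank ranks makes
# it proximal; any remaining pair is dispersed; no pair at all, singleton.

#' Read a two-column homolog pair TSV
#'
#' @param path TSV with columns \code{gene_a}, \code{gene_b} and optionally
#'   \code{score}; a header row is detected by non-numeric third column or
#'   the literal names.
#' @return Data frame with \code{gene_a}, \code{gene_b}, \code{score}.
#' @export
read_homolog_pairs <- function(path) {
  if (!file.exists(path)) stop_data("pairs file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(df))) {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(df)[1:2] <- c("gene_a", "gene_b")
  }
  if (is.null(df$score)) df$score <- 1
  if (any(df$gene_a == df$gene_b)) stop_data("self-pair in homolog pairs")
  key <- paste(pmin(df$gene_a, df$gene_b), pmax(df$gene_a, df$gene_b))
  df[!duplicated(key), c("gene_a", "gene_b", "score")]
}

#' Chain homolog pairs into collinear blocks
#'
#' @param loci Gene loci from [read_gff3_gene_loci()].
#' @param pairs Homolog pairs (\code{gene_a}, \code{gene_b}).
#' @param min_block_size Minimum anchors per block (default 5).
#' @param max_gap Maximum intervening gene ranks between consecutive
#'   anchors on either chromosome (default 25).
#' @param gap_penalty Score penalty per skipped rank (default 0.25; an
#'   anchor scores 1).
#' @return List of blocks; each block is a list with \code{chrom_a},
#'   \code{chrom_b}, \code{orientation} ("same"/"inverted"), \code{score},
#'   and \code{anchors} (data frame \code{gene_a}, \code{gene_b},
#'   \code{pos_a}, \code{pos_b} in rank coordinates).
#' @export
chain_collinear_blocks <- function(loci, pairs, min_block_size = 5,
                                   max_gap = 25, gap_penalty = 0.25) {
  if (nrow(pairs) == 0) return(list())
  chrom_of <- stats::setNames(loci$chromosome, loci$gene_id)
  rank_of <- stats::setNames(loci$order_index, loci$gene_id)
  known <- pairs$gene_a %in% names(rank_of) & pairs$gene_b %in% names(rank_of)
  if (any(!known)) {
    warning(sum(!known), " pair(s) reference genes without placement; excluded",
            call. = FALSE)
    pairs <- pairs[known, , drop = FALSE]
  }
  if (nrow(pairs) == 0) return(list())
  ca <- unname(chrom_of[pairs$gene_a]); cb <- unname(chrom_of[pairs$gene_b])
  # canonical orientation: chrom_a <= chrom_b; within a chromosome pos_a < pos_b
  swap <- ca > cb | (ca == cb & rank_of[pairs$gene_a] > rank_of[pairs$gene_b])
  ga <- ifelse(swap, pairs$gene_b, pairs$gene_a)
  gb <- ifelse(swap, pairs$gene_a, pairs$gene_b)
  anchors <- data.frame(gene_a = ga, gene_b = gb,
                        chrom_a = unname(chrom_of[ga]), chrom_b = unname(chrom_of[gb]),
                        pos_a = unname(rank_of[ga]), pos_b = unname(rank_of[gb]),
                        stringsAsFactors = FALSE)
  blocks <- list()
  for (cp in unique(paste(anchors$chrom_a, anchors$chrom_b))) {
    sub <- anchors[paste(anchors$chrom_a, anchors$chrom_b) == cp, , drop = FALSE]
    repeat {
      best <- NULL
      for (orient in c("same", "inverted")) {
        ch <- best_chain(sub$pos_a, if (orient == "same") sub$pos_b else -sub$pos_b,
                         max_gap, gap_penalty)
        if (!is.null(ch) && (is.null(best) || ch$score > best$score)) {
          best <- ch; best$orientation <- orient
        }
      }
      if (is.null(best) || length(best$idx) < min_block_size) break
      bl <- sub[best$idx, , drop = FALSE]
      blocks[[length(blocks) + 1]] <- list(
        chrom_a = bl$chrom_a[1], chrom_b = bl$chrom_b[1],
        orientation = best$orientation, score = best$score,
        anchors = bl[, c("gene_a", "gene_b", "pos_a", "pos_b")])
      sub <- sub[-best$idx, , drop = FALSE]
      if (nrow(sub) < min_block_size) break
    }
  }
  # post-hoc invariant check: gap constraint and monotonicity on every block
  for (b in blocks) {
    da <- diff(b$anchors$pos_a)
    db <- diff(b$anchors$pos_b)
    stopifnot(all(da >= 1), all(da - 1 <= max_gap),
              all(abs(db) - 1 <= max_gap),
              if (b$orientation == "same") all(db >= 1) else all(db <= -1))
  }
  blocks
}

# Single best chain by DP over anchors monotone increasing in both
# coordinate vectors, gap <= max_gap ranks on each. Score: 1 per anchor
# minus gap_penalty per skipped rank (the larger of the two gaps).
#' @keywords internal
best_chain <- function(pos_a, pos_b, max_gap, gap_penalty) {
  n <- length(pos_a)
  if (n == 0) return(NULL)
  ord <- order(pos_a, pos_b)
  pa <- pos_a[ord]; pb <- pos_b[ord]
  dp <- rep(1, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      da <- pa[i] - pa[j]; db <- pb[i] - pb[j]
      if (da >= 1 && db >= 1 && (da - 1) <= max_gap && (db - 1) <= max_gap) {
        cand <- dp[j] + 1 - gap_penalty * (max(da, db) - 1)
        if (cand > dp[i]) { dp[i] <- cand; prev[i] <- j }
      }
    }
  }
  i <- which.max(dp)
  idx <- integer(0)
  while (i != 0L) { idx <- c(i, idx); i <- prev[i] }
  list(idx = ord[idx], score = max(dp))  # in chain order (ascending pos_a)
}

#' Classify duplication origin of genes
#'
#' @param loci Gene loci table.
#' @param pairs Homolog pairs.
#' @param blocks Output of [chain_collinear_blocks()] on the same inputs.
#' @param genes Genes to type (default: every gene in \code{loci}).
#' @param proximal_rank Maximum rank separation for "proximal" (default 10).
#' @param tandem_rank Maximum rank separation for "tandem" (default 1,
#'   i.e. adjacent genes).
#' @return Data frame \code{gene_id}, \code{dup_type} with
#'   \code{dup_type} one of singleton, dispersed, proximal, tandem,
#'   wgd_segmental (precedence in that increasing order).
#' @export
classify_duplications <- function(loci, pairs, blocks, genes = NULL,
                                  proximal_rank = 10, tandem_rank = 1) {
  if (is.null(genes)) genes <- loci$gene_id
  chrom_of <- stats::setNames(loci$chromosome, loci$gene_id)
  rank_of <- stats::setNames(loci$order_index, loci$gene_id)
  anchor_genes <- unique(unlist(lapply(blocks, function(b)
    c(b$anchors$gene_a, b$anchors$gene_b))))
  keep <- pairs$gene_a %in% names(rank_of) & pairs$gene_b %in% names(rank_of)
  pairs <- pairs[keep, , drop = FALSE]
  partner <- split(c(pairs$gene_b, pairs$gene_a), c(pairs$gene_a, pairs$gene_b))
  dup <- vapply(genes, function(g) {
    ps <- unique(partner[[g]])
    if (is.null(ps) || length(ps) == 0) return("singleton")
    if (g %in% anchor_genes) return("wgd_segmental")
    same <- ps[chrom_of[ps] == chrom_of[[g]]]
    if (length(same)) {
      dr <- abs(rank_of[same] - rank_of[[g]])
      if (any(dr <= tandem_rank)) return("tandem")
      if (any(dr <= proximal_rank)) return("proximal")
    }
    "dispersed"
  }, "")
  data.frame(gene_id = genes, dup_type = unname(dup), stringsAsFactors = FALSE)
}

#' Summarize collinear blocks by subgenome
#'
#' @param blocks Output of [chain_collinear_blocks()].
#' @param subgenome_of_chrom Named character vector: chromosome ->
#'   subgenome label (e.g. "A"/"D").
#' @return List with \code{within} (named counts per subgenome),
#'   \code{between} (count of cross-subgenome blocks),
#'   \code{fraction_between}, and \code{within_ratio} (largest within
#'   count over smallest, \code{NA} if a subgenome has none).
#' @export
subgenome_collinearity_summary <- function(blocks, subgenome_of_chrom) {
  if (length(blocks) == 0) {
    return(list(within = integer(0), between = 0L,
                fraction_between = NA_real_, within_ratio = NA_real_))
  }
  sa <- vapply(blocks, function(b) unname(subgenome_of_chrom[b$chrom_a]), "")
  sb <- vapply(blocks, function(b) unname(subgenome_of_chrom[b$chrom_b]), "")
  if (anyNA(sa) || anyNA(sb)) stop_validation("chromosome without subgenome label")
  within <- table(sa[sa == sb])
  between <- sum(sa != sb)
  ratio <- if (length(within) >= 2) max(within) / min(within) else NA_real_
  list(within = c(within), between = between,
       fraction_between = between / length(blocks), within_ratio = ratio)
}

#' Write collinear blocks as text
#'
#' MCScanX-style listing: one alignment header per block followed by its
#' anchor pairs.
#'
#' @param blocks Output of [chain_collinear_blocks()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_collinearity <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("############### collinear blocks ###############", con)
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    writeLines(sprintf("## Alignment %d: score=%.2f N=%d %s&%s %s",
                       k - 1, b$score, nrow(b$anchors), b$chrom_a, b$chrom_b,
                       if (b$orientation == "same") "plus" else "minus"), con)
    writeLines(sprintf("%3d-%3d:\t%s\t%s", k - 1, seq_len(nrow(b$anchors)) - 1,
                       b$anchors$gene_a, b$anchors$gene_b), con)
  }
  invisible(path)
}
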
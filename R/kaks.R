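# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction.
#
# Synonymous/nonsynonymous site counts: per codon position, the fraction of
# the three possible single-nucleotide changes that preserve the encoded
# amino acid (changes to stop codons count as nonsynonymous), so each codon
# contributes exactly 3 sites. Substitutions between differing codons are
# counted by averaging over all minimal mutational pathways (orderings of
# the differing positions), skipping pathways that pass through a stop
# codon; if every pathway does, all are used with stop steps counted as
# nonsynonymous. Proportions are Jukes-Cantor corrected,
# d = -(3/4) log(1 - (4/3) p), undefined ("saturated") at p >= 3/4.
# Ka/Ks is NA when Ks = 0 or either distance is saturated.

codon_table_env <- new.env(parent = emptyenv())

#' @keywords internal
genetic_code <- function() {
  if (is.null(codon_table_env$code)) {
    gc <- Biostrings::GENETIC_CODE
    codon_table_env$code <- stats::setNames(as.character(gc), names(gc))
  }
  codon_table_env$code
}

#' @keywords internal
translate_codon <- function(codon) {
  aa <- genetic_code()[codon]
  if (is.na(aa)) stop_validation("invalid codon '", codon, "'")
  unname(aa)
}

#' Synonymous and nonsynonymous site counts of one codon
#'
#' For each of the three positions, the fraction of the three possible
#' single-nucleotide changes that are synonymous (mutations to stop codons
#' count as nonsynonymous) is the position's synonymous site contribution;
#' the counts always sum to 3.
#'
#' @param codon A 3-letter string over ACGT encoding a sense codon.
#' @return Named numeric vector \code{c(syn = ..., nonsyn = ...)}.
#' @export
count_sites <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3 || grepl("[^ACGT]", codon))
    stop_validation("invalid codon '", codon, "'")
  cached <- codon_table_env$sites[[codon]]
  if (!is.null(cached)) return(cached)
  aa <- translate_codon(codon)
  if (aa == "*") stop_validation("stop codon '", codon, "' has no site counts")
  nts <- c("A", "C", "G", "T")
  syn <- 0
  for (pos in 1:3) {
    for (nt in setdiff(nts, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (translate_codon(mut) == aa) syn <- syn + 1 / 3
    }
  }
  out <- c(syn = syn, nonsyn = 3 - syn)
  if (is.null(codon_table_env$sites)) codon_table_env$sites <- list()
  codon_table_env$sites[[codon]] <- out
  out
}

#' Construct a pairwise codon alignment
#'
#' Splits two in-frame coding sequences into codons, removes codon pairs
#' where either sequence has a gap, and validates: equal length, ACGT
#' alphabet, no internal stop codons.
#'
#' @param id_a,id_b Sequence identifiers.
#' @param seq_a,seq_b Aligned nucleotide strings (length divisible by 3;
#'   \code{-} allowed as gap).
#' @return Object of class \code{codon_alignment}: list with \code{id_a},
#'   \code{id_b}, \code{codons_a}, \code{codons_b}.
#' @export
codon_alignment <- function(id_a, id_b, seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    stop_validation("aligned sequences differ in length (", id_a, ", ", id_b, ")")
  if (nchar(seq_a) %% 3 != 0)
    stop_validation("alignment length not divisible by 3")
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  ca <- split3(seq_a); cb <- split3(seq_b)
  gap <- grepl("-", ca) | grepl("-", cb)
  ca <- ca[!gap]; cb <- cb[!gap]
  if (length(ca) == 0) stop_validation("no aligned codons left after gap removal")
  if (any(grepl("[^ACGT]", c(ca, cb))))
    stop_validation("non-ACGT character in coding sequence")
  code <- genetic_code()
  # trailing stop codons are trimmed; internal stops are an error
  while (length(ca) > 1 && (code[ca[length(ca)]] == "*" || code[cb[length(cb)]] == "*")) {
    ca <- ca[-length(ca)]; cb <- cb[-length(cb)]
  }
  if (any(code[ca] == "*") || any(code[cb] == "*"))
    stop_validation("internal stop codon in alignment (", id_a, ", ", id_b, ")")
  structure(list(id_a = id_a, id_b = id_b, codons_a = ca, codons_b = cb),
            class = "codon_alignment")
}

# Average synonymous/nonsynonymous substitution counts between two codons
# over all minimal mutational pathways.
#' @keywords internal
count_codon_differences <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(syn = 0, nonsyn = 0))
  perms <- if (k == 1) list(pos) else {
    pm <- list()
    recurse <- function(prefix, rest) {
      if (length(rest) == 0) { pm[[length(pm) + 1]] <<- prefix; return() }
      for (r in rest) recurse(c(prefix, r), setdiff(rest, r))
    }
    recurse(integer(0), pos)
    pm
  }
  code <- genetic_code()
  path_counts <- function(order, count_stop_steps) {
    cur <- ca; s <- 0; n <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (code[nxt] == "*" && !count_stop_steps) return(NULL)
      if (code[cur] == code[nxt]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s, n)
  }
  res <- Filter(Negate(is.null), lapply(perms, path_counts, count_stop_steps = FALSE))
  if (length(res) == 0) {
    res <- lapply(perms, path_counts, count_stop_steps = TRUE)
  }
  m <- Reduce(`+`, res) / length(res)
  c(syn = m[1], nonsyn = m[2])
}

#' @keywords internal
jukes_cantor <- function(p) {
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - (4 / 3) * p)
}

#' Compute Ka, Ks and their ratio for one codon alignment
#'
#' @param alignment A [codon_alignment()].
#' @return Object of class \code{kaks_result}: list with \code{Ka},
#'   \code{Ks}, \code{ratio} (NA when Ks is 0 or a distance is saturated),
#'   substitution counts \code{Nd}, \code{Sd}, site counts \code{N_sites},
#'   \code{S_sites}, proportions \code{pN}, \code{pS}, and flag
#'   \code{saturated}.
#' @export
compute_kaks <- function(alignment) {
  if (!inherits(alignment, "codon_alignment"))
    stop_validation("alignment must be a codon_alignment")
  ca <- alignment$codons_a; cb <- alignment$codons_b
  sites_a <- vapply(ca, count_sites, c(syn = 0, nonsyn = 0))
  sites_b <- vapply(cb, count_sites, c(syn = 0, nonsyn = 0))
  S <- (sum(sites_a["syn", ]) + sum(sites_b["syn", ])) / 2
  N <- (sum(sites_a["nonsyn", ]) + sum(sites_b["nonsyn", ])) / 2
  diffs <- mapply(function(x, y) count_codon_differences(x, y), ca, cb)
  Sd <- sum(diffs["syn", ]); Nd <- sum(diffs["nonsyn", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  Ks <- jukes_cantor(pS)
  Ka <- jukes_cantor(pN)
  saturated <- is.na(Ks) || is.na(Ka)
  ratio <- if (saturated || is.na(Ks) || Ks == 0) NA_real_ else Ka / Ks
  structure(list(Ka = Ka, Ks = Ks, ratio = ratio, Nd = Nd, Sd = Sd,
                 N_sites = N, S_sites = S, pN = pN, pS = pS,
                 saturated = saturated, n_codons = length(ca)),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("Ka = %.4f  Ks = %.4f  Ka/Ks = %s  (%d codons%s)\n",
              x$Ka, x$Ks,
              if (is.na(x$ratio)) "NA" else sprintf("%.4f", x$ratio),
              x$n_codons, if (x$saturated) ", saturated" else ""))
  invisible(x)
}

#' Ka/Ks table for a set of gene pairs
#'
#' @param pairs Data frame with \code{gene_a}, \code{gene_b}.
#' @param cds Named character vector (or [read_fasta()]-style data frame)
#'   of aligned, in-frame coding sequences; pair members must have equal
#'   aligned lengths.
#' @return Data frame with one row per pair: ids, \code{Ka}, \code{Ks},
#'   \code{ratio}, \code{Nd}, \code{Sd}, \code{N_sites}, \code{S_sites},
#'   \code{saturated}.
#' @export
kaks_table <- function(pairs, cds) {
  if (is.data.frame(cds)) cds <- stats::setNames(cds$sequence, cds$id)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    if (is.na(cds[a]) || is.na(cds[b]))
      stop_data("coding sequence missing for pair ", a, " / ", b)
    r <- compute_kaks(codon_alignment(a, b, cds[[a]], cds[[b]]))
    data.frame(gene_a = a, gene_b = b, Ka = r$Ka, Ks = r$Ks, ratio = r$ratio,
               Nd = r$Nd, Sd = r$Sd, N_sites = r$N_sites, S_sites = r$S_sites,
               saturated = r$saturated, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
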
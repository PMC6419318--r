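# Independent oracles used to validate the package's implementations.
# These are deliberately written as brute-force enumerations, separate from
# the code paths they check.

# --- Nei-Gojobori by direct enumeration -------------------------------------

oracle_ng86 <- function(codons_a, codons_b) {
  GC <- as.character(Biostrings::GENETIC_CODE)
  names(GC) <- names(Biostrings::GENETIC_CODE)
  nts <- c("A", "C", "G", "T")
  site_syn <- function(codon) {
    aa <- GC[[codon]]
    s <- 0
    for (p in 1:3) for (n in nts) {
      if (n == substr(codon, p, p)) next
      m <- codon
      substr(m, p, p) <- n
      if (GC[[m]] == aa) s <- s + 1 / 3
    }
    s
  }
  perms_of <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  walk <- function(ca, cb, ord, allow_stop) {
    cur <- ca; s <- 0; n <- 0
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (GC[[nxt]] == "*" && !allow_stop) return(NULL)
      if (GC[[cur]] == GC[[nxt]]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s, n)
  }
  Sd <- 0; Nd <- 0; S <- 0
  for (i in seq_along(codons_a)) {
    ca <- codons_a[i]; cb <- codons_b[i]
    S <- S + (site_syn(ca) + site_syn(cb)) / 2
    dpos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    if (length(dpos)) {
      paths <- perms_of(dpos)
      valid <- Filter(Negate(is.null),
                      lapply(paths, function(o) walk(ca, cb, o, FALSE)))
      if (!length(valid)) {
        valid <- lapply(paths, function(o) walk(ca, cb, o, TRUE))
      }
      avg <- Reduce(`+`, valid) / length(valid)
      Sd <- Sd + avg[1]; Nd <- Nd + avg[2]
    }
  }
  N <- 3 * length(codons_a) - S
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(Ka = jc(Nd / N), Ks = jc(Sd / S), Sd = Sd, Nd = Nd, S = S, N = N)
}

random_codon_alignment <- function(n_codons, max_diffs = 3) {
  GC <- as.character(Biostrings::GENETIC_CODE)
  names(GC) <- names(Biostrings::GENETIC_CODE)
  sense <- names(GC)[GC != "*"]
  nts <- c("A", "C", "G", "T")
  ca <- sample(sense, n_codons, replace = TRUE)
  cb <- vapply(ca, function(c0) {
    k <- sample(0:max_diffs, 1)
    for (tries in 1:50) {
      m <- c0
      if (k > 0) {
        for (p in sample(1:3, k)) {
          substr(m, p, p) <- sample(setdiff(nts, substr(m, p, p)), 1)
        }
      }
      if (GC[[m]] != "*") return(m)
    }
    c0
  }, "")
  list(a = unname(ca), b = unname(cb))
}

# --- exhaustive collinear chain search --------------------------------------

# Best score over all subsets of anchors forming a valid chain (monotone
# increasing in both coordinates when ordered by the first, gaps bounded),
# scored as 1 per anchor minus gap_penalty per skipped rank.
oracle_best_chain_score <- function(pos_a, pos_b, max_gap, gap_penalty) {
  n <- length(pos_a)
  best <- -Inf
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    ord <- idx[order(pos_a[idx])]
    pa <- pos_a[ord]; pb <- pos_b[ord]
    ok <- TRUE
    pen <- 0
    if (length(ord) > 1) {
      da <- diff(pa); db <- diff(pb)
      ok <- all(da >= 1) && all(db >= 1) &&
        all(da - 1 <= max_gap) && all(db - 1 <= max_gap)
      if (ok) pen <- sum(pmax(da, db) - 1) * gap_penalty
    }
    if (ok) best <- max(best, length(ord) - pen)
  }
  best
}

# --- brute-force motif null distribution ------------------------------------

# Null pmf over discretized window scores by enumerating residue
# combinations on the same integer grid the DP uses. For L <= 3 the
# enumeration is direct; for larger L a meet-in-the-middle sum over the
# two halves is used (uniform background only).
oracle_motif_pmf <- function(null, background, L) {
  ip <- null$int_pwm
  if (L <= 3) {
    combos <- expand.grid(rep(list(1:20), L))
    scores <- as.integer(rowSums(mapply(function(j) ip[combos[[j]], j],
                                        seq_len(L))))
    probs <- apply(mapply(function(j) background[combos[[j]]], seq_len(L)),
                   1, prod)
    pmf <- rep(0, null$max_int + 1)
    agg <- tapply(probs, scores, sum)
    pmf[as.integer(names(agg)) + 1] <- agg
    return(pmf)
  }
  stopifnot(max(abs(background - 1 / 20)) < 1e-12)
  half <- function(cols) {
    combos <- expand.grid(rep(list(1:20), length(cols)))
    as.integer(rowSums(mapply(function(k) ip[combos[[k]], cols[k]],
                              seq_along(cols))))
  }
  s1 <- half(seq_len(L %/% 2))
  s2 <- half((L %/% 2 + 1):L)
  allsum <- as.integer(outer(s1, s2, "+"))
  counts <- tabulate(allsum + 1L, nbins = null$max_int + 1)
  counts / 20^L
}

# --- hand-written decision truth table --------------------------------------

# Expected verdict/reason for every feasible combination of
# {above, below} x {known, unknown} x cluster type x {forced, not}.
# Infeasible combinations (a below-threshold gene cannot sit in a complete
# cluster; a known singleton's only gene is the known one, which the
# threshold rule forces above) are omitted.
decision_truth_table <- function() {
  tt <- rbind(
    c("above", "known",   "singleton",    "no",  "keep",   "KNOWN_ABOVE"),
    c("above", "known",   "singleton",    "yes", "keep",   "KNOWN_ABOVE"),
    c("above", "known",   "complete",     "no",  "keep",   "KNOWN_ABOVE"),
    c("above", "known",   "complete",     "yes", "keep",   "KNOWN_ABOVE"),
    c("above", "known",   "partial_ge50", "no",  "keep",   "KNOWN_ABOVE"),
    c("above", "known",   "partial_ge50", "yes", "keep",   "KNOWN_ABOVE"),
    c("above", "known",   "partial_lt50", "no",  "keep",   "KNOWN_ABOVE"),
    c("above", "known",   "partial_lt50", "yes", "keep",   "KNOWN_ABOVE"),
    c("above", "unknown", "singleton",    "no",  "keep",   "SINGLETON_ABOVE"),
    c("above", "unknown", "singleton",    "yes", "keep",   "SINGLETON_ABOVE"),
    c("above", "unknown", "complete",     "no",  "keep",   "PARTIAL_GE50"),
    c("above", "unknown", "complete",     "yes", "keep",   "PARTIAL_GE50"),
    c("above", "unknown", "partial_ge50", "no",  "keep",   "PARTIAL_GE50"),
    c("above", "unknown", "partial_ge50", "yes", "keep",   "PARTIAL_GE50"),
    c("above", "unknown", "partial_lt50", "no",  "reject", "PARTIAL_LT50"),
    c("above", "unknown", "partial_lt50", "yes", "keep",   "FORCED"),
    c("below", "known",   "partial_ge50", "no",  "reject", "BELOW_THRESHOLD"),
    c("below", "known",   "partial_ge50", "yes", "keep",   "FORCED"),
    c("below", "known",   "partial_lt50", "no",  "reject", "BELOW_THRESHOLD"),
    c("below", "known",   "partial_lt50", "yes", "keep",   "FORCED"),
    c("below", "unknown", "singleton",    "no",  "reject", "BELOW_THRESHOLD"),
    c("below", "unknown", "singleton",    "yes", "keep",   "FORCED"),
    c("below", "unknown", "partial_ge50", "no",  "reject", "BELOW_THRESHOLD"),
    c("below", "unknown", "partial_ge50", "yes", "keep",   "FORCED"),
    c("below", "unknown", "partial_lt50", "no",  "reject", "BELOW_THRESHOLD"),
    c("below", "unknown", "partial_lt50", "yes", "keep",   "FORCED"))
  as.data.frame(stats::setNames(as.data.frame(tt, stringsAsFactors = FALSE),
                                c("hit", "cluster", "type", "forced",
                                  "verdict", "reason")))
}

# Build a minimal classification scenario realizing one truth-table row and
# return the decision emitted for the gene under test ("GENE1").
run_decision_scenario <- function(hit, cluster, type, forced,
                                  completion_threshold = 0.5) {
  above <- hit == "above"
  known <- cluster == "known"
  # threshold anchor: REF1 at 1e-50
  hit_rows <- list(data.frame(target_id = "REF1.1", evalue = 1e-50))
  add_hit <- function(id, ev) {
    hit_rows[[length(hit_rows) + 1]] <<- data.frame(target_id = id, evalue = ev)
  }
  add_hit("GENE1.1", if (above) 1e-60 else 1e-40)
  # cluster composition around GENE1 (A* above-threshold fillers, B* below)
  members <- switch(type,
    singleton = "GENE1",
    complete = c("GENE1", "AUX1", "AUX2"),
    partial_ge50 = if (above) c("GENE1", "AUX1", "BUX1", "BUX2")
                   else c("AUX1", "GENE1"),
    partial_lt50 = if (above) c("GENE1", "BUX1", "BUX2")
                   else c("AUX1", "GENE1", "BUX1"))
  if (known && type != "singleton") members <- c("REF1", members)
  if (known && type == "partial_lt50") {
    # REF1 counts as above; pad with below-threshold genes to keep ratio < 0.5
    members <- c(members, if (above) c("BUX3", "BUX4", "BUX5") else "BUX2")
  }
  for (m in grep("^AUX", members, value = TRUE)) add_hit(paste0(m, ".1"), 1e-70)
  for (m in grep("^BUX", members, value = TRUE)) add_hit(paste0(m, ".1"), 1e-30)
  hits <- do.call(rbind, hit_rows)
  hits <- hits[order(hits$evalue), ]
  hits$subfamily <- "FAM"
  hits$bitscore <- -log10(hits$evalue)
  hits$rank <- seq_len(nrow(hits))
  groups <- data.frame(group_id = "OG1", species = "Sp",
                       gene_id = members, transcript_id = paste0(members, ".1"),
                       stringsAsFactors = FALSE)
  if (!"REF1" %in% members) {
    groups <- rbind(groups, data.frame(group_id = "OGR", species = "Sp",
                                       gene_id = "REF1",
                                       transcript_id = "REF1.1"))
  }
  # a known singleton is realized by the gene itself being a reference
  ref_ids <- c("REF1.1", if (known && type == "singleton") "GENE1.1")
  refs <- reference_set(list(FAM = ref_ids),
                        force_include = if (forced == "yes") "GENE1"
                                        else character(0))
  dec <- decide(groups, list(FAM = hits), refs,
                completion_threshold = completion_threshold)
  dec[dec$gene_id == "GENE1", ]
}
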
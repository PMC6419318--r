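# Diagnostic-motif verification by PWM scanning with exact p-values.
#
# Degenerate consensus patterns (e.g. "G(T/S)Px(F/Y/W)MAPEV") are compiled
# to log-odds position weight matrices. The null distribution of window
# scores under i.i.d. background residues is computed *exactly* on a
# discretized score grid by convolving per-column score distributions, so
# reported p-values are exact tail probabilities (up to discretization),
# the same construction FIMO uses. The p-value of the best window per
# protein decides motif conservation, at a primary threshold of 1e-4 and a
# relaxed re-scan threshold of 1e-3.

#' Compile a degenerate consensus pattern to a PWM motif model
#'
#' Pattern syntax: a single residue letter matches that residue; a
#' parenthesized alternation \code{(L/V/M)} matches any listed residue;
#' \code{x} is a wildcard. Per column, the allowed residues share
#' probability mass \code{1 - 20 * pseudocount} uniformly, and every
#' residue additionally receives \code{pseudocount}; a wildcard column
#' equals the background exactly (log-odds 0). The PWM holds
#' \code{log2(p / background)}; minus-infinity entries (pseudocount 0) are
#' capped at \code{-cap} bits so scores stay finite for the discretized
#' dynamic program.
#'
#' @param pattern Consensus pattern string.
#' @param name Motif name.
#' @param background Length-20 vector of residue background frequencies
#'   (named by residue, summing to 1); default uniform.
#' @param pseudocount Probability added to every residue per column.
#' @param cap Magnitude (bits) at which infinite log-odds are capped.
#' @return An object of class \code{motif_model}: list with \code{name},
#'   \code{pattern}, \code{length}, \code{pwm} (20 x L log-odds matrix),
#'   \code{probs}, \code{background}, \code{consensus} (one maximal-scoring
#'   instantiation).
#' @export
compile_motif <- function(pattern, name = pattern,
                          background = NULL, pseudocount = 0, cap = 30) {
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  background <- background[AA_ALPHABET]
  if (anyNA(background) || any(background <= 0))
    stop_validation("background must be strictly positive over the 20 residues")
  background <- background / sum(background)
  cols <- parse_motif_pattern(pattern)
  L <- length(cols)
  probs <- matrix(0, nrow = 20, ncol = L, dimnames = list(AA_ALPHABET, NULL))
  for (j in seq_len(L)) {
    allowed <- cols[[j]]
    if (identical(allowed, "x")) {
      probs[, j] <- background
    } else {
      p <- rep(pseudocount, 20)
      names(p) <- AA_ALPHABET
      p[allowed] <- p[allowed] + (1 - 20 * pseudocount) / length(allowed)
      probs[, j] <- p
    }
  }
  pwm <- log2(sweep(probs, 1, background, "/"))
  # wildcard columns are exactly background: force clean zeros
  wild <- vapply(cols, function(a) identical(a, "x"), TRUE)
  pwm[, wild] <- 0
  pwm[pwm < -cap] <- -cap
  consensus <- paste(vapply(seq_len(L), function(j)
    AA_ALPHABET[which.max(pwm[, j])], ""), collapse = "")
  structure(list(name = name, pattern = pattern, length = L, pwm = pwm,
                 probs = probs, background = background, consensus = consensus),
            class = "motif_model")
}

#' @keywords internal
parse_motif_pattern <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  cols <- list(); i <- 1
  while (i <= length(chars)) {
    c0 <- chars[i]
    if (c0 == "(") {
      j <- which(chars == ")" & seq_along(chars) > i)[1]
      if (is.na(j)) stop_validation("unclosed alternation in pattern '", pattern, "'")
      inner <- paste(chars[(i + 1):(j - 1)], collapse = "")
      alts <- toupper(strsplit(inner, "/", fixed = TRUE)[[1]])
      alts <- alts[nzchar(alts)]
      if (length(alts) == 0) stop_validation("empty alternation in pattern '", pattern, "'")
      if (!all(alts %in% AA_ALPHABET))
        stop_validation("invalid residue in alternation '", inner, "'")
      cols[[length(cols) + 1]] <- alts
      i <- j + 1
    } else if (c0 %in% c("x", "X")) {
      cols[[length(cols) + 1]] <- "x"
      i <- i + 1
    } else if (toupper(c0) %in% AA_ALPHABET) {
      cols[[length(cols) + 1]] <- toupper(c0)
      i <- i + 1
    } else {
      stop_validation("invalid character '", c0, "' in pattern '", pattern, "'")
    }
  }
  if (length(cols) == 0) stop_validation("empty motif pattern")
  cols
}

#' Exact null distribution of discretized PWM scores
#'
#' Discretizes each PWM column onto a common integer grid (one bin width
#' for the whole matrix, chosen so the widest column spans
#' \code{granularity} bins) and convolves the per-column score
#' distributions under the background, yielding for every achievable
#' integer score s the exact probability P(score >= s) for an i.i.d.
#' background window. p-values are read at the conservative (upper) side
#' of each bin.
#'
#' @param model A [compile_motif()] model.
#' @param granularity Bins spanning the widest column's score range
#'   (default 1000).
#' @return An object of class \code{motif_null}: list with \code{delta}
#'   (bin width, bits), \code{offset} (real score of integer 0),
#'   \code{int_pwm} (integer 20 x L matrix), \code{pmf} and \code{tail}
#'   (vectors over integer scores 0..max), and \code{max_int}.
#' @export
exact_score_pvalues <- function(model, granularity = 1000) {
  if (granularity < 100) stop_validation("granularity must be >= 100")
  pwm <- model$pwm
  L <- ncol(pwm)
  col_min <- apply(pwm, 2, min)
  col_range <- apply(pwm, 2, max) - col_min
  delta <- max(col_range) / granularity
  if (delta == 0) delta <- 1  # degenerate all-wildcard motif: all scores 0
  int_pwm <- round(sweep(pwm, 2, col_min, "-") / delta)
  storage.mode(int_pwm) <- "integer"
  max_int <- sum(apply(int_pwm, 2, max))
  pmf <- c(1, rep(0, max_int))
  bg <- model$background
  for (j in seq_len(L)) {
    col_pmf <- tapply(bg, int_pwm[, j], sum)
    new <- rep(0, max_int + 1)
    ints <- as.integer(names(col_pmf))
    for (k in seq_along(ints)) {
      s <- ints[k]
      new[(s + 1):(max_int + 1)] <- new[(s + 1):(max_int + 1)] +
        col_pmf[[k]] * pmf[1:(max_int + 1 - s)]
    }
    pmf <- new
  }
  tail <- rev(cumsum(rev(pmf)))
  structure(list(delta = delta, offset = sum(col_min), int_pwm = int_pwm,
                 pmf = pmf, tail = tail, max_int = max_int),
            class = "motif_null")
}

#' @keywords internal
window_int_score <- function(null, residues) {
  # residues outside the 20-letter alphabet (X) take the column minimum
  idx <- match(residues, AA_ALPHABET)
  s <- 0L
  for (j in seq_along(residues)) {
    s <- s + if (is.na(idx[j])) 0L else null$int_pwm[idx[j], j]
  }
  s
}

#' Scan one protein for the best motif window
#'
#' Slides the motif over all \code{len - L + 1} windows, scores each
#' against the PWM, and returns the window with the smallest exact p-value
#' provided it beats the threshold (strict inequality). Proteins shorter
#' than the motif yield no hit.
#'
#' @param model A [compile_motif()] model.
#' @param sequence Protein sequence string (or a single row of
#'   [read_fasta()] output).
#' @param pvalue_threshold Report the best window only if its p-value is
#'   strictly below this (default 1e-4); use 1 to always obtain the best
#'   window.
#' @param null Precomputed [exact_score_pvalues()] result (computed on the
#'   fly when \code{NULL}; precompute when scanning many proteins).
#' @param protein_id Identifier carried into the hit.
#' @return A one-row \code{data.frame} (\code{protein_id}, \code{offset},
#'   \code{window}, \code{score}, \code{pvalue}) or a zero-row frame if no
#'   window passes.
#' @export
scan_protein <- function(model, sequence, pvalue_threshold = 1e-4,
                         null = NULL, protein_id = NA_character_) {
  if (is.data.frame(sequence)) {
    protein_id <- sequence$id[1]
    sequence <- sequence$sequence[1]
  }
  if (is.null(null)) null <- exact_score_pvalues(model)
  L <- model$length
  empty <- data.frame(protein_id = character(0), offset = integer(0),
                      window = character(0), score = numeric(0),
                      pvalue = numeric(0), stringsAsFactors = FALSE)
  n <- nchar(sequence)
  if (n < L) return(empty)
  chars <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(chars, AA_ALPHABET)
  # column scores per position: int_pwm[residue, col]; X -> column minimum (0)
  n_win <- n - L + 1
  scores <- integer(n_win)
  for (j in seq_len(L)) {
    col <- null$int_pwm[, j]
    r <- idx[j:(j + n_win - 1)]
    contrib <- ifelse(is.na(r), 0L, col[r])
    scores <- scores + contrib
  }
  best <- which.max(scores)
  p <- null$tail[scores[best] + 1]
  if (p >= pvalue_threshold) return(empty)
  win <- substr(sequence, best, best + L - 1)
  real_score <- sum(vapply(seq_len(L), function(j) {
    r <- match(substr(win, j, j), AA_ALPHABET)
    if (is.na(r)) min(model$pwm[, j]) else model$pwm[r, j]
  }, 0))
  data.frame(protein_id = protein_id, offset = best, window = win,
             score = real_score, pvalue = unname(p), stringsAsFactors = FALSE)
}

#' Motif conservation report over kept genes
#'
#' For each protein, scans the motif model of its assigned subfamily and
#' reports the best p-value plus conservation flags at the primary and
#' relaxed thresholds ("unique hits in individual proteins" = best hit per
#' protein).
#'
#' @param proteins Data frame from [read_fasta()].
#' @param subfamily_of Named character vector: protein id -> subfamily.
#' @param models Named list: subfamily -> [compile_motif()] model.
#' @param thresholds Numeric vector of two thresholds, primary then
#'   relaxed (default \code{c(1e-4, 1e-3)}).
#' @return A \code{data.frame} with one row per protein with a configured
#'   model: \code{protein_id}, \code{subfamily}, \code{best_pvalue},
#'   \code{conserved_primary}, \code{conserved_relaxed}. A per-subfamily
#'   summary is attached as attribute \code{"summary"}.
#' @export
motif_conservation_report <- function(proteins, subfamily_of, models,
                                      thresholds = c(1e-4, 1e-3)) {
  nulls <- lapply(models, exact_score_pvalues)
  rows <- list()
  for (i in seq_len(nrow(proteins))) {
    pid <- proteins$id[i]
    sf <- unname(subfamily_of[pid])
    if (is.na(sf) || is.null(models[[sf]])) next
    hit <- scan_protein(models[[sf]], proteins$sequence[i],
                        pvalue_threshold = 1, null = nulls[[sf]],
                        protein_id = pid)
    bp <- if (nrow(hit)) hit$pvalue else 1
    rows[[length(rows) + 1]] <- data.frame(
      protein_id = pid, subfamily = sf, best_pvalue = bp,
      conserved_primary = bp < thresholds[1],
      conserved_relaxed = bp < thresholds[2], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows) %||%
    data.frame(protein_id = character(0), subfamily = character(0),
               best_pvalue = numeric(0), conserved_primary = logical(0),
               conserved_relaxed = logical(0))
  if (nrow(out)) {
    summ <- aggregate(cbind(conserved_primary, conserved_relaxed) ~ subfamily,
                      data = out, FUN = sum)
    summ$n <- as.vector(table(out$subfamily)[summ$subfamily])
    attr(out, "summary") <- summ
  }
  out
}
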
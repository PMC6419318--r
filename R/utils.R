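# Shared helpers: condition classes, id handling, seeded streams.

#' @keywords internal
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("genefamkit_validation_error", "error")))
}

#' @keywords internal
stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("genefamkit_data_error", "error")))
}

#' Strip a trailing transcript-variant suffix from an identifier
#'
#' Phytozome-style transcript ids carry a trailing \code{.N} variant number
#' (\code{AT5G07140.1} is a transcript of gene \code{AT5G07140}). Decision
#' making operates on genes, so variant suffixes are stripped before counting
#' cluster members or comparing identifiers.
#'
#' @param id Character vector of gene or transcript identifiers.
#' @return Character vector with any trailing \code{.N} removed.
#' @examples
#' gene_of("AT5G07140.1")
#' @export
gene_of <- function(id) {
  sub("\\.[0-9]+$", "", id)
}

# Deterministic per-output-file seed derived from a master seed, so that
# adding a new fixture type never perturbs the random stream of an existing
# one. Kept below 2^31 - 1.
#' @keywords internal
derive_seed <- function(master, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483629L)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Amino-acid alphabet used throughout (20 canonical residues; X allowed in
# proteomes but never in motif models).
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
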
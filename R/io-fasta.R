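# Protein FASTA reading with strict residue validation.
#
# Proteome files feed both the classifier (id universe) and the motif
# scanner, so illegal residues must be caught at the boundary with a line
# number rather than surfacing later as a matrix lookup failure. Biostrings
# is used for sequence containers elsewhere; the reader here is line-based
# so parse errors can name their line.

#' Read a protein FASTA file
#'
#' Parses a FASTA file into one record per entry. The identifier is the
#' header token before the first whitespace; the remainder of the header is
#' kept as a description. Sequences are validated against the 20-letter
#' amino-acid alphabet plus \code{X} (unknown residue); any other character
#' is a parse error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @param species Optional species tag attached to every record.
#' @return A \code{data.frame} with columns \code{id}, \code{species},
#'   \code{sequence}, \code{is_longest_variant} and \code{description}, one
#'   row per entry, in file order.
#' @export
read_fasta <- function(path, species = NA_character_) {
  if (!file.exists(path)) stop_data("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  allowed <- paste0("^[", paste(AA_ALPHABET, collapse = ""), "X]*$")
  ids <- character(0); desc <- character(0); seqs <- character(0)
  cur <- NULL; buf <- character(0)
  flush <- function() {
    if (!is.null(cur)) {
      s <- paste(buf, collapse = "")
      if (!nzchar(s)) stop_data("empty sequence for record '", cur[1], "'")
      ids <<- c(ids, cur[1]); desc <<- c(desc, cur[2]); seqs <<- c(seqs, s)
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, ">")) {
      flush()
      hdr <- trimws(substring(ln, 2))
      if (!nzchar(hdr)) stop_data("malformed FASTA header at line ", i)
      tok <- strsplit(hdr, "\\s+")[[1]]
      cur <- c(tok[1], if (length(tok) > 1) paste(tok[-1], collapse = " ") else "")
      buf <- character(0)
    } else {
      if (is.null(cur)) stop_data("sequence data before any header at line ", i)
      s <- toupper(trimws(ln))
      if (!grepl(allowed, s)) {
        bad <- regmatches(s, regexpr(paste0("[^", paste(AA_ALPHABET, collapse = ""), "X]"), s))
        stop_data("illegal residue '", bad, "' at line ", i)
      }
      buf <- c(buf, s)
    }
  }
  flush()
  if (anyDuplicated(ids)) {
    stop_data("duplicate sequence id: ", ids[duplicated(ids)][1])
  }
  data.frame(id = ids, species = rep(species, length(ids)),
             sequence = seqs, is_longest_variant = rep(TRUE, length(ids)),
             description = desc, stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records Data frame with columns \code{id} and \code{sequence}
#'   (as returned by [read_fasta()]).
#' @param path Output path.
#' @param width Line wrap width for sequences.
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
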
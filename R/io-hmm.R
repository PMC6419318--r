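# HMMER3 per-target tabular output ("tblout"). Whitespace-delimited, comment
# lines start with '#'; the columns consumed are target name (1), full-
# sequence E-value (5) and full-sequence bit score (6). hmmsearch emits rows
# sorted by E-value, and the threshold rule reads output *position*, so rank
# is assigned by file order and an out-of-order E-value only warns.

#' Read a HMMER3 per-target table (tblout)
#'
#' @param path Path to a tblout file.
#' @param subfamily Label attached to every hit (the subfamily whose profile
#'   HMM produced this search output, e.g. \code{"RAF"}).
#' @return A \code{data.frame} with columns \code{target_id},
#'   \code{subfamily}, \code{evalue}, \code{bitscore}, \code{rank} (1-based
#'   file order).
#' @export
read_hmm_tblout <- function(path, subfamily) {
  if (!file.exists(path)) stop_data("tblout file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) {
    return(data.frame(target_id = character(0), subfamily = character(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(fields) < 6)) {
    stop_data("tblout row with fewer than 6 columns at data line ",
              which(lengths(fields) < 6)[1])
  }
  target <- vapply(fields, `[`, "", 1)
  ev <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5)))
  sc <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 6)))
  if (anyNA(ev)) stop_data("non-numeric E-value at data line ", which(is.na(ev))[1])
  if (anyNA(sc)) stop_data("non-numeric bit score at data line ", which(is.na(sc))[1])
  if (any(ev <= 0)) stop_data("non-positive E-value at data line ", which(ev <= 0)[1])
  if (is.unsorted(ev)) {
    warning("E-values in '", basename(path),
            "' are not sorted; ranks follow file order", call. = FALSE)
  }
  data.frame(target_id = target, subfamily = subfamily, evalue = ev,
             bitscore = sc, rank = seq_along(target), stringsAsFactors = FALSE)
}

#' Write hits as a HMMER3-style per-target table
#'
#' Emits the 18 standard tblout columns (unused ones filled with
#' placeholders) so that the output round-trips through
#' [read_hmm_tblout()] and resembles real search output.
#'
#' @param hits Data frame with \code{target_id}, \code{evalue},
#'   \code{bitscore} (file order defines rank).
#' @param path Output path.
#' @param query Query model name written into column 3.
#' @return The path, invisibly.
#' @export
write_hmm_tblout <- function(hits, path, query = "model") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#                                 --- full sequence ---",
               "# target name  accession  query name  accession  E-value  score  bias"), con)
  for (i in seq_len(nrow(hits))) {
    writeLines(sprintf("%-20s - %-10s - %12.4g %8.1f 0.0 %12.4g %8.1f 0.0 1 1 0 0 1 1 1 -",
                       hits$target_id[i], query, hits$evalue[i], hits$bitscore[i],
                       hits$evalue[i], hits$bitscore[i]), con)
  }
  invisible(path)
}
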
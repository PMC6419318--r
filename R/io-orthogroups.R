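# OrthoMCL "groups" text dialect: one cluster per line,
#   GROUPID: species|memberid species|memberid ...
# Member ids may carry a ".N" transcript-variant suffix; the gene id is the
# id with the suffix stripped. No parser for this dialect ships with R, so
# it is implemented here.

#' Read an OrthoMCL groups file
#'
#' Each line holds one orthogroup: a group id terminated by \code{":"},
#' followed by whitespace-separated \code{species|member} tokens. Member
#' tokens may carry a transcript-variant suffix (\code{.N}); the gene id is
#' derived by stripping it. Singleton clusters (one member) are permitted.
#'
#' @param path Path to a groups file.
#' @return A long-format \code{data.frame} with one row per member and
#'   columns \code{group_id}, \code{species}, \code{gene_id},
#'   \code{transcript_id}.
#' @export
read_orthogroups <- function(path) {
  if (!file.exists(path)) stop_data("groups file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  seen <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    m <- regmatches(ln, regexec("^(\\S+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop_data("malformed groups line ", i, ": '", ln, "'")
    gid <- m[2]
    if (gid %in% seen) stop_data("duplicate group id '", gid, "' at line ", i)
    seen <- c(seen, gid)
    toks <- strsplit(trimws(m[3]), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0) stop_data("group '", gid, "' has no members (line ", i, ")")
    parts <- strsplit(toks, "|", fixed = TRUE)
    if (any(lengths(parts) != 2)) {
      stop_data("member token without species tag in group '", gid, "' (line ", i, ")")
    }
    sp <- vapply(parts, `[`, "", 1)
    tid <- vapply(parts, `[`, "", 2)
    if (anyDuplicated(paste(sp, tid))) {
      stop_data("duplicate member in group '", gid, "' (line ", i, ")")
    }
    out[[i]] <- data.frame(group_id = gid, species = sp,
                           gene_id = gene_of(tid), transcript_id = tid,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write orthogroups to the OrthoMCL groups dialect
#'
#' @param groups Long-format data frame as returned by [read_orthogroups()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_orthogroups <- function(groups, path) {
  gids <- unique(groups$group_id)
  lines <- vapply(gids, function(g) {
    rows <- groups[groups$group_id == g, , drop = FALSE]
    paste0(g, ": ", paste(paste0(rows$species, "|", rows$transcript_id), collapse = " "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
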
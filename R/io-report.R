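# Classification report writer. Deterministic ordering (subfamily, then
# gene id) so identical inputs always produce byte-identical reports.

#' Write a classification report
#'
#' @param decisions Data frame of decisions as returned by [decide()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_classification_report <- function(decisions, path) {
  cols <- c("gene_id", "subfamily", "cluster_id", "cluster_type",
            "completion_ratio", "evalue", "verdict", "reason_code", "ambiguous")
  missing <- setdiff(cols, names(decisions))
  if (length(missing)) stop_validation("decisions lack columns: ",
                                       paste(missing, collapse = ", "))
  out <- decisions[order(decisions$subfamily, decisions$gene_id), cols]
  out$evalue <- ifelse(is.na(out$evalue), "NA", sprintf("%.6g", out$evalue))
  out$completion_ratio <- ifelse(is.na(out$completion_ratio), "NA",
                                 sprintf("%.4f", out$completion_ratio))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
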
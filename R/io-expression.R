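# FPKM expression tables: TSV, first column gene ids, remaining columns one
# per condition, one of which is the designated control.

#' Read an FPKM expression table
#'
#' @param path Path to a TSV with a header row of condition names and gene
#'   ids in the first column.
#' @param control_name Name of the control condition column.
#' @return An object of class \code{expression_table}: a list with
#'   \code{genes}, \code{conditions}, \code{control} and the numeric
#'   \code{fpkm} matrix (genes x conditions).
#' @export
read_expression_tsv <- function(path, control_name) {
  if (!file.exists(path)) stop_data("expression table not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_data("expression table needs gene ids plus >= 1 condition")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    stop_data("duplicate gene id in expression table: ", genes[duplicated(genes)][1])
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop_data("non-numeric FPKM value in expression table")
  if (any(mat < 0)) stop_data("negative FPKM value in expression table")
  rownames(mat) <- genes
  if (!control_name %in% colnames(mat)) {
    stop_data("control condition '", control_name, "' not present in table")
  }
  expression_table(genes, colnames(mat), control_name, mat)
}

#' Construct an expression table object
#'
#' @param genes Character vector of gene ids.
#' @param conditions Character vector of condition names.
#' @param control Which condition is the control.
#' @param fpkm Non-negative numeric matrix, genes x conditions.
#' @return An \code{expression_table} object.
#' @export
expression_table <- function(genes, conditions, control, fpkm) {
  stopifnot(is.matrix(fpkm), nrow(fpkm) == length(genes),
            ncol(fpkm) == length(conditions))
  if (!control %in% conditions) stop_validation("control condition missing")
  if (any(fpkm < 0)) stop_validation("FPKM values must be non-negative")
  if (anyDuplicated(genes)) stop_validation("duplicate gene ids")
  dimnames(fpkm) <- list(genes, conditions)
  structure(list(genes = genes, conditions = conditions,
                 control = control, fpkm = fpkm),
            class = "expression_table")
}

#' Write an expression table as TSV
#'
#' @param table An \code{expression_table}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression_tsv <- function(table, path) {
  df <- data.frame(gene_id = table$genes, table$fpkm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.expression_table <- function(x, ...) {
  cat("expression_table:", length(x$genes), "genes x", length(x$conditions),
      "conditions (control:", x$control, ")\n")
  invisible(x)
}
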
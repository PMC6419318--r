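# Stress-response expression labeling.
#
# Fold change is computed on the shifted scale: log2FC = log2(FPKM_treat+1)
# - log2(FPKM_ctrl+1) (the +1 offset absorbs zeros), with upregulation
# positive by default. Labels, with strict inequalities at the boundaries:
#   significant: fold change > 1.5 or < 0.5   (>= 50% change)
#   moderate:    fold change > 1.2 or < 0.8   (>= 20% change), not significant
#   unchanged:   otherwise

#' Fold changes and differential-expression labels
#'
#' One call per gene and non-control condition. \code{direction}
#' "treatment_vs_control" (default) makes upregulation positive;
#' "control_vs_treatment" negates every log2 fold change.
#'
#' @param table An [expression_table()].
#' @param direction Fold-change orientation (see above).
#' @param significant_bounds Length-2 vector: lower/upper fold-change
#'   bounds for "significant" (default \code{c(0.5, 1.5)}, strict).
#' @param moderate_bounds Length-2 vector for "moderate" (default
#'   \code{c(0.8, 1.2)}, strict).
#' @return Data frame: \code{gene_id}, \code{condition}, \code{log2fc},
#'   \code{fold_change}, \code{label} in \{significant_up,
#'   significant_down, moderate_up, moderate_down, unchanged\}.
#' @export
fold_changes <- function(table,
                         direction = c("treatment_vs_control",
                                       "control_vs_treatment"),
                         significant_bounds = c(0.5, 1.5),
                         moderate_bounds = c(0.8, 1.2)) {
  direction <- match.arg(direction)
  if (!inherits(table, "expression_table"))
    stop_validation("table must be an expression_table")
  treats <- setdiff(table$conditions, table$control)
  ctrl <- table$fpkm[, table$control]
  rows <- lapply(treats, function(cond) {
    l2 <- log2(table$fpkm[, cond] + 1) - log2(ctrl + 1)
    if (direction == "control_vs_treatment") l2 <- -l2
    fc <- 2^l2
    data.frame(gene_id = table$genes, condition = cond, log2fc = unname(l2),
               fold_change = unname(fc),
               label = de_label(fc, significant_bounds, moderate_bounds),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @keywords internal
de_label <- function(fc, sig = c(0.5, 1.5), mod = c(0.8, 1.2)) {
  ifelse(fc > sig[2], "significant_up",
  ifelse(fc < sig[1], "significant_down",
  ifelse(fc > mod[2], "moderate_up",
  ifelse(fc < mod[1], "moderate_down", "unchanged"))))
}

#' Per-gene ring annotations for tree viewers
#'
#' Condenses expression calls into one row per gene with one column per
#' condition ring, in a fixed condition order, marking significant
#' up/downregulation (the circle colors of typical cladogram figures:
#' red = significant up, blue = significant down, none otherwise).
#'
#' @param calls Output of [fold_changes()].
#' @param conditions_order Ring order (default cold, heat, drought, salt).
#' @return Data frame: \code{gene_id}, then \code{ring1..ringK} columns
#'   with values "red", "blue" or "none"; condition names kept in
#'   attribute \code{"conditions"}.
#' @export
annotate_tree_rings <- function(calls,
                                conditions_order = c("cold", "heat",
                                                     "drought", "salt")) {
  present <- intersect(conditions_order, unique(calls$condition))
  genes <- sort(unique(calls$gene_id))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (k in seq_along(present)) {
    sub <- calls[calls$condition == present[k], ]
    lab <- stats::setNames(sub$label, sub$gene_id)[genes]
    out[[paste0("ring", k)]] <- ifelse(lab == "significant_up", "red",
                                ifelse(lab == "significant_down", "blue",
                                       "none"))
  }
  attr(out, "conditions") <- present
  out
}
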
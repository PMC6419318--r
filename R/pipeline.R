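# Orchestration: classify -> motifscan -> dupclass -> kaks -> express,
# writing one report directory with a machine-readable run manifest.
# Stages whose inputs are absent are skipped with a logged notice.

#' Default pipeline configuration
#'
#' Input paths (NULL = stage skipped where optional) and every module
#' tunable, overridable by a YAML config file and again by arguments.
#' Unknown keys are rejected.
#'
#' @param ... Overrides of the defaults (see source / vignette for keys).
#' @param config_file Optional YAML file of overrides (lower precedence
#'   than \code{...}).
#' @return Validated configuration list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(..., config_file = NULL) {
  defaults <- list(
    groups = NULL, tblout = NULL, refs = NULL, fasta = NULL,
    gff = NULL, pairs = NULL, cds = NULL, fpkm = NULL,
    control = "CK", out_dir = "genefam_out",
    completion_threshold = 0.5, partial_keep_below = FALSE,
    motifs = c(ZIK = "GTPEFMAPE(L/V/M)(Y/F/L)",
               MEKK = "G(T/S)Px(F/Y/W)MAPEV",
               RAF = "GTxx(W/Y)MAPE"),
    pvalue_primary = 1e-4, pvalue_relaxed = 1e-3,
    min_block_size = 5, max_gap = 25, gap_penalty = 0.25,
    proximal_rank = 10, tandem_rank = 1,
    fc_direction = "treatment_vs_control",
    significant_bounds = c(0.5, 1.5), moderate_bounds = c(0.8, 1.2),
    seed = 1L, verbose = TRUE)
  overrides <- list(...)
  if (!is.null(config_file)) {
    file_cfg <- yaml::read_yaml(config_file)
    overrides <- utils::modifyList(file_cfg, overrides)
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) stop_validation("unknown config keys: ",
                                       paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  if (cfg$completion_threshold < 0 || cfg$completion_threshold > 1)
    stop_validation("completion_threshold must be in [0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' @keywords internal
pipeline_log <- function(cfg, ...) {
  if (isTRUE(cfg$verbose)) message("[genefamkit] ", ...)
}

#' Load a reference set from a YAML file
#'
#' Schema: top-level \code{members} (subfamily -> list of ids) and optional
#' \code{force_include} (list of gene ids).
#'
#' @param path YAML file path.
#' @return A [reference_set()].
#' @export
read_reference_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$members)) stop_data("reference YAML lacks a 'members' section")
  reference_set(lapply(y$members, as.character),
                force_include = as.character(y$force_include %||% character(0)))
}

#' Write a reference set to YAML
#'
#' @param refs A [reference_set()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_reference_yaml <- function(refs, path) {
  yaml::write_yaml(list(members = refs$members,
                        force_include = refs$force_include), path)
  invisible(path)
}

#' Run the full gene-family pipeline
#'
#' Stages, in order: membership classification (requires \code{groups},
#' \code{tblout}, \code{refs}), motif conservation on kept genes (requires
#' \code{fasta}), duplication/collinearity typing (requires \code{gff} and
#' \code{pairs}), Ka/Ks (requires \code{pairs} and \code{cds}), expression
#' labeling (requires \code{fpkm}). Missing optional inputs skip their
#' stage with a notice. Outputs land in \code{cfg$out_dir}:
#' \code{decisions.tsv}, \code{motifs.tsv}, \code{duplication.tsv},
#' \code{collinearity.txt}, \code{kaks.tsv}, \code{expression.tsv},
#' \code{summary.txt} and \code{manifest.json} (package version, seed,
#' parameters, per-file md5 checksums).
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list of the in-memory stage results plus
#'   \code{manifest}.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) stop_validation("cfg must be a pipeline_config")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  outputs <- character(0)

  decisions <- NULL
  if (!is.null(cfg$groups) && !is.null(cfg$tblout) && !is.null(cfg$refs)) {
    pipeline_log(cfg, "classify: reading orthogroups and hit tables")
    groups <- read_orthogroups(cfg$groups)
    refs <- if (inherits(cfg$refs, "reference_set")) cfg$refs
            else read_reference_yaml(cfg$refs)
    hits <- lapply(stats::setNames(names(cfg$tblout), names(cfg$tblout)),
                   function(sf) {
                     h <- cfg$tblout[[sf]]
                     if (is.data.frame(h)) h else read_hmm_tblout(h, sf)
                   })
    thresholds <- lapply(stats::setNames(names(hits), names(hits)), function(sf) {
      th <- determine_threshold(hits[[sf]], refs, sf)
      pipeline_log(cfg, sprintf("threshold %s: anchor %s at E-value %.3g",
                                sf, th$anchor_id, th$evalue_cutoff))
      th
    })
    decisions <- decide(groups, hits, refs,
                        completion_threshold = cfg$completion_threshold,
                        partial_keep_below = cfg$partial_keep_below,
                        thresholds = thresholds)
    p <- file.path(cfg$out_dir, "decisions.tsv")
    write_classification_report(decisions, p)
    outputs <- c(outputs, p)
    results$decisions <- decisions
    results$thresholds <- thresholds
  } else {
    pipeline_log(cfg, "classify: inputs missing, stage skipped")
  }

  if (!is.null(cfg$fasta) && !is.null(decisions)) {
    pipeline_log(cfg, "motifscan: verifying diagnostic motifs on kept genes")
    proteins <- if (is.data.frame(cfg$fasta)) cfg$fasta else read_fasta(cfg$fasta)
    kept <- decisions[decisions$verdict == "keep", ]
    sf_of_gene <- stats::setNames(kept$subfamily, kept$gene_id)
    sf_of <- stats::setNames(unname(sf_of_gene[gene_of(proteins$id)]), proteins$id)
    models <- lapply(cfg$motifs, compile_motif)
    motif_rep <- motif_conservation_report(
      proteins, sf_of, models,
      thresholds = c(cfg$pvalue_primary, cfg$pvalue_relaxed))
    p <- file.path(cfg$out_dir, "motifs.tsv")
    utils::write.table(motif_rep[order(motif_rep$subfamily, motif_rep$protein_id), ],
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, p)
    results$motifs <- motif_rep
  } else if (!is.null(cfg$fasta)) {
    pipeline_log(cfg, "motifscan: no decisions available, stage skipped")
  }

  if (!is.null(cfg$gff) && !is.null(cfg$pairs)) {
    pipeline_log(cfg, "dupclass: chaining collinear blocks")
    loci <- if (is.data.frame(cfg$gff)) cfg$gff else read_gff3_gene_loci(cfg$gff)
    pairs <- if (is.data.frame(cfg$pairs)) cfg$pairs else read_homolog_pairs(cfg$pairs)
    blocks <- chain_collinear_blocks(loci, pairs,
                                     min_block_size = cfg$min_block_size,
                                     max_gap = cfg$max_gap,
                                     gap_penalty = cfg$gap_penalty)
    dups <- classify_duplications(loci, pairs, blocks,
                                  proximal_rank = cfg$proximal_rank,
                                  tandem_rank = cfg$tandem_rank)
    p1 <- file.path(cfg$out_dir, "duplication.tsv")
    utils::write.table(dups, p1, sep = "\t", quote = FALSE, row.names = FALSE)
    p2 <- file.path(cfg$out_dir, "collinearity.txt")
    write_collinearity(blocks, p2)
    outputs <- c(outputs, p1, p2)
    results$blocks <- blocks
    results$duplications <- dups
  } else {
    pipeline_log(cfg, "dupclass: inputs missing, stage skipped")
  }

  if (!is.null(cfg$cds) && !is.null(cfg$pairs)) {
    pipeline_log(cfg, "kaks: estimating substitution rates")
    pairs <- if (is.data.frame(cfg$pairs)) cfg$pairs else read_homolog_pairs(cfg$pairs)
    cds <- if (is.character(cfg$cds) && length(cfg$cds) > 1) cfg$cds
           else read_cds_fasta(cfg$cds)
    have <- pairs$gene_a %in% names(cds) & pairs$gene_b %in% names(cds)
    kk <- kaks_table(pairs[have, , drop = FALSE], cds)
    p <- file.path(cfg$out_dir, "kaks.tsv")
    utils::write.table(kk, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, p)
    results$kaks <- kk
  } else {
    pipeline_log(cfg, "kaks: inputs missing, stage skipped")
  }

  if (!is.null(cfg$fpkm)) {
    pipeline_log(cfg, "express: labeling stress-response fold changes")
    tbl <- if (inherits(cfg$fpkm, "expression_table")) cfg$fpkm
           else read_expression_tsv(cfg$fpkm, cfg$control)
    calls <- fold_changes(tbl, direction = cfg$fc_direction,
                          significant_bounds = cfg$significant_bounds,
                          moderate_bounds = cfg$moderate_bounds)
    p <- file.path(cfg$out_dir, "expression.tsv")
    utils::write.table(calls[order(calls$gene_id, calls$condition), ], p,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, p)
    results$expression <- calls
  } else {
    pipeline_log(cfg, "express: no FPKM table supplied, stage skipped")
  }

  # summary + manifest
  summ <- c(sprintf("genefamkit pipeline summary"),
            if (!is.null(results$decisions))
              sprintf("kept genes: %d / %d candidates",
                      sum(results$decisions$verdict == "keep"),
                      nrow(results$decisions)),
            if (!is.null(results$motifs))
              sprintf("motif-conserved (primary threshold): %d / %d",
                      sum(results$motifs$conserved_primary), nrow(results$motifs)),
            if (!is.null(results$blocks))
              sprintf("collinear blocks: %d", length(results$blocks)),
            if (!is.null(results$kaks))
              sprintf("mean Ka/Ks: %.3f",
                      mean(results$kaks$ratio, na.rm = TRUE)),
            if (!is.null(results$expression))
              sprintf("significant expression calls: %d",
                      sum(grepl("^significant", results$expression$label))))
  sp <- file.path(cfg$out_dir, "summary.txt")
  writeLines(summ, sp)
  outputs <- c(outputs, sp)

  manifest <- list(
    package = "genefamkit",
    version = as.character(utils::packageVersion("genefamkit")),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), c("tblout", "refs", "fasta", "gff",
                                           "pairs", "cds", "fpkm", "groups"))],
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

#' Read aligned coding sequences (DNA FASTA)
#'
#' @param path FASTA file of nucleotide sequences.
#' @return Named character vector of sequences.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop_data("CDS FASTA not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  nm <- vapply(strsplit(names(x), "\\s+"), `[`, "", 1)
  stats::setNames(as.character(x), nm)
}
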
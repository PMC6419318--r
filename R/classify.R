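# Gene-family membership decisions.
#
# Two homology signals are combined: a ranked profile-HMM search per
# subfamily, and orthogroup clusters. The E-value inclusion threshold for a
# subfamily is anchored on the worst-scoring *reference* member (previously
# validated genes in the anchor species): specifically the first-occurring
# hit, in search-output order, of the reference gene whose best hit has the
# largest E-value. Candidates are then kept or rejected by a decision table
# over the cluster context:
#
#   above threshold, known cluster                       -> keep (KNOWN_ABOVE)
#   above threshold, singleton cluster                   -> keep (SINGLETON_ABOVE)
#   above threshold, unknown cluster, completion >= 50%  -> keep (PARTIAL_GE50)
#   above threshold, unknown cluster, completion <  50%  -> reject (PARTIAL_LT50)
#   below threshold                                      -> reject (BELOW_THRESHOLD)
#   forced reference gene                                -> keep (FORCED)
#
# "Known" means the cluster contains a previously identified family member;
# the completion ratio is the fraction of a cluster's member *genes* (not
# transcripts) scoring above the threshold. An unknown complete cluster has
# ratio 1 and is kept through the >= 50% representation rule.

#' Build a reference set
#'
#' A reference set names, per subfamily, the previously validated member
#' transcripts/genes in the anchor species (these define the threshold and
#' mark clusters as "known"), plus an optional list of gene ids that are
#' always kept regardless of threshold.
#'
#' @param members Named list: subfamily -> character vector of reference
#'   transcript or gene ids.
#' @param force_include Character vector of gene ids to keep
#'   unconditionally (typically all anchor-species reference genes).
#' @return An object of class \code{reference_set}.
#' @export
reference_set <- function(members, force_include = character(0)) {
  if (!is.list(members) || is.null(names(members)) || any(!nzchar(names(members))))
    stop_validation("members must be a named list (subfamily -> ids)")
  if (any(lengths(members) == 0))
    stop_validation("every configured subfamily needs >= 1 reference id")
  structure(list(members = lapply(members, as.character),
                 force_include = as.character(force_include)),
            class = "reference_set")
}

#' Determine the E-value inclusion threshold for one subfamily
#'
#' For each reference gene, the first-occurring hit (smallest rank) among
#' its transcript variants is taken as the gene's representative hit. The
#' threshold anchor is the reference gene whose representative hit has the
#' largest E-value (the "last identified" reference member in output
#' order); ties are broken by larger rank, then lexicographic target id.
#' The cutoff is that hit's E-value, and comparison downstream is
#' inclusive, so the anchor itself passes.
#'
#' @param hits Ranked hit table from [read_hmm_tblout()].
#' @param refs A [reference_set()].
#' @param subfamily Which subfamily's references to use.
#' @return A list with \code{subfamily}, \code{anchor_id} (the transcript id
#'   of the anchoring hit) and \code{evalue_cutoff}.
#' @export
determine_threshold <- function(hits, refs, subfamily) {
  if (!inherits(refs, "reference_set")) stop_validation("refs must be a reference_set")
  ref_ids <- refs$members[[subfamily]]
  if (is.null(ref_ids)) stop_validation("no references configured for subfamily '",
                                        subfamily, "'")
  ref_genes <- unique(gene_of(ref_ids))
  hit_genes <- gene_of(hits$target_id)
  present <- ref_genes[ref_genes %in% hit_genes]
  if (length(present) == 0) {
    stop_data("threshold undefined: no reference member of '", subfamily,
              "' found among hits")
  }
  # representative hit per reference gene: minimum rank among its variants
  rep_rows <- vapply(present, function(g) {
    idx <- which(hit_genes == g)
    idx[which.min(hits$rank[idx])]
  }, integer(1))
  ev <- hits$evalue[rep_rows]
  best <- which(ev == max(ev))
  if (length(best) > 1) {
    rk <- hits$rank[rep_rows[best]]
    best <- best[rk == max(rk)]
    if (length(best) > 1) {
      ids <- hits$target_id[rep_rows[best]]
      best <- best[order(ids)][1]
    }
  }
  row <- rep_rows[best]
  list(subfamily = subfamily,
       anchor_id = hits$target_id[row],
       evalue_cutoff = hits$evalue[row])
}

#' Genes above an inclusion threshold
#'
#' A gene is above threshold if any of its transcript variants has a hit
#' with E-value less than or equal to the cutoff.
#'
#' @param hits Hit table.
#' @param cutoff E-value cutoff (inclusive).
#' @return Character vector of gene ids.
#' @export
genes_above_threshold <- function(hits, cutoff) {
  unique(gene_of(hits$target_id[hits$evalue <= cutoff]))
}

#' Assess one orthogroup against a threshold
#'
#' Transcript variants are collapsed to genes before counting. The
#' completion ratio is the fraction of member genes above the threshold.
#' Cluster type: \code{singleton} (exactly one member gene),
#' \code{complete} (ratio 1, more than one gene), \code{absent} (ratio 0),
#' otherwise \code{partial}.
#'
#' @param group_members Character vector of the group's member transcript or
#'   gene ids.
#' @param hits_above Character vector of gene ids above threshold.
#' @param known_ids Character vector of previously identified member gene
#'   ids (cluster is "known" if it contains one).
#' @param group_id Group identifier carried into the result.
#' @return A one-row \code{data.frame}: \code{group_id},
#'   \code{cluster_type}, \code{is_known}, \code{completion_ratio},
#'   \code{n_genes}, \code{n_above}.
#' @export
assess_cluster <- function(group_members, hits_above, known_ids = character(0),
                           group_id = NA_character_) {
  genes <- unique(gene_of(group_members))
  if (length(genes) == 0) stop_validation("empty orthogroup")
  above <- intersect(genes, unique(gene_of(hits_above)))
  ratio <- length(above) / length(genes)
  type <- if (length(genes) == 1) "singleton"
          else if (ratio == 1) "complete"
          else if (ratio == 0) "absent"
          else "partial"
  data.frame(group_id = group_id, cluster_type = type,
             is_known = length(intersect(genes, unique(gene_of(known_ids)))) > 0,
             completion_ratio = ratio, n_genes = length(genes),
             n_above = length(above), stringsAsFactors = FALSE)
}

#' Apply the membership decision table
#'
#' For each candidate gene of each subfamily (genes with at least one hit,
#' plus forced reference genes, plus any explicitly supplied candidates),
#' emits one keep/reject decision with a machine-readable reason code. A
#' gene with hits in more than one subfamily receives a decision in each,
#' flagged \code{ambiguous}; nothing is silently dropped.
#'
#' @param groups Long-format orthogroup table from [read_orthogroups()], or
#'   \code{NULL} if no clustering is available (all candidates are then
#'   treated as singleton clusters, mirroring OrthoMCL's treatment of
#'   unclustered sequences).
#' @param hits_by_subfamily Named list: subfamily -> hit table.
#' @param refs A [reference_set()].
#' @param completion_threshold Minimum completion ratio for keeping
#'   above-threshold genes in partial/unknown clusters (default 0.5).
#' @param partial_keep_below If \code{TRUE}, below-threshold member genes of
#'   clusters meeting the completion threshold are kept too (default
#'   \code{FALSE}, which keeps the decision sound: every kept gene outside
#'   the forced list is above threshold).
#' @param thresholds Optional named list of precomputed thresholds
#'   (subfamily -> result of [determine_threshold()]); computed when
#'   \code{NULL}.
#' @param candidates Optional named list: subfamily -> extra candidate gene
#'   ids to emit decisions for even without hits (reason \code{NO_HIT}).
#' @return A \code{data.frame} with one row per (gene, subfamily):
#'   \code{gene_id}, \code{subfamily}, \code{verdict} (keep/reject),
#'   \code{reason_code}, \code{cluster_id}, \code{cluster_type},
#'   \code{completion_ratio}, \code{evalue} (best variant E-value or NA),
#'   \code{ambiguous}.
#' @export
decide <- function(groups, hits_by_subfamily, refs,
                   completion_threshold = 0.5, partial_keep_below = FALSE,
                   thresholds = NULL, candidates = NULL) {
  if (!inherits(refs, "reference_set")) stop_validation("refs must be a reference_set")
  subfams <- names(hits_by_subfamily)
  if (is.null(subfams)) stop_validation("hits_by_subfamily must be named by subfamily")
  force_genes <- unique(gene_of(refs$force_include))

  # cluster lookup: gene -> group id (first match); member genes per group
  if (!is.null(groups) && nrow(groups) > 0) {
    gene2group <- tapply(groups$group_id, groups$gene_id, function(x) x[1])
    group_members <- split(groups$gene_id, groups$group_id)
  } else {
    gene2group <- character(0)
    group_members <- list()
  }

  all_rows <- list()
  for (sf in subfams) {
    hits <- hits_by_subfamily[[sf]]
    thr <- if (!is.null(thresholds) && !is.null(thresholds[[sf]])) thresholds[[sf]]
           else determine_threshold(hits, refs, sf)
    above <- genes_above_threshold(hits, thr$evalue_cutoff)
    known <- unique(gene_of(refs$members[[sf]] %||% character(0)))
    hit_genes <- gene_of(hits$target_id)
    best_ev <- tapply(hits$evalue, hit_genes, min)
    cand <- unique(c(names(best_ev), intersect(force_genes, names(best_ev)),
                     force_genes[force_genes %in% known],
                     as.character(candidates[[sf]] %||% character(0))))

    # per-cluster assessment cache for this subfamily's threshold
    assess_cache <- new.env(parent = emptyenv())
    get_assessment <- function(gid) {
      if (is.null(assess_cache[[gid]])) {
        assess_cache[[gid]] <- assess_cluster(group_members[[gid]], above,
                                              known, group_id = gid)
      }
      assess_cache[[gid]]
    }

    rows <- lapply(sort(cand), function(g) {
      has_hit <- g %in% names(best_ev)
      is_above <- g %in% above
      gid <- if (g %in% names(gene2group)) unname(gene2group[[g]]) else NA_character_
      if (!is.na(gid)) {
        a <- get_assessment(gid)
        ctype <- a$cluster_type; ck <- a$is_known; cr <- a$completion_ratio
      } else {
        # unclustered sequence: OrthoMCL semantics make it its own singleton
        ctype <- "singleton"; ck <- g %in% known; cr <- as.numeric(is_above)
      }
      meets <- cr >= completion_threshold
      if (is_above && ck) {
        v <- "keep"; rc <- "KNOWN_ABOVE"
      } else if (is_above && ctype == "singleton") {
        v <- "keep"; rc <- "SINGLETON_ABOVE"
      } else if (is_above && meets) {
        v <- "keep"; rc <- "PARTIAL_GE50"
      } else if (g %in% force_genes) {
        v <- "keep"; rc <- "FORCED"
      } else if (!has_hit) {
        v <- "reject"; rc <- "NO_HIT"
      } else if (is_above) {
        v <- "reject"; rc <- "PARTIAL_LT50"
      } else if (partial_keep_below && ctype %in% c("partial", "complete") && meets) {
        v <- "keep"; rc <- "PARTIAL_GE50"
      } else {
        v <- "reject"; rc <- "BELOW_THRESHOLD"
      }
      data.frame(gene_id = g, subfamily = sf, verdict = v, reason_code = rc,
                 cluster_id = if (is.na(gid)) "unclustered" else gid,
                 cluster_type = ctype, completion_ratio = cr,
                 evalue = if (has_hit) unname(best_ev[[g]]) else NA_real_,
                 ambiguous = FALSE, stringsAsFactors = FALSE)
    })
    all_rows[[sf]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, all_rows)
  rownames(out) <- NULL
  multi <- names(which(table(unique(out[, c("gene_id", "subfamily")])$gene_id) > 1))
  out$ambiguous <- out$gene_id %in% multi
  out
}

#' Summarize kept genes per species and subfamily
#'
#' @param decisions Decision table from [decide()].
#' @param species_of Named character vector mapping gene id -> species tag.
#' @param published_ids Optional character vector of previously published
#'   member gene ids, used to split counts into published vs new.
#' @return A \code{data.frame} with per (species, subfamily) counts:
#'   \code{n_kept}, \code{n_published}, \code{n_new}.
#' @export
summarize_by_species <- function(decisions, species_of, published_ids = NULL) {
  kept <- decisions[decisions$verdict == "keep", , drop = FALSE]
  kept$species <- unname(species_of[kept$gene_id])
  kept$species[is.na(kept$species)] <- "unknown"
  pub <- unique(gene_of(published_ids %||% character(0)))
  agg <- aggregate(gene_id ~ species + subfamily, data = kept,
                   FUN = function(g) c(n = length(unique(g)),
                                       p = length(unique(intersect(g, pub)))))
  out <- data.frame(species = agg$species, subfamily = agg$subfamily,
                    n_kept = agg$gene_id[, "n"],
                    n_published = agg$gene_id[, "p"],
                    stringsAsFactors = FALSE)
  out$n_new <- out$n_kept - out$n_published
  out[order(out$species, out$subfamily), ]
}
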
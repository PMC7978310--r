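#' Fraction of DEGs targeted by at least one transcription factor
#'
#' Deduplicates (tf, target) pairs across motifs, intersects targets with
#' the DEG set, and reports the covered fraction with its counts — overall
#' and, when the DE result carries biotypes, restricted to protein-coding
#' DEGs. An empty hit table yields coverage 0 with a warning.
#'
#' @param hits motif-hit data.frame (tf, motif, target), e.g. from
#'   [read_motif_hits()].
#' @param de a `"de_result"` data.frame, or a character vector of DEG ids.
#' @param digits decimal places of the reported percent (default 0, the
#'   convention for headline coverage figures).
#' @return one-row data.frame: n_deg, n_covered, fraction, percent, n_tf,
#'   plus coding columns when biotypes are available.
#' @export
motif_coverage <- function(hits, de, digits = 0) {
  degs <- if (is.character(de)) de else deg_ids(de)
  if (length(degs) == 0) stop("empty DEG set")
  pairs <- unique(hits[, c("tf", "target")])
  covered <- intersect(unique(pairs$target), degs)
  if (nrow(pairs) == 0) warning("empty motif-hit table; coverage is 0")
  out <- data.frame(n_deg = length(degs), n_covered = length(covered),
                    fraction = length(covered) / length(degs),
                    percent = percent_of(length(covered), length(degs), digits),
                    n_tf = length(unique(pairs$tf[pairs$target %in% degs])),
                    stringsAsFactors = FALSE)
  if (!is.character(de) && "biotype" %in% names(de)) {
    coding <- de$gene_id[de$deg & de$biotype %in% "protein_coding"]
    cov_coding <- intersect(covered, coding)
    out$n_deg_coding <- length(coding)
    out$n_covered_coding <- length(cov_coding)
    out$percent_coding <- if (length(coding) > 0) {
      percent_of(length(cov_coding), length(coding), max(digits, 2))
    } else NA_real_
  }
  out
}

#' Classify transcription factors by the direction of their DEG targets
#'
#' After deduplicating (tf, target) pairs and restricting targets to the
#' DEG set, each TF is labeled `up-only` if all its targets are
#' up-regulated, `down-only` if all are down-regulated, and `both`
#' otherwise. TFs with no DEG targets are excluded with a message.
#'
#' @inheritParams motif_coverage
#' @return data.frame: tf, n_targets, n_up, n_down, class; one row per
#'   classified TF, sorted by tf id.
#' @export
classify_tf_direction <- function(hits, de) {
  direction <- stats::setNames(de$direction, de$gene_id)
  degs <- deg_ids(de)
  pairs <- unique(hits[, c("tf", "target")])
  pairs <- pairs[pairs$target %in% degs, , drop = FALSE]
  skipped <- setdiff(unique(hits$tf), unique(pairs$tf))
  if (length(skipped) > 0) {
    message(length(skipped), " TF(s) with zero DEG targets excluded: ",
            paste(sort(skipped), collapse = ", "))
  }
  if (nrow(pairs) == 0) {
    return(data.frame(tf = character(0), n_targets = integer(0),
                      n_up = integer(0), n_down = integer(0),
                      class = character(0), stringsAsFactors = FALSE))
  }
  out <- lapply(split(pairs$target, pairs$tf), function(targets) {
    dirs <- direction[targets]
    n_up <- sum(dirs == "up")
    n_down <- sum(dirs == "down")
    data.frame(n_targets = length(targets), n_up = n_up, n_down = n_down,
               class = if (n_down == 0) "up-only"
                       else if (n_up == 0) "down-only" else "both",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- data.frame(tf = names(out), res, stringsAsFactors = FALSE)
  res <- res[order(res$tf), ]
  rownames(res) <- NULL
  res
}

#' Pathway enrichment of each TF's DEG targets (Sankey table)
#'
#' Runs hypergeometric enrichment of every TF's differentially expressed
#' target set against a pathway collection and keeps (tf, pathway) links at
#' raw p at or below `p_cutoff` (the published convention for this display;
#' switch `use_adjusted` for BH-adjusted filtering). TFs with fewer DEG
#' targets than `min_targets` are skipped with a message. The output is
#' ready for Sankey rendering: source TF, target pathway, and
#' `value = -log10(p)`.
#'
#' @inheritParams motif_coverage
#' @param collection named list of pathway gene sets.
#' @param universe background gene ids.
#' @param p_cutoff raw-p threshold for keeping a link (default 0.05).
#' @param min_targets minimum DEG-target count per TF (default 5).
#' @param use_adjusted filter on BH-adjusted p instead of raw p.
#' @return data.frame: tf, pathway, k, n_targets, pvalue, padj, value.
#' @export
tf_pathway_links <- function(hits, de, collection, universe,
                             p_cutoff = 0.05, min_targets = 5,
                             use_adjusted = FALSE) {
  degs <- deg_ids(de)
  pairs <- unique(hits[, c("tf", "target")])
  pairs <- pairs[pairs$target %in% degs, , drop = FALSE]
  targets_by_tf <- split(pairs$target, pairs$tf)
  rows <- lapply(sort(names(targets_by_tf)), function(tf) {
    targets <- targets_by_tf[[tf]]
    if (length(targets) < min_targets) {
      message("TF ", tf, " skipped: ", length(targets), " DEG target(s) < ",
              min_targets)
      return(NULL)
    }
    enr <- suppressMessages(
      hypergeom_enrich(targets, collection, universe, q_cutoff = NULL))
    keep <- if (use_adjusted) enr$padj <= p_cutoff else enr$pvalue <= p_cutoff
    enr <- enr[keep, , drop = FALSE]
    if (nrow(enr) == 0) return(NULL)
    data.frame(tf = tf, pathway = enr$set, k = enr$k,
               n_targets = length(targets),
               pvalue = enr$pvalue, padj = enr$padj,
               value = -log10(enr$pvalue), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(tf = character(0), pathway = character(0), k = integer(0),
                      n_targets = integer(0), pvalue = numeric(0),
                      padj = numeric(0), value = numeric(0),
                      stringsAsFactors = FALSE)
  }
  res <- res[order(res$tf, res$pvalue, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' TF-target-pathway bipartite graph for one transcription factor
#'
#' Tri-partite graph of the TF, its DEG targets (carrying the DE direction)
#' and the pathways those targets belong to: edges TF-target for every
#' deduplicated hit, and target-pathway for every membership. Targets in no
#' pathway remain as leaves of the TF.
#'
#' @inheritParams tf_pathway_links
#' @param tf the transcription factor id (must appear in `hits`).
#' @return an igraph graph with vertex attributes `type`
#'   (`"tf"`/`"gene"`/`"pathway"`) and `direction` (genes only).
#' @export
tf_target_pathway_graph <- function(tf, hits, de, collection) {
  if (!tf %in% hits$tf) stop("unknown TF id: ", tf)
  direction <- stats::setNames(de$direction, de$gene_id)
  degs <- deg_ids(de)
  targets <- sort(intersect(unique(hits$target[hits$tf == tf]), degs))
  edges <- data.frame(from = rep(tf, length(targets)), to = targets,
                      stringsAsFactors = FALSE)
  pathways <- character(0)
  for (nm in names(collection)) {
    memb <- intersect(targets, collection[[nm]])
    if (length(memb) > 0) {
      pathways <- c(pathways, nm)
      edges <- rbind(edges, data.frame(from = memb, to = nm,
                                       stringsAsFactors = FALSE))
    }
  }
  vertices <- data.frame(
    name = c(tf, targets, pathways),
    type = rep(c("tf", "gene", "pathway"),
               c(1, length(targets), length(pathways))),
    direction = c(NA_character_, unname(direction[targets]),
                  rep(NA_character_, length(pathways))),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}
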
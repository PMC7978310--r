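#' Build a term-to-gene bipartite graph from enrichment results
#'
#' One node per enriched term and one per distinct member DEG, with an edge
#' for every membership. Gene nodes carry the regulation direction copied
#' from the DE result; rows whose genes lack a direction are rejected and
#' logged with a message.
#'
#' @param rows enrichment data.frame (from [hypergeom_enrich()]); must carry
#'   the comma-collapsed `genes` column.
#' @param de a `"de_result"` data.frame supplying per-gene directions.
#' @return an `igraph` bipartite graph with vertex attributes `type`
#'   (`"term"` / `"gene"`), `direction` (genes only) and `category`
#'   (terms only).
#' @export
build_term_gene_graph <- function(rows, de) {
  if (nrow(rows) == 0) stop("no enrichment rows to build a graph from")
  direction <- stats::setNames(de$direction, de$gene_id)
  edges <- NULL
  kept <- logical(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    genes <- strsplit(rows$genes[i], ",", fixed = TRUE)[[1]]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) next
    dirs <- direction[genes]
    if (any(is.na(dirs))) {
      message("term '", rows$set[i], "' rejected: ", sum(is.na(dirs)),
              " member gene(s) without a DE direction")
      next
    }
    kept[i] <- TRUE
    edges <- rbind(edges, data.frame(term = rows$set[i], gene = genes,
                                     stringsAsFactors = FALSE))
  }
  if (is.null(edges)) stop("no usable term rows (all rejected or empty)")
  terms <- unique(edges$term)
  genes <- unique(edges$gene)
  vertices <- data.frame(
    name = c(terms, genes),
    type = rep(c("term", "gene"), c(length(terms), length(genes))),
    direction = c(rep(NA_character_, length(terms)), unname(direction[genes])),
    category = c(rows$category[match(terms, rows$set)],
                 rep(NA_character_, length(genes))),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
  igraph::V(g)$bipartite_type <- igraph::V(g)$type == "term"
  g
}

#' Jaccard similarity between enriched terms
#'
#' `J(A, B) = |genes(A) ∩ genes(B)| / |genes(A) ∪ genes(B)|` over the terms'
#' member genes in a term-gene bipartite graph. Terms with no genes are
#' excluded with a warning.
#'
#' @param graph bipartite graph from [build_term_gene_graph()], or a named
#'   list of per-term gene-id vectors.
#' @return symmetric term x term matrix with unit diagonal, values in [0,1],
#'   rows/columns in lexicographic term order.
#' @export
jaccard_term_similarity <- function(graph) {
  memb <- term_memberships(graph)
  empty <- lengths(memb) == 0
  if (any(empty)) {
    warning("term(s) with zero genes excluded: ",
            paste(names(memb)[empty], collapse = ", "))
    memb <- memb[!empty]
  }
  if (length(memb) < 2) stop("need >= 2 non-empty terms")
  memb <- memb[order(names(memb))]
  nt <- length(memb)
  J <- matrix(1, nt, nt, dimnames = list(names(memb), names(memb)))
  for (i in seq_len(nt - 1)) {
    for (j in seq((i + 1), nt)) {
      inter <- length(intersect(memb[[i]], memb[[j]]))
      J[i, j] <- J[j, i] <- inter / length(union(memb[[i]], memb[[j]]))
    }
  }
  J
}

# internal: term -> member gene sets from a graph or a plain list
term_memberships <- function(graph) {
  if (is.list(graph) && !igraph::is_igraph(graph)) return(graph)
  term_v <- igraph::V(graph)[igraph::V(graph)$type == "term"]
  memb <- lapply(term_v, function(v) {
    nb <- igraph::neighbors(graph, v)
    nb$name
  })
  stats::setNames(memb, term_v$name)
}

#' Cluster enriched terms by shared-gene similarity
#'
#' Average-linkage hierarchical clustering on the distance `1 - J` (Jaccard
#' similarity of term gene memberships), cut to `k` flat groups. Terms are
#' ordered lexicographically before clustering so merge order, and hence
#' labels, are deterministic; a silhouette-based suggestion for `k` is
#' printed as a message but never applied automatically (group counts in
#' published analyses of this kind are chosen by eye).
#'
#' @param similarity symmetric Jaccard matrix from
#'   [jaccard_term_similarity()].
#' @param k number of flat term groups (1 <= k <= number of terms).
#' @param suggest_k print a silhouette-based suggestion (default TRUE).
#' @return list of class `"term_clustering"`: `labels` (named integer),
#'   `hclust`.
#' @export
cluster_terms <- function(similarity, k, suggest_k = TRUE) {
  nt <- nrow(similarity)
  if (k < 1 || k > nt) stop("k must be between 1 and the number of terms")
  ord <- order(rownames(similarity))
  similarity <- similarity[ord, ord]
  d <- stats::as.dist(1 - similarity)
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = k)
  if (suggest_k && nt > 3) {
    ks <- 2:min(8, nt - 1)
    sil <- vapply(ks, function(kk) {
      mean(cluster::silhouette(stats::cutree(hc, kk), d)[, "sil_width"])
    }, 0)
    message("silhouette suggests k = ", ks[which.max(sil)],
            " (mean width ", signif(max(sil), 3), "); using k = ", k)
  }
  out <- list(labels = labels, hclust = hc, k = k)
  class(out) <- "term_clustering"
  out
}

#' Export a bipartite graph for external viewers
#'
#' `write_graphml()` writes GraphML; `write_graph_tables()` writes a
#' two-column edge-list TSV plus a node-attribute sidecar TSV.
#'
#' @param graph an igraph graph.
#' @param path output path (for tables, the edge-list path; the sidecar gets
#'   a `_nodes.tsv` suffix).
#' @return the path(s), invisibly.
#' @export
write_graphml <- function(graph, path) {
  g <- graph
  # GraphML cannot hold NA attribute values; blank them
  for (a in igraph::vertex_attr_names(g)) {
    v <- igraph::vertex_attr(g, a)
    if (is.character(v)) igraph::vertex_attr(g, a) <- ifelse(is.na(v), "", v)
    if (is.logical(v)) igraph::vertex_attr(g, a) <- as.character(v)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_graph_tables <- function(graph, path) {
  el <- igraph::as_data_frame(graph, what = "edges")
  write_tsv_prov(el[, c("from", "to")], path)
  nodes <- igraph::as_data_frame(graph, what = "vertices")
  node_path <- sub("\\.tsv$", "_nodes.tsv", path)
  if (identical(node_path, path)) node_path <- paste0(path, "_nodes.tsv")
  write_tsv_prov(nodes, node_path)
  invisible(c(path, node_path))
}
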
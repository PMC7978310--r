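#' Log-scale normalized expression
#'
#' Median-of-ratios size factors (the normalization of the first DE
#' procedure) followed by `log2(count / sizefactor + 1)`. This is the
#' transformation used throughout the exploration stage for variance
#' ranking, PCA and sample-sample distances.
#'
#' @param counts gene x sample integer matrix.
#' @return numeric matrix of log2 normalized expression.
#' @export
normalize_log2 <- function(counts) {
  check_count_matrix(counts)
  sf <- tryCatch(DESeq2::estimateSizeFactorsForMatrix(counts),
                 error = function(e) colSums(counts) / mean(colSums(counts)))
  log2(sweep(counts, 2, sf, `/`) + 1)
}

#' Select the genes with the largest expression variance
#'
#' Genes are ranked by the variance of their log2 normalized expression
#' across the selected samples; ties are broken by gene id order so the
#' selection is deterministic.
#'
#' @param counts gene x sample integer matrix.
#' @param k number of genes to keep (default 500).
#' @param samples optional sample subset (e.g. PE samples only).
#' @return character vector of k gene ids, highest variance first.
#' @export
select_top_variance_genes <- function(counts, k = 500, samples = colnames(counts)) {
  if (k <= 0) stop("k must be positive")
  if (k > nrow(counts)) stop("k exceeds the number of genes")
  lm <- normalize_log2(counts[, samples, drop = FALSE])
  v <- apply(lm, 1, stats::var)
  ord <- order(-v, rownames(lm))
  rownames(lm)[ord][seq_len(k)]
}

#' PCA of samples on a gene subset
#'
#' Centered principal component analysis of the samples on the log2
#' normalized expression of the selected genes. Each component is oriented
#' so that its largest-absolute gene loading is positive, making scores and
#' loadings deterministic. `top_loading_genes()` extracts the genes that
#' contribute most to a component, ranked by absolute loading.
#'
#' @param counts gene x sample integer matrix.
#' @param genes character vector of genes to use (e.g. from
#'   [select_top_variance_genes()]).
#' @param samples optional sample subset.
#' @param n_components number of components to keep (default 10, capped by
#'   the data's rank).
#' @return list of class `"pe_pca"`: `scores` (samples x components),
#'   `loadings` (genes x components), `var_explained` (fractions in [0,1],
#'   non-increasing, summing to <= 1).
#' @export
pca_samples <- function(counts, genes, samples = colnames(counts), n_components = 10) {
  m <- normalize_log2(counts[, samples, drop = FALSE])[genes, , drop = FALSE]
  if (ncol(m) < 2) stop("need >= 2 samples for PCA")
  n_components <- min(n_components, ncol(m) - 1, nrow(m))
  if (n_components < 1) stop("fewer samples than requested components")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  idx <- seq_len(n_components)
  scores <- pc$x[, idx, drop = FALSE]
  loadings <- pc$rotation[, idx, drop = FALSE]
  # sign convention: largest-absolute loading positive per component
  for (j in idx) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  var_explained <- (pc$sdev^2 / sum(pc$sdev^2))[idx]
  out <- list(scores = scores, loadings = loadings, var_explained = var_explained)
  class(out) <- "pe_pca"
  out
}

#' @export
print.pe_pca <- function(x, ...) {
  cat("pe_pca:", nrow(x$scores), "samples,", ncol(x$scores), "components\n")
  cat("  variance explained:",
      paste(sprintf("PC%d=%.1f%%", seq_along(x$var_explained),
                    100 * x$var_explained), collapse = " "), "\n")
  invisible(x)
}

#' @rdname pca_samples
#' @param pca a `"pe_pca"` object.
#' @param component which component (default 1).
#' @param n how many genes (default 50).
#' @export
top_loading_genes <- function(pca, component = 1, n = 50) {
  l <- pca$loadings[, component]
  ord <- order(-abs(l), names(l))
  utils::head(names(l)[ord], n)
}

#' Ward hierarchical clustering of samples
#'
#' Euclidean distances between samples on log2 normalized expression of the
#' chosen genes (by default all "expressed" genes: raw count above 1 in
#' every sample), Ward linkage, and a flat cut at `k` clusters.
#'
#' @param counts gene x sample integer matrix.
#' @param genes gene subset; `NULL` (default) uses the expressed-gene filter.
#' @param samples optional sample subset.
#' @param k number of flat clusters (default 2).
#' @return list of class `"pe_clustering"`: `hclust` (the tree), `labels`
#'   (named integer cluster assignment), `dist` (sample-sample distances).
#' @export
cluster_samples <- function(counts, genes = NULL, samples = colnames(counts), k = 2) {
  m <- counts[, samples, drop = FALSE]
  if (ncol(m) < 2) stop("need >= 2 samples to cluster")
  if (k > ncol(m)) stop("k exceeds the number of samples")
  if (is.null(genes)) {
    genes <- rownames(m)[apply(m > 1, 1, all)]
    if (length(genes) < 2) genes <- rownames(m)
  }
  lm <- normalize_log2(m)[genes, , drop = FALSE]
  d <- stats::dist(t(lm), method = "euclidean")
  hc <- stats::hclust(d, method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  out <- list(hclust = hc, labels = labels, dist = d, genes = genes, k = k)
  class(out) <- "pe_clustering"
  out
}

#' @export
print.pe_clustering <- function(x, ...) {
  cat("pe_clustering:", length(x$labels), "samples,", x$k, "flat clusters on",
      length(x$genes), "genes\n")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Export a sample dendrogram in Newick format
#'
#' @param clustering a `"pe_clustering"` object.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  phy <- ape::as.phylo(clustering$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
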
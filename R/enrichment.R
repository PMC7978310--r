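#' Hypergeometric over-representation of gene sets in a query
#'
#' For each set, the upper-tail hypergeometric probability of drawing at
#' least the observed overlap: with universe size N, set size K, query size
#' n and overlap k, `p = P(X >= k)` for `X ~ Hypergeom(N, K, n)`. P-values
#' are Benjamini-Hochberg adjusted and a q-value is attached (BH by default;
#' a Storey-type smoother estimator via `q_method = "storey"`). Query genes
#' outside the universe are dropped with a message; sets are intersected
#' with the universe.
#'
#' @param query character vector of gene ids (e.g. DEGs).
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @param universe character vector of background gene ids.
#' @param q_cutoff keep rows with q-value at or below this (default 0.2, the
#'   pathway screening cutoff; use 0.05 for GO-style screens, `NULL` for no
#'   filtering).
#' @param padj_cutoff optional additional adjusted-p cutoff (e.g. 0.05).
#' @param category optional named vector of per-set categories
#'   (pathway / GO-BP / GO-CC / GO-MF).
#' @param q_method `"bh"` (default) or `"storey"`.
#' @return data.frame sorted by adjusted p, one row per set passing the
#'   cutoffs: set, category, k, n, K, N, gene_ratio (k/n), pvalue, padj,
#'   qvalue, genes (comma-collapsed overlap).
#' @export
hypergeom_enrich <- function(query, collection, universe,
                             q_cutoff = 0.2, padj_cutoff = NULL,
                             category = NULL, q_method = c("bh", "storey")) {
  q_method <- match.arg(q_method)
  universe <- unique(universe)
  N <- length(universe)
  dropped <- setdiff(query, universe)
  if (length(dropped) > 0) {
    message(length(dropped), " query gene(s) outside the universe dropped")
  }
  query <- unique(intersect(query, universe))
  n <- length(query)
  if (n == 0) {
    warning("empty query after universe intersection; no enrichment computed")
    return(empty_enrichment())
  }
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), universe)
    K <- length(set)
    if (K == 0) return(NULL)
    hit <- intersect(query, set)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm,
               category = if (is.null(category)) NA_character_ else category[[nm]],
               k = k, n = n, K = K, N = N,
               gene_ratio = k / n, pvalue = p,
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(empty_enrichment())
  res$padj <- stats::p.adjust(res$pvalue, method = "BH")
  res$qvalue <- if (q_method == "bh") res$padj else qvalue_storey(res$pvalue)
  if (!is.null(q_cutoff)) res <- res[res$qvalue <= q_cutoff, , drop = FALSE]
  if (!is.null(padj_cutoff)) res <- res[res$padj <= padj_cutoff, , drop = FALSE]
  res <- res[order(res$padj, res$pvalue, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("set", "category", "k", "n", "K", "N", "gene_ratio",
          "pvalue", "padj", "qvalue", "genes")]
}

empty_enrichment <- function() {
  data.frame(set = character(0), category = character(0), k = integer(0),
             n = integer(0), K = integer(0), N = integer(0),
             gene_ratio = numeric(0), pvalue = numeric(0), padj = numeric(0),
             qvalue = numeric(0), genes = character(0), stringsAsFactors = FALSE)
}

# Storey-type q-values: pi0 estimated by a cubic smoothing spline over a
# lambda grid, then applied to the BH-style step-up quantities.
qvalue_storey <- function(p) {
  lambda <- seq(0.05, 0.90, by = 0.05)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
  pi0 <- if (length(p) < 50) {
    min(1, 2 * mean(p))  # too few p-values to smooth; conservative estimate
  } else {
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    max(min(stats::predict(fit, x = max(lambda))$y, 1), 0)
  }
  if (pi0 <= 0) pi0 <- 1e-8
  pi0 * stats::p.adjust(p, method = "BH")
}

#' Fraction enrichment of a curated gene list in a query
#'
#' Compares the observed fraction of curated-list genes among the query
#' (mode `"of_query"`: |query ∩ list| / |query|, as in fraction bar plots)
#' or the fraction of the list recovered by the query (mode `"of_list"`:
#' |query ∩ list| / |list|) against the expected fraction
#' |list| / |universe|. Significance is a one-sided Fisher's exact test on
#' the 2x2 membership table over the universe, and the uncertainty of the
#' observed fraction is the standard deviation over `n_boot` bootstrap
#' resamples of the query (sampling with replacement, seeded).
#'
#' @param query character vector of gene ids (e.g. DEGs); non-empty.
#' @param curated_list character vector of curated gene ids; non-empty
#'   (intersected with the universe).
#' @param universe background gene ids.
#' @param mode `"of_query"` (default) or `"of_list"`.
#' @param n_boot bootstrap resamples for the SE (default 100).
#' @param digits decimal places for the reported percent (default 1).
#' @param seed RNG seed for the bootstrap (default 1).
#' @return one-row data.frame: mode, overlap, query_size, list_size,
#'   universe_size, observed_fraction, observed_percent, expected_fraction,
#'   expected_percent, fisher_p, boot_se.
#' @export
fraction_enrichment <- function(query, curated_list, universe,
                                mode = c("of_query", "of_list"),
                                n_boot = 100, digits = 1, seed = 1) {
  mode <- match.arg(mode)
  universe <- unique(universe)
  query <- unique(intersect(query, universe))
  curated_list <- unique(intersect(curated_list, universe))
  if (length(query) == 0) stop("empty query")
  if (length(curated_list) == 0) stop("empty curated list")
  N <- length(universe)
  n <- length(query)
  K <- length(curated_list)
  k <- length(intersect(query, curated_list))
  denom <- if (mode == "of_query") n else K
  observed <- k / denom
  expected <- K / N
  tab <- matrix(c(k, n - k, K - k, N - K - (n - k)), nrow = 2)
  fisher_p <- stats::fisher.test(tab, alternative = "greater")$p.value
  set.seed(seed)
  in_list <- query %in% curated_list
  boot <- vapply(seq_len(n_boot), function(i) {
    bs <- sample(in_list, n, replace = TRUE)
    sum(bs) / denom
  }, 0)
  data.frame(mode = mode, overlap = k, query_size = n, list_size = K,
             universe_size = N,
             observed_fraction = observed,
             observed_percent = percent_of(k, denom, digits),
             expected_fraction = expected,
             expected_percent = percent_of(K, N, digits),
             fisher_p = fisher_p, boot_se = stats::sd(boot),
             stringsAsFactors = FALSE)
}

#' Recovery of a curated literature list by DEGs, stratified by occurrence
#'
#' Splits the curated list into occurrence strata {1, 2, >=3} (times a gene
#' is reported in the literature) and reports, per stratum, the fraction of
#' its genes recovered by the DEG set, as a percentage at one decimal.
#' Empty strata are reported as missing.
#'
#' @param degs character vector of DEG ids.
#' @param curated data.frame(gene_id, occurrence_count) as from
#'   [read_curated_list()].
#' @param digits decimal places for the percentage (default 1).
#' @return data.frame: stratum ("1", "2", ">=3"), n_genes, n_recovered,
#'   fraction, percent.
#' @export
literature_recovery <- function(degs, curated, digits = 1) {
  if (any(curated$occurrence_count < 1)) stop("occurrence counts must be >= 1")
  stratum <- cut(curated$occurrence_count, breaks = c(0, 1, 2, Inf),
                 labels = c("1", "2", ">=3"))
  out <- lapply(levels(stratum), function(s) {
    genes <- curated$gene_id[stratum == s]
    n <- length(genes)
    r <- length(intersect(genes, degs))
    data.frame(stratum = s, n_genes = n, n_recovered = r,
               fraction = if (n > 0) r / n else NA_real_,
               percent = if (n > 0) percent_of(r, n, digits) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
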
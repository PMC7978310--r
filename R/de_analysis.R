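#' Gene filters for the two differential-expression procedures
#'
#' `filter_min_count()` keeps genes with at least 1 count in every sample
#' (the filter feeding the median-of-ratios/Wald procedure).
#' `filter_cpm()` keeps genes whose counts-per-million exceed 1 in at least
#' one sample (the filter feeding the TMM/quasi-likelihood procedure);
#' CPM = count / library size x 1e6, strict inequality.
#'
#' @param counts gene x sample integer matrix.
#' @param samples optional character vector restricting the filter to a
#'   subset of samples (e.g. the two groups of a contrast).
#' @return character vector of retained gene ids (possibly empty).
#' @export
filter_min_count <- function(counts, samples = colnames(counts)) {
  check_count_matrix(counts)
  m <- counts[, samples, drop = FALSE]
  rownames(m)[apply(m >= 1, 1, all)]
}

#' @rdname filter_min_count
#' @export
filter_cpm <- function(counts, samples = colnames(counts)) {
  check_count_matrix(counts)
  m <- counts[, samples, drop = FALSE]
  libsize <- colSums(m)
  if (any(libsize == 0)) {
    stop("zero library size for sample(s): ",
         paste(colnames(m)[libsize == 0], collapse = ", "))
  }
  cpm <- sweep(m, 2, libsize, `/`) * 1e6
  rownames(m)[apply(cpm > 1, 1, any)]
}

#' Per-gene differential expression by one of two published procedures
#'
#' Fits a per-gene negative-binomial model for a two-group contrast with the
#' chosen procedure's own normalization and test, and returns log2 fold
#' change, raw p and Benjamini-Hochberg adjusted p:
#' \describe{
#'   \item{`"deseq2"` (procedure A)}{median-of-ratios size factors and a
#'     Wald test, via DESeq2; genes are pre-filtered with
#'     [filter_min_count()].}
#'   \item{`"edger"` (procedure B)}{TMM scaling and a quasi-likelihood F
#'     test, via edgeR; genes are pre-filtered with [filter_cpm()].}
#' }
#' Fold changes are reported as case versus control.
#'
#' @param counts gene x sample integer count matrix.
#' @param metadata data.frame(sample_id, group) covering the matrix columns.
#' @param contrast character pair `c(case, control)`.
#' @param procedure `"deseq2"` or `"edger"`.
#' @return data.frame(gene_id, log2fc, pvalue, padj), one row per tested gene.
#' @export
test_de <- function(counts, metadata, contrast, procedure = c("deseq2", "edger")) {
  procedure <- match.arg(procedure)
  check_count_matrix(counts)
  if (length(contrast) != 2 || contrast[1] == contrast[2]) {
    stop("contrast must be two distinct group names c(case, control)")
  }
  if (!all(contrast %in% metadata$group)) stop("contrast group missing from metadata")
  keep <- metadata$group %in% contrast
  meta <- metadata[keep, , drop = FALSE]
  if (any(table(factor(meta$group, levels = contrast)) < 2)) {
    stop("need >= 2 samples per group in the contrast")
  }
  missing <- setdiff(meta$sample_id, colnames(counts))
  if (length(missing) > 0) stop("metadata samples absent from counts: ",
                                paste(missing, collapse = ", "))
  m <- counts[, meta$sample_id, drop = FALSE]
  group <- factor(meta$group, levels = c(contrast[2], contrast[1]))  # control first

  if (procedure == "deseq2") {
    genes <- filter_min_count(m)
    if (length(genes) < 2) stop("fewer than 2 genes pass the min-count filter")
    dds <- DESeq2::DESeqDataSetFromMatrix(
      countData = m[genes, , drop = FALSE],
      colData = data.frame(group = group),
      design = ~group)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds, contrast = c("group", contrast[1], contrast[2]))
    out <- data.frame(gene_id = rownames(res),
                      log2fc = res$log2FoldChange,
                      pvalue = res$pvalue,
                      padj = res$padj,
                      stringsAsFactors = FALSE)
  } else {
    genes <- filter_cpm(m)
    if (length(genes) < 2) stop("fewer than 2 genes pass the CPM filter")
    y <- edgeR::DGEList(counts = m[genes, , drop = FALSE], group = group)
    y <- edgeR::calcNormFactors(y, method = "TMM")
    design <- stats::model.matrix(~group)
    y <- edgeR::estimateDisp(y, design)
    fit <- edgeR::glmQLFit(y, design)
    qlf <- edgeR::glmQLFTest(fit, coef = 2)
    tab <- qlf$table
    out <- data.frame(gene_id = rownames(tab),
                      log2fc = tab$logFC,
                      pvalue = tab$PValue,
                      padj = stats::p.adjust(tab$PValue, method = "BH"),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Combine the two procedures' results into final DEG calls
#'
#' Under the `"intersect"` rule a gene is flagged iff its adjusted p is at or
#' below `alpha` in BOTH procedures — and, when `require_concordance` is on
#' (default), the two fold-change signs agree; sign-discordant genes are
#' dropped from the flagged set with a message. Under the `"union"` rule a
#' gene is flagged iff either procedure reaches `alpha` (used for contrasts
#' where power is very low, e.g. the mild late-onset subtype). The reported
#' direction comes from procedure A's fold change when available, otherwise
#' from B.
#'
#' @param resA,resB data.frames from [test_de()] (procedures A and B).
#' @param rule `"intersect"` or `"union"`.
#' @param alpha adjusted-p threshold in (0, 1), default 0.05.
#' @param require_concordance logical; drop sign-discordant genes under the
#'   intersect rule (default TRUE).
#' @param annotation optional data.frame(gene_id, biotype) merged into the
#'   result; biotypes are grouped into protein_coding / lncRNA / microRNA /
#'   pseudogene / other.
#' @return data.frame of class `"de_result"` with per-gene columns
#'   log2fc_A, pvalue_A, padj_A, log2fc_B, pvalue_B, padj_B, `deg` flag and
#'   `direction` ("up"/"down", NA for unflagged genes), plus `biotype` if
#'   annotation was supplied.
#' @export
combine_de <- function(resA, resB, rule = c("intersect", "union"), alpha = 0.05,
                       require_concordance = TRUE, annotation = NULL) {
  rule <- match.arg(rule)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  names(resA)[-1] <- paste0(names(resA)[-1], "_A")
  names(resB)[-1] <- paste0(names(resB)[-1], "_B")
  merged <- merge(resA, resB, by = "gene_id", all = TRUE)

  hitA <- !is.na(merged$padj_A) & merged$padj_A <= alpha
  hitB <- !is.na(merged$padj_B) & merged$padj_B <= alpha
  if (rule == "intersect") {
    deg <- hitA & hitB
    if (require_concordance) {
      discordant <- deg & sign(merged$log2fc_A) != sign(merged$log2fc_B)
      if (any(discordant)) {
        message(sum(discordant), " gene(s) significant in both procedures but ",
                "with discordant fold-change signs; dropped from the DEG set")
        deg <- deg & !discordant
      }
    }
  } else {
    deg <- hitA | hitB
  }

  lfc <- ifelse(is.na(merged$log2fc_A), merged$log2fc_B, merged$log2fc_A)
  merged$deg <- deg
  merged$direction <- ifelse(deg, ifelse(lfc > 0, "up", "down"), NA_character_)
  if (!is.null(annotation)) {
    merged$biotype <- biotype_category(
      annotation$biotype[match(merged$gene_id, annotation$gene_id)])
  }
  attr(merged, "rule") <- rule
  attr(merged, "alpha") <- alpha
  class(merged) <- c("de_result", "data.frame")
  merged
}

# internal: collapse annotation biotypes into the reporting categories
biotype_category <- function(biotype) {
  out <- rep("other", length(biotype))
  out[biotype %in% c("protein_coding")] <- "protein_coding"
  out[biotype %in% c("lncRNA", "lincRNA", "antisense")] <- "lncRNA"
  out[biotype %in% c("miRNA", "microRNA")] <- "microRNA"
  out[grepl("pseudogene", biotype)] <- "pseudogene"
  out[is.na(biotype)] <- NA_character_
  out
}

#' Run the full dual-procedure DE analysis for one contrast
#'
#' Convenience wrapper chaining [test_de()] for both procedures and
#' [combine_de()].
#'
#' @inheritParams test_de
#' @inheritParams combine_de
#' @return a `"de_result"` data.frame, see [combine_de()].
#' @export
run_de <- function(counts, metadata, contrast, rule = "intersect", alpha = 0.05,
                   require_concordance = TRUE, annotation = NULL) {
  resA <- test_de(counts, metadata, contrast, "deseq2")
  resB <- test_de(counts, metadata, contrast, "edger")
  combine_de(resA, resB, rule = rule, alpha = alpha,
             require_concordance = require_concordance, annotation = annotation)
}

#' Extract flagged DEG ids from a DE result
#'
#' @param de a `"de_result"` data.frame.
#' @param direction optional `"up"` or `"down"` to subset by direction.
#' @return character vector of gene ids.
#' @export
deg_ids <- function(de, direction = NULL) {
  ids <- de$gene_id[de$deg]
  if (!is.null(direction)) ids <- de$gene_id[de$deg & de$direction %in% direction]
  ids
}

#' Summarize DEG counts by direction and coding status
#'
#' @param de a `"de_result"` data.frame (with `biotype` if available).
#' @return one-row data.frame: n_deg, n_up, n_down, n_coding, n_noncoding.
#' @export
summarize_de <- function(de) {
  n_deg <- sum(de$deg)
  coding <- if ("biotype" %in% names(de)) {
    sum(de$deg & de$biotype %in% "protein_coding")
  } else NA_integer_
  data.frame(n_deg = n_deg,
             n_up = sum(de$deg & de$direction %in% "up"),
             n_down = sum(de$deg & de$direction %in% "down"),
             n_coding = coding,
             n_noncoding = if (is.na(coding)) NA_integer_ else n_deg - coding)
}
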
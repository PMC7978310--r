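#' Configuration for an end-to-end pipeline run
#'
#' Collects input paths (or a simulation request), stage toggles, and stage
#' parameters. One global `seed` fans out to per-stage seeds by fixed
#' offsets (+0 simulation, +1 annotations, +2 bootstrap), so each stage is
#' individually reproducible.
#'
#' @param out_dir output directory (created if needed).
#' @param simulate if `TRUE` (default) inputs are generated with
#'   [simulate_dataset()] / [simulate_annotations()]; otherwise the paths
#'   below must point at existing files.
#' @param counts,metadata,blood,annotation,gmt,curated,hits input file paths
#'   (TSV/GMT), used when `simulate = FALSE`.
#' @param markers marker gene id(s) for decontamination; defaults to the
#'   simulation's marker when simulating.
#' @param contrasts list of `c(case, control)` pairs; default the three
#'   subtype-versus-normal comparisons.
#' @param rules named per-case-group combination rule; defaults to
#'   `"intersect"` for EOSPE/LOSPE and `"union"` for LOMPE (the low-power
#'   contrast).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param top_n_variance genes for PCA/clustering (default 500).
#' @param cluster_k flat cluster count (default 2).
#' @param q_cutoff gene-set q-value cutoff (default 0.2).
#' @param n_boot bootstrap resamples for fraction SEs (default 100).
#' @param term_k flat term-group count for the term network (default 5).
#' @param stages character vector of stages to run, in dependency order;
#'   any subset of `c("decontam", "de", "cluster", "enrich", "termnet",
#'   "tfnet")`.
#' @param sim_config optional [sim_config()] overriding the default
#'   simulation (its seed is replaced by the pipeline seed).
#' @param seed global seed (default 1).
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir,
                            simulate = TRUE,
                            counts = NULL, metadata = NULL, blood = NULL,
                            annotation = NULL, gmt = NULL, curated = NULL,
                            hits = NULL,
                            markers = NULL,
                            contrasts = list(c("EOSPE", "normal"),
                                             c("LOSPE", "normal"),
                                             c("LOMPE", "normal")),
                            rules = c(EOSPE = "intersect", LOSPE = "intersect",
                                      LOMPE = "union"),
                            alpha = 0.05,
                            top_n_variance = 500, cluster_k = 2,
                            q_cutoff = 0.2, n_boot = 100, term_k = 5,
                            stages = c("decontam", "de", "cluster", "enrich",
                                       "termnet", "tfnet"),
                            sim_config = NULL,
                            seed = 1) {
  if (!simulate) {
    needed <- list(counts = counts, metadata = metadata)
    missing <- names(needed)[vapply(needed, is.null, TRUE)]
    if (length(missing) > 0) {
      stop("simulate = FALSE requires input paths: ", paste(missing, collapse = ", "))
    }
  }
  cfg <- list(out_dir = out_dir, simulate = simulate,
              paths = list(counts = counts, metadata = metadata, blood = blood,
                           annotation = annotation, gmt = gmt,
                           curated = curated, hits = hits),
              markers = markers, contrasts = contrasts, rules = rules,
              alpha = alpha, top_n_variance = top_n_variance,
              cluster_k = cluster_k, q_cutoff = q_cutoff, n_boot = n_boot,
              term_k = term_k, stages = stages, sim_config = sim_config,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full subtype analysis pipeline
#'
#' Executes the enabled stages in dependency order — decontamination,
#' dual-procedure DE per contrast, sample clustering, enrichment, term
#' network, TF network — writing every stage's tables under `out_dir` with
#' provenance headers, and a `manifest.json` recording parameters, seeds,
#' per-stage status and output checksums. Rerunning with the same
#' configuration reproduces the checksums of all deterministic stages.
#' A stage failure aborts its downstream dependents but completed outputs
#' are kept.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   parameters = config[c("alpha", "top_n_variance", "cluster_k",
                                         "q_cutoff", "n_boot", "term_k")],
                   stages = list(), outputs = list())
  results <- list()
  failed <- character(0)
  prov <- c(seed = config$seed)

  out <- function(name) file.path(config$out_dir, name)
  record <- function(stage, status, files = character(0)) {
    manifest$stages[[stage]] <<- status
    for (f in files) manifest$outputs[[basename(f)]] <<- unname(tools::md5sum(f))
  }
  run_stage <- function(stage, deps, fun) {
    if (!stage %in% c(config$stages, "input")) return(invisible())
    if (any(deps %in% failed)) {
      record(stage, "skipped: failed dependency")
      failed <<- c(failed, stage)
      return(invisible())
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      record(stage, paste("failed:", conditionMessage(res)))
      failed <<- c(failed, stage)
    }
    invisible()
  }

  # --- inputs -----------------------------------------------------------
  run_stage("input", character(0), function() {
    if (config$simulate) {
      sc <- config$sim_config
      if (is.null(sc)) sc <- sim_config(seed = config$seed)
      sc$seed <- config$seed
      sim <- simulate_dataset(sc)
      ann <- simulate_annotations(
        sim, list_size = min(300L, floor(nrow(sim$observed) / 5)),
        seed = config$seed + 1L)
      results$sim <<- sim
      results$input <<- list(counts = sim$observed, metadata = sim$metadata,
                             blood = sim$blood_refs, annotation = sim$annotation,
                             gene_sets = ann$gene_sets,
                             set_category = ann$set_category,
                             curated = ann$curated_list, hits = ann$motif_hits,
                             markers = sc$marker_ids)
      files <- c(write_count_matrix(sim$observed, out("observed_counts.tsv"), prov),
                 write_sample_metadata(sim$metadata, out("metadata.tsv"), prov),
                 write_count_matrix(sim$blood_refs, out("blood_refs.tsv"), prov),
                 write_tsv_prov(sim$annotation, out("annotation.tsv"), prov),
                 write_gmt(ann$gene_sets, out("gene_sets.gmt")),
                 write_tsv_prov(ann$curated_list, out("curated_list.tsv"), prov),
                 write_tsv_prov(ann$motif_hits, out("motif_hits.tsv"), prov))
      record("input", "ok", files)
    } else {
      p <- config$paths
      results$input <<- list(
        counts = read_count_matrix(p$counts),
        metadata = read_sample_metadata(p$metadata),
        blood = if (!is.null(p$blood)) read_count_matrix(p$blood),
        annotation = if (!is.null(p$annotation)) read_tsv_prov(p$annotation),
        gene_sets = if (!is.null(p$gmt)) read_gmt(p$gmt),
        set_category = NULL,
        curated = if (!is.null(p$curated)) read_curated_list(p$curated),
        hits = if (!is.null(p$hits)) read_motif_hits(p$hits),
        markers = config$markers)
      record("input", "ok")
    }
  })

  # --- decontamination --------------------------------------------------
  run_stage("decontam", "input", function() {
    # (decontam depends only on the inputs)
    inp <- results$input
    if (is.null(inp$blood) || is.null(inp$markers)) {
      stop("decontam needs blood references and marker id(s)")
    }
    dec <- remove_blood_contamination(inp$counts, inp$blood, inp$markers)
    results$decontam <<- dec
    files <- c(write_count_matrix(dec$corrected, out("corrected_counts.tsv"), prov),
               write_tsv_prov(dec$report, out("decontam_report.tsv"), prov))
    record("decontam", "ok", files)
  })

  de_input <- function() {
    if (!is.null(results$decontam)) results$decontam$corrected
    else results$input$counts
  }

  # --- differential expression -----------------------------------------
  run_stage("de", c("input", "decontam"), function() {
    inp <- results$input
    de_list <- list()
    files <- character(0)
    summaries <- NULL
    for (ct in config$contrasts) {
      rule <- config$rules[[ct[1]]]
      if (is.null(rule) || is.na(rule)) rule <- "intersect"
      de <- run_de(de_input(), inp$metadata, ct, rule = rule,
                   alpha = config$alpha, annotation = inp$annotation)
      de_list[[ct[1]]] <- de
      f <- out(sprintf("de_%s_vs_%s.tsv", ct[1], ct[2]))
      write_tsv_prov(as.data.frame(de), f, c(prov, rule = rule))
      files <- c(files, f)
      summaries <- rbind(summaries,
                         cbind(contrast = paste(ct, collapse = "_vs_"),
                               rule = rule, summarize_de(de)))
    }
    results$de <<- de_list
    f <- out("de_summary.tsv")
    write_tsv_prov(summaries, f, prov)
    record("de", "ok", c(files, f))
  })

  # --- clustering -------------------------------------------------------
  run_stage("cluster", c("input", "decontam"), function() {
    inp <- results$input
    m <- de_input()
    genes <- select_top_variance_genes(m, min(config$top_n_variance, nrow(m)))
    pca <- pca_samples(m, genes)
    cl <- cluster_samples(m, k = config$cluster_k)
    results$cluster <<- list(genes = genes, pca = pca, clustering = cl)
    scores <- data.frame(sample_id = rownames(pca$scores), pca$scores)
    labels <- data.frame(sample_id = names(cl$labels), cluster = cl$labels)
    files <- c(write_tsv_prov(scores, out("pca_scores.tsv"), prov),
               write_tsv_prov(labels, out("cluster_labels.tsv"), prov),
               write_dendrogram_newick(cl, out("dendrogram.nwk")))
    record("cluster", "ok", files)
  })

  # --- enrichment -------------------------------------------------------
  run_stage("enrich", c("input", "de"), function() {
    inp <- results$input
    if (is.null(inp$gene_sets)) stop("enrich needs a gene-set collection")
    universe <- rownames(de_input())
    enr_list <- list()
    files <- character(0)
    for (grp in names(results$de)) {
      degs <- deg_ids(results$de[[grp]])
      if (length(degs) == 0) next
      enr <- suppressMessages(hypergeom_enrich(
        degs, inp$gene_sets, universe, q_cutoff = config$q_cutoff,
        category = inp$set_category))
      enr_list[[grp]] <- enr
      f <- out(sprintf("enrichment_%s.tsv", grp))
      write_tsv_prov(enr, f, prov)
      files <- c(files, f)
    }
    if (!is.null(inp$curated)) {
      fracs <- NULL
      for (grp in names(results$de)) {
        degs <- deg_ids(results$de[[grp]])
        if (length(degs) == 0) next
        fr <- fraction_enrichment(degs, inp$curated$gene_id, universe,
                                  n_boot = config$n_boot,
                                  seed = config$seed + 2L)
        fracs <- rbind(fracs, cbind(group = grp, fr))
      }
      all_degs <- unique(unlist(lapply(results$de, deg_ids)))
      rec <- literature_recovery(all_degs, inp$curated)
      f1 <- out("fraction_enrichment.tsv"); f2 <- out("literature_recovery.tsv")
      write_tsv_prov(fracs, f1, prov)
      write_tsv_prov(rec, f2, prov)
      files <- c(files, f1, f2)
      results$recovery <<- rec
      results$fractions <<- fracs
    }
    results$enrich <<- enr_list
    record("enrich", "ok", files)
  })

  # --- term network -----------------------------------------------------
  run_stage("termnet", c("input", "de", "enrich"), function() {
    grp <- names(results$enrich)[1]
    enr <- results$enrich[[grp]]
    enr <- enr[enr$k >= 2, , drop = FALSE]
    if (is.null(enr) || nrow(enr) < 2) stop("not enough enriched terms for a network")
    g <- suppressMessages(build_term_gene_graph(enr, results$de[[grp]]))
    J <- jaccard_term_similarity(g)
    k <- min(config$term_k, nrow(J))
    cl <- suppressMessages(cluster_terms(J, k, suggest_k = FALSE))
    results$termnet <<- list(graph = g, similarity = J, clusters = cl)
    labels <- data.frame(term = names(cl$labels), group = cl$labels)
    files <- c(write_graphml(g, out("term_gene_network.graphml")),
               write_graph_tables(g, out("term_gene_edges.tsv")),
               write_tsv_prov(labels, out("term_groups.tsv"), prov))
    record("termnet", "ok", files)
  })

  # --- TF network -------------------------------------------------------
  run_stage("tfnet", c("input", "de"), function() {
    inp <- results$input
    if (is.null(inp$hits)) stop("tfnet needs a motif-hit table")
    grp <- names(results$de)[1]
    de <- results$de[[grp]]
    universe <- rownames(de_input())
    cov <- motif_coverage(inp$hits, de)
    cls <- suppressMessages(classify_tf_direction(inp$hits, de))
    links <- suppressMessages(tf_pathway_links(inp$hits, de, inp$gene_sets,
                                               universe))
    results$tfnet <<- list(coverage = cov, classes = cls, links = links)
    files <- c(write_tsv_prov(cov, out("tf_coverage.tsv"), prov),
               write_tsv_prov(cls, out("tf_classes.tsv"), prov),
               write_tsv_prov(links, out("tf_pathway_links.tsv"), prov))
    if (nrow(cls) > 0) {
      g <- tf_target_pathway_graph(cls$tf[1], inp$hits, de, inp$gene_sets)
      files <- c(files, write_graphml(g, out("tf_target_pathway.graphml")))
    }
    record("tfnet", "ok", files)
  })

  manifest$ok <- length(failed) == 0
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
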
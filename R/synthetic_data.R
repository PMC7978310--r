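#' Configuration for the synthetic placental RNA-seq generator
#'
#' The generator emulates the cohort structure the pipeline is designed for:
#' bulk negative-binomial counts for a normal group and three preeclampsia
#' subtypes (EOSPE, LOSPE, LOMPE), contaminated by an admixture of cord
#' blood that carries a blood-exclusive hemoglobin-like marker gene, with
#' subtype-specific differential expression implanted at very different
#' rates (many DEGs in EOSPE, few in LOSPE, near none in LOMPE).
#'
#' @param n_genes total number of genes, including the marker (default 5000).
#' @param group_sizes named integer vector of samples per group; defaults to
#'   the cohort sizes the pipeline targets (normal=32, EOSPE=9, LOSPE=15,
#'   LOMPE=9). Every group used in a DE contrast needs >= 2 samples.
#' @param de_fraction named fractions of genes implanted as DE versus normal
#'   per case group (default EOSPE=0.12, LOSPE=0.02, LOMPE=0.002).
#' @param log2fc_magnitude absolute implanted log2 fold change (default 1.5).
#' @param up_bias probability an implanted DE gene is up-regulated
#'   (default 0.6, reflecting the excess of up-regulated DEGs seen in
#'   placental PE data).
#' @param dispersion two-parameter NB dispersion trend
#'   `phi(mu) = asymptote + scale / mu`, decreasing in the mean as is typical
#'   for bulk RNA-seq (default asymptote 0.05, scale 2).
#' @param library_size_range sampling interval for per-sample sequencing
#'   depth (default 5e5 to 2e6).
#' @param contamination_range interval in `[0, 1)` for the per-sample blood
#'   admixture scale alpha (default 0.02 to 0.20).
#' @param n_blood_refs number of cord-blood reference columns (default 2).
#' @param marker_gene_id identifier of the blood-exclusive marker; its true
#'   placental expression is exactly 0 and it is never implanted as DE.
#' @param marker_ids optional additional blood-exclusive marker ids (for the
#'   multi-marker decontamination option); same constraints as the marker.
#' @param marker_blood_mean expected marker count in the blood profile at the
#'   blood reference depth (default 10000; the marker is kept the most
#'   abundant blood gene, as hemoglobin transcripts dominate red cells).
#' @param blood_depth reference depth at which the blood profile is expressed
#'   (default 1e6).
#' @param contaminant_noise if `TRUE` (default) contaminant counts are
#'   Poisson draws with mean `alpha_s * blood_profile`; if `FALSE` the
#'   admixture is deterministic (`round_half_up(alpha_s * blood_profile)`),
#'   which makes marker-based correction exact up to rounding.
#' @param seed integer RNG seed.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 5000,
                       group_sizes = c(normal = 32, EOSPE = 9, LOSPE = 15, LOMPE = 9),
                       de_fraction = c(EOSPE = 0.12, LOSPE = 0.02, LOMPE = 0.002),
                       log2fc_magnitude = 1.5,
                       up_bias = 0.6,
                       dispersion = c(asymptote = 0.05, scale = 2),
                       library_size_range = c(5e5, 2e6),
                       contamination_range = c(0.02, 0.20),
                       n_blood_refs = 2,
                       marker_gene_id = "HBM_LIKE",
                       marker_ids = character(0),
                       marker_blood_mean = 1e4,
                       blood_depth = 1e6,
                       contaminant_noise = TRUE,
                       seed = 1) {
  if (n_genes < 10) stop("n_genes too small")
  if (is.null(names(group_sizes)) || !"normal" %in% names(group_sizes)) {
    stop("group_sizes must be named and include 'normal'")
  }
  if (any(group_sizes != floor(group_sizes))) stop("group sizes must be integers")
  if (any(group_sizes < 2)) stop("every group needs >= 2 samples")
  if (!all(names(de_fraction) %in% names(group_sizes))) {
    stop("de_fraction names must be a subset of group_sizes names")
  }
  if (any(de_fraction < 0 | de_fraction > 1)) stop("de_fraction values must be in [0, 1]")
  if (up_bias < 0 || up_bias > 1) stop("up_bias must be in [0, 1]")
  if (log2fc_magnitude <= 0) stop("log2fc_magnitude must be positive")
  if (length(contamination_range) != 2 || any(contamination_range < 0) ||
      any(contamination_range >= 1) || diff(contamination_range) < 0) {
    stop("contamination_range must be an increasing interval inside [0, 1)")
  }
  if (length(library_size_range) != 2 || any(library_size_range <= 0) ||
      diff(library_size_range) < 0) {
    stop("library_size_range must be an increasing pair of positive depths")
  }
  if (n_blood_refs < 1) stop("n_blood_refs must be >= 1")
  cfg <- list(n_genes = as.integer(n_genes), group_sizes = group_sizes,
              de_fraction = de_fraction, log2fc_magnitude = log2fc_magnitude,
              up_bias = up_bias, dispersion = dispersion,
              library_size_range = library_size_range,
              contamination_range = contamination_range,
              n_blood_refs = as.integer(n_blood_refs),
              marker_gene_id = marker_gene_id,
              marker_ids = unique(c(marker_gene_id, marker_ids)),
              marker_blood_mean = marker_blood_mean,
              blood_depth = blood_depth,
              contaminant_noise = isTRUE(contaminant_noise),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a contaminated placental RNA-seq dataset with ground truth
#'
#' Draws true placental counts from per-gene negative binomials (log-normal
#' baseline means, mean-decreasing dispersion trend), implants group-specific
#' fold changes of `2^(+-log2fc_magnitude)` relative to normal, and adds a
#' cord-blood contaminant: for sample `s`, contaminant counts are Poisson
#' (or deterministic, see `contaminant_noise`) with mean
#' `alpha_s * blood_profile`, where the blood profile is the expected blood
#' count vector at the blood reference depth. Marker genes are expressed only
#' in blood, so any marker signal in a placental sample comes from
#' contamination alone. Blood reference columns are independent Poisson draws
#' from the profile at their own depths.
#'
#' @param config a [sim_config()] object.
#' @return list of class `"pe_simulation"` with elements
#'   \describe{
#'     \item{observed}{gene x sample integer matrix, contaminated counts}
#'     \item{metadata}{data.frame(sample_id, group)}
#'     \item{blood_refs}{gene x reference integer matrix}
#'     \item{annotation}{data.frame(gene_id, symbol, biotype)}
#'     \item{truth}{ground-truth bundle: `true_counts`, `contaminant`
#'       (exact bookkeeping: observed = true_counts + contaminant),
#'       `de_labels` (per group, data.frame(gene_id, sign)), `alpha`,
#'       `blood_profile`, `gene_means`, `dispersion`, `seed_used`}
#'   }
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  ng <- config$n_genes
  markers <- config$marker_ids
  if (length(markers) >= ng) stop("more markers than genes")

  gene_ids <- sprintf("G%05d", seq_len(ng - length(markers)))
  gene_ids <- c(gene_ids, markers)
  is_marker <- gene_ids %in% markers

  # baseline placental means, expressed as expected counts at depth 1e6
  base <- stats::rlnorm(ng, meanlog = log(40), sdlog = 1.6)
  base[is_marker] <- 0
  rel <- base / sum(base)                         # relative abundance
  mu_ref <- stats::setNames(rel * 1e6, gene_ids)
  phi <- config$dispersion[["asymptote"]] +
    config$dispersion[["scale"]] / pmax(unname(mu_ref), 1e-8)
  phi[is_marker] <- config$dispersion[["asymptote"]]
  names(phi) <- gene_ids

  # implanted DE structure per case group (marker genes never eligible)
  de_labels <- list()
  fc <- list()
  eligible <- which(!is_marker)
  for (grp in names(config$de_fraction)) {
    n_de <- round(config$de_fraction[[grp]] * length(eligible))
    idx <- sort(sample(eligible, n_de))
    sign <- ifelse(stats::runif(n_de) < config$up_bias, 1L, -1L)
    de_labels[[grp]] <- data.frame(gene_id = gene_ids[idx], sign = sign,
                                   stringsAsFactors = FALSE)
    v <- rep(1, ng)
    v[idx] <- 2^(sign * config$log2fc_magnitude)
    fc[[grp]] <- v
  }

  groups <- rep(names(config$group_sizes), config$group_sizes)
  n_samples <- length(groups)
  sample_ids <- sprintf("S%03d_%s", seq_len(n_samples), groups)
  depths <- stats::runif(n_samples, config$library_size_range[1], config$library_size_range[2])

  true_counts <- matrix(0L, ng, n_samples, dimnames = list(gene_ids, sample_ids))
  for (j in seq_len(n_samples)) {
    v <- if (groups[j] %in% names(fc)) fc[[groups[j]]] else rep(1, ng)
    mu <- rel * v
    mu <- mu / sum(mu) * depths[j]              # renormalize to target depth
    true_counts[, j] <- stats::rnbinom(ng, mu = mu, size = 1 / phi)
  }

  # blood profile: expected contaminant counts at the blood reference depth;
  # the marker dominates, as hemoglobin transcripts do in red blood cells
  blood_base <- stats::rlnorm(ng, meanlog = log(30), sdlog = 1.3)
  blood_base[is_marker] <- 0
  blood_nonmarker <- blood_base / sum(blood_base) *
    (config$blood_depth - config$marker_blood_mean * length(markers))
  blood_nonmarker <- pmin(blood_nonmarker, 0.8 * config$marker_blood_mean)
  blood_profile <- blood_nonmarker
  blood_profile[is_marker] <- config$marker_blood_mean
  names(blood_profile) <- gene_ids

  alpha <- stats::runif(n_samples, config$contamination_range[1], config$contamination_range[2])
  contaminant <- matrix(0L, ng, n_samples, dimnames = dimnames(true_counts))
  for (j in seq_len(n_samples)) {
    contaminant[, j] <- if (config$contaminant_noise) {
      stats::rpois(ng, lambda = alpha[j] * blood_profile)
    } else {
      as.integer(round_half_up(alpha[j] * blood_profile))
    }
  }
  observed <- true_counts + contaminant

  ref_depths <- stats::runif(config$n_blood_refs, config$library_size_range[1],
                             config$library_size_range[2])
  blood_refs <- vapply(ref_depths, function(d) {
    as.integer(stats::rpois(ng, lambda = blood_profile * d / config$blood_depth))
  }, integer(ng))
  dimnames(blood_refs) <- list(gene_ids, sprintf("CB%02d", seq_len(config$n_blood_refs)))

  biotype <- sample(c("protein_coding", "lncRNA", "microRNA", "pseudogene", "other"),
                    ng, replace = TRUE, prob = c(0.70, 0.15, 0.04, 0.08, 0.03))
  annotation <- data.frame(gene_id = gene_ids, symbol = paste0("SYM_", gene_ids),
                           biotype = biotype, stringsAsFactors = FALSE)

  storage.mode(observed) <- "integer"
  storage.mode(true_counts) <- "integer"
  out <- list(observed = observed,
              metadata = data.frame(sample_id = sample_ids, group = groups,
                                    stringsAsFactors = FALSE),
              blood_refs = blood_refs,
              annotation = annotation,
              truth = list(true_counts = true_counts, contaminant = contaminant,
                           de_labels = de_labels, alpha = alpha,
                           blood_profile = blood_profile,
                           gene_means = mu_ref, dispersion = phi,
                           seed_used = config$seed),
              config = config)
  class(out) <- "pe_simulation"
  out
}

#' @export
print.pe_simulation <- function(x, ...) {
  cat("pe_simulation:", nrow(x$observed), "genes x", ncol(x$observed), "samples\n")
  cat("  groups:", paste(sprintf("%s=%d", names(table(x$metadata$group)),
                                 table(x$metadata$group)), collapse = ", "), "\n")
  cat("  implanted DEGs:", paste(sprintf("%s=%d", names(x$truth$de_labels),
                                         vapply(x$truth$de_labels, nrow, 0L)),
                                 collapse = ", "), "\n")
  invisible(x)
}

#' Simulate annotations: curated lists, gene sets, and motif hits
#'
#' Generates the annotation side-inputs the enrichment and network stages
#' consume, with controlled overlap to the implanted DE structure:
#' a curated literature-like gene list whose members are enriched for true
#' DEGs at a configurable odds ratio and carry occurrence counts (1 / 2 / >=3,
#' with recovery increasing in occurrence), a GMT-style gene-set collection in
#' which half the sets are DEG-enriched, and a TF -> target motif-hit table
#' covering a configurable fraction of one group's true DEGs.
#'
#' @param sim a `"pe_simulation"` from [simulate_dataset()] (or its `truth`).
#' @param list_size curated list size (default 300).
#' @param odds_ratio sampling odds of a true DEG entering the curated list
#'   relative to a non-DEG (default 4; 1 = null overlap).
#' @param n_sets number of gene sets (default 40).
#' @param set_size_range inclusive size interval per set (default 10 to 200).
#' @param set_odds_ratio DEG sampling odds inside the enriched half of the
#'   sets (default 5).
#' @param n_tf number of transcription factors (default 23).
#' @param tf_coverage fraction of the target group's true DEGs covered by at
#'   least one TF (default 0.79).
#' @param tf_group truth group whose DEGs the TFs target (default "EOSPE").
#' @param seed RNG seed (default: the simulation's seed + 1).
#' @return list with `curated_list` (data.frame gene_id, occurrence_count),
#'   `gene_sets` (named list with a `"description"` attribute),
#'   `set_category` (named vector pathway/GO-BP), and `motif_hits`
#'   (data.frame tf, motif, target).
#' @export
simulate_annotations <- function(sim, list_size = 300, odds_ratio = 4,
                                 n_sets = 40, set_size_range = c(10, 200),
                                 set_odds_ratio = 5,
                                 n_tf = 23, tf_coverage = 0.79,
                                 tf_group = "EOSPE", seed = NULL) {
  truth <- if (inherits(sim, "pe_simulation")) sim$truth else sim
  genes <- rownames(truth$true_counts)
  if (is.null(seed)) seed <- truth$seed_used + 1L
  set.seed(seed)

  all_degs <- unique(unlist(lapply(truth$de_labels, `[[`, "gene_id")))
  universe <- genes
  if (list_size > length(universe)) stop("curated list larger than the gene universe")
  if (odds_ratio <= 0) stop("odds_ratio must be positive")

  w <- ifelse(universe %in% all_degs, odds_ratio, 1)
  curated <- sample(universe, list_size, prob = w)
  in_deg <- curated %in% all_degs
  # occurrence strata: genes reported more often are more reliably DE
  occ <- integer(list_size)
  occ[in_deg] <- sample(c(1L, 2L, 3L), sum(in_deg), replace = TRUE,
                        prob = c(0.30, 0.30, 0.40))
  occ[!in_deg] <- sample(c(1L, 2L, 3L), sum(!in_deg), replace = TRUE,
                         prob = c(0.75, 0.17, 0.08))
  occ[occ == 3L] <- occ[occ == 3L] + stats::rpois(sum(occ == 3L), 0.7)
  curated_list <- data.frame(gene_id = curated, occurrence_count = occ,
                             stringsAsFactors = FALSE)

  if (set_size_range[1] < 1 || set_size_range[2] > length(universe)) {
    stop("set_size_range infeasible for the gene universe")
  }
  sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets, replace = TRUE)
  enriched <- seq_len(n_sets) %% 2 == 1
  gene_sets <- lapply(seq_len(n_sets), function(i) {
    wset <- if (enriched[i]) ifelse(universe %in% all_degs, set_odds_ratio, 1) else NULL
    sort(sample(universe, sizes[i], prob = wset))
  })
  names(gene_sets) <- sprintf("SET%03d", seq_len(n_sets))
  attr(gene_sets, "description") <- stats::setNames(
    ifelse(enriched, "deg_enriched", "background"), names(gene_sets))
  set_category <- stats::setNames(
    rep_len(c("pathway", "GO-BP"), n_sets), names(gene_sets))

  group_degs <- if (tf_group %in% names(truth$de_labels)) {
    truth$de_labels[[tf_group]]$gene_id
  } else character(0)
  motif_hits <- if (length(group_degs) == 0 || n_tf == 0) {
    data.frame(tf = character(0), motif = character(0), target = character(0),
               stringsAsFactors = FALSE)
  } else {
    if (tf_coverage < 0 || tf_coverage > 1) stop("tf_coverage must be in [0, 1]")
    covered <- sample(group_degs, round(tf_coverage * length(group_degs)))
    tfs <- sprintf("TF%02d", seq_len(n_tf))
    # every covered DEG gets >=1 TF; some get several (shared regulation)
    n_per <- 1L + stats::rpois(length(covered), 0.5)
    rows <- data.frame(
      tf = unlist(lapply(n_per, function(k) sample(tfs, min(k, n_tf)))),
      target = rep(covered, pmin(n_per, n_tf)), stringsAsFactors = FALSE)
    # background targets outside the DEG set (the scanner also hits non-DEGs)
    bg <- sample(setdiff(universe, group_degs), min(100, length(universe) - length(group_degs)))
    rows <- rbind(rows, data.frame(tf = sample(tfs, length(bg), replace = TRUE),
                                   target = bg, stringsAsFactors = FALSE))
    rows$motif <- paste0("M_", rows$tf)
    # a second motif for a few TFs, duplicating hits (dedup is downstream's job)
    dup <- rows$tf %in% tfs[seq_len(min(3, n_tf))]
    extra <- rows[dup, ]
    extra$motif <- paste0(extra$motif, "b")
    rows <- rbind(rows, extra)
    rows[order(rows$tf, rows$target, rows$motif), c("tf", "motif", "target")]
  }
  rownames(motif_hits) <- NULL

  list(curated_list = curated_list, gene_sets = gene_sets,
       set_category = set_category, motif_hits = motif_hits)
}
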
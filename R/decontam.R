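#' Build a per-gene blood reference profile from cord-blood samples
#'
#' Combines one or more cord-blood reference columns into a single per-gene
#' count profile: each column is scaled to the mean reference depth, the
#' scaled columns are averaged per gene, and the average is rounded half-up
#' to an integer. A single reference column is returned unchanged.
#'
#' @param blood_refs integer matrix (genes x reference samples) or a single
#'   named vector/one-column matrix.
#' @return named integer vector of per-gene blood reference counts.
#' @export
#' @examples
#' m <- matrix(c(10L, 0L, 20L, 2L), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
#' build_blood_profile(m)  # g1 averages its depth-scaled counts
build_blood_profile <- function(blood_refs) {
  if (is.vector(blood_refs)) {
    blood_refs <- matrix(blood_refs, ncol = 1,
                         dimnames = list(names(blood_refs), "blood"))
  }
  check_count_matrix(blood_refs, "blood_refs")
  depths <- colSums(blood_refs)
  if (any(depths == 0)) {
    stop("all-zero blood reference column: ", colnames(blood_refs)[depths == 0][1])
  }
  if (ncol(blood_refs) == 1) {
    return(stats::setNames(as.integer(blood_refs[, 1]), rownames(blood_refs)))
  }
  scaled <- sweep(blood_refs, 2, mean(depths) / depths, `*`)
  stats::setNames(as.integer(round_half_up(rowMeans(scaled))), rownames(blood_refs))
}

#' Estimate per-sample blood contamination scales from a marker gene
#'
#' The contamination scale of sample `j` is the ratio of the marker count
#' observed in that placental sample to the marker count in the blood
#' profile — with the canonical single hemoglobin-like marker this is
#' exactly the marker ratio used to recalibrate raw counts. With several
#' markers the ratio of summed marker counts is used, which reduces
#' single-gene sampling noise.
#'
#' @param observed gene x sample integer count matrix (placental samples).
#' @param profile named per-gene blood profile from [build_blood_profile()].
#' @param markers character vector of one or more blood-exclusive marker
#'   gene ids; all must be present in both matrices, and their summed count
#'   in the profile must be positive.
#' @return list of class `"contamination_estimate"` with per-sample `scale`
#'   (>= 0; 0 iff the sample shows no marker signal), `marker_placenta`
#'   (per-sample summed marker counts) and `marker_blood` (profile sum).
#' @export
estimate_scale <- function(observed, profile, markers) {
  check_count_matrix(observed, "observed")
  if (length(markers) == 0) stop("need at least one marker gene id")
  missing_obs <- setdiff(markers, rownames(observed))
  if (length(missing_obs) > 0) {
    stop("marker(s) absent from count matrix: ", paste(missing_obs, collapse = ", "))
  }
  missing_prof <- setdiff(markers, names(profile))
  if (length(missing_prof) > 0) {
    stop("marker(s) absent from blood profile: ", paste(missing_prof, collapse = ", "))
  }
  marker_blood <- sum(profile[markers])
  if (marker_blood <= 0) stop("marker count in blood profile is 0; scale undefined")
  marker_placenta <- colSums(observed[markers, , drop = FALSE])
  est <- list(scale = marker_placenta / marker_blood,
              marker_placenta = marker_placenta,
              marker_blood = marker_blood,
              markers = markers)
  class(est) <- "contamination_estimate"
  est
}

#' @export
print.contamination_estimate <- function(x, ...) {
  cat("contamination_estimate over", length(x$scale), "samples;",
      "markers:", paste(x$markers, collapse = ", "), "\n")
  cat("  scale: min", signif(min(x$scale), 3), " median",
      signif(stats::median(x$scale), 3), " max", signif(max(x$scale), 3), "\n")
  invisible(x)
}

#' Subtract scaled blood contamination from placental counts
#'
#' For every gene X and sample j the corrected count is
#' `observed[X, j] - profile[X] * scale[j]`, i.e. the raw placental count
#' minus the blood count scaled by that sample's marker ratio. The result is
#' rounded half-up to an integer and clipped below at zero (counts must stay
#' non-negative for downstream NB models). Genes absent from the blood
#' profile are left unchanged.
#'
#' @param observed gene x sample integer count matrix.
#' @param profile named per-gene blood profile.
#' @param estimate a `"contamination_estimate"` computed against `profile`
#'   for these samples.
#' @return corrected integer count matrix, same dimensions as `observed`.
#' @export
#' @examples
#' obs <- matrix(c(100L, 5L), 2, dimnames = list(c("gA", "gB"), "s1"))
#' prof <- c(gA = 40, gB = 100, HBM = 200)
#' est <- list(scale = c(s1 = 0.25), marker_blood = 200,
#'             marker_placenta = c(s1 = 50), markers = "HBM")
#' class(est) <- "contamination_estimate"
#' decontaminate(obs, prof, est)  # gA: 100 - 40*0.25 = 90; gB clipped to 0
decontaminate <- function(observed, profile, estimate) {
  check_count_matrix(observed, "observed")
  if (!inherits(estimate, "contamination_estimate")) {
    stop("estimate must come from estimate_scale()")
  }
  if (length(estimate$scale) != ncol(observed) ||
      !identical(names(estimate$scale), colnames(observed))) {
    stop("estimate does not match the samples of the count matrix")
  }
  prof <- align_profile(profile, rownames(observed))
  corrected <- observed - outer(prof, estimate$scale)
  corrected <- round_half_up(corrected)
  corrected[corrected < 0] <- 0
  storage.mode(corrected) <- "integer"
  dimnames(corrected) <- dimnames(observed)
  corrected
}

#' One-call decontamination of a count matrix
#'
#' Convenience wrapper: build the blood profile, estimate per-sample scales
#' from the marker(s), and subtract. Returns the corrected matrix with the
#' estimate attached as an attribute, plus a per-sample report table.
#'
#' @inheritParams estimate_scale
#' @param blood_refs cord-blood reference count matrix.
#' @return list with `corrected` (integer matrix), `estimate`, `profile`,
#'   and `report` (data.frame sample_id, marker_count, scale).
#' @export
remove_blood_contamination <- function(observed, blood_refs, markers) {
  profile <- build_blood_profile(blood_refs)
  estimate <- estimate_scale(observed, profile, markers)
  corrected <- decontaminate(observed, profile, estimate)
  report <- data.frame(sample_id = colnames(observed),
                       marker_count = as.integer(estimate$marker_placenta),
                       scale = unname(estimate$scale),
                       stringsAsFactors = FALSE)
  list(corrected = corrected, estimate = estimate, profile = profile,
       report = report)
}
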
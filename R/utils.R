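#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed percentages in reports
#' follow the everyday half-up convention (e.g. 187.5 -> 188), so all
#' integerization and percent reporting in this package goes through here.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(187.5)    # 188
#' round_half_up(0.125, 2) # 0.13
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Report a count ratio as a rounded percentage
#'
#' The reporting primitive behind every fraction in the package's outputs:
#' `100 * numerator / denominator`, rounded half-up at the requested
#' precision. Feeding it a printed numerator/denominator pair reproduces the
#' printed percentage exactly.
#'
#' @param numerator,denominator non-negative counts; `denominator > 0`.
#' @param digits decimal places of the percentage (default 1).
#' @return numeric percentage.
#' @export
#' @examples
#' percent_of(296, 934)       # 31.7
#' percent_of(2349, 2977, 0)  # 79
percent_of <- function(numerator, denominator, digits = 1) {
  stopifnot(length(numerator) == length(denominator) || length(denominator) == 1)
  if (any(denominator <= 0)) stop("denominator must be positive")
  round_half_up(100 * numerator / denominator, digits)
}

# internal: stop unless counts look like a gene x sample integer matrix
check_count_matrix <- function(counts, what = "counts") {
  if (!is.matrix(counts)) stop(what, " must be a matrix")
  if (is.null(rownames(counts))) stop(what, " must have gene ids as rownames")
  if (is.null(colnames(counts))) stop(what, " must have sample ids as colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids in ", what)
  if (any(counts < 0)) stop(what, " contains negative values")
  if (any(counts != floor(counts))) stop(what, " contains non-integer values")
  invisible(counts)
}

# internal: align a per-gene profile vector to a matrix's genes (absent -> 0)
align_profile <- function(profile, gene_ids) {
  if (is.null(names(profile))) stop("blood profile must be a named vector")
  out <- stats::setNames(numeric(length(gene_ids)), gene_ids)
  shared <- intersect(gene_ids, names(profile))
  out[shared] <- profile[shared]
  out
}
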
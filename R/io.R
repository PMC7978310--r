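#' Read a gene x sample count matrix from TSV
#'
#' Expects a header row, gene identifiers in the first column and one column
#' per sample. Lines starting with `#` (provenance headers written by this
#' package) are skipped. Cells must be non-negative integers.
#'
#' @param path path to a tab-separated file.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count matrix needs a gene-id column plus >=1 sample column: ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate gene ids in ", path, ": ",
         paste(utils::head(unique(ids[duplicated(ids)]), 3), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!is.finite(m) | m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-integer or negative count at gene '", ids[bad[1, 1]],
         "', sample '", colnames(m)[bad[1, 2]], "' in ", path)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Write a count matrix as TSV with a provenance header
#'
#' @param counts integer matrix, genes x samples.
#' @param path output path.
#' @param provenance optional named character/numeric vector recorded in the
#'   `#` header line (e.g. seed and stage parameters).
#' @export
write_count_matrix <- function(counts, path, provenance = NULL) {
  check_count_matrix(counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(provenance), con)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

provenance_line <- function(extra = NULL) {
  fields <- c(package = "pesubtype",
              version = as.character(utils::packageVersion("pesubtype")))
  if (!is.null(extra)) fields <- c(fields, vapply(extra, as.character, ""))
  paste0("# ", paste(names(fields), unname(fields), sep = "=", collapse = " "))
}

#' Read/write a sample metadata table (sample_id, group)
#'
#' @param path TSV path with columns `sample_id` and `group`.
#' @return data.frame with character `sample_id` and `group`.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("metadata must have columns sample_id and group: ", path)
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in ", path)
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  df
}

#' @rdname read_sample_metadata
#' @param metadata data.frame with `sample_id` and `group`.
#' @param provenance optional provenance fields, see [write_count_matrix()].
#' @export
write_sample_metadata <- function(metadata, path, provenance = NULL) {
  write_tsv_prov(metadata, path, provenance)
}

# internal generic TSV writer with provenance header
write_tsv_prov <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal generic TSV reader tolerant of provenance headers
read_tsv_prov <- function(path, required = NULL) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!is.null(required) && !all(required %in% names(df))) {
    stop("expected columns ", paste(required, collapse = ", "), " in ", path)
  }
  df
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @return named list of character vectors; the `description` field is kept
#'   as a `"description"` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT line (need name, description, >=1 gene): line ", which(bad)[1])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(names(sets))) stop("duplicate set names in ", path)
  attr(sets, "description") <- stats::setNames(vapply(parts, `[[`, "", 2), names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param description optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- attr(sets, "description")
  if (is.null(description)) description <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a curated gene list with literature occurrence counts
#'
#' @param path TSV with columns `gene_id` and `occurrence_count` (integers
#'   >= 1: times the gene appears in the literature).
#' @return data.frame(gene_id, occurrence_count).
#' @export
read_curated_list <- function(path) {
  df <- read_tsv_prov(path, c("gene_id", "occurrence_count"))
  if (any(df$occurrence_count < 1 | df$occurrence_count != floor(df$occurrence_count))) {
    stop("occurrence_count must be integers >= 1 in ", path)
  }
  df
}

#' Read a motif-hit table (tf, motif, target)
#'
#' Output of an external motif scanner mapping transcription factors to
#' putative target genes. A missing `motif` column is tolerated (filled
#' with the TF id).
#'
#' @param path TSV with columns `tf`, `target` and optionally `motif`.
#' @return data.frame(tf, motif, target).
#' @export
read_motif_hits <- function(path) {
  df <- read_tsv_prov(path, c("tf", "target"))
  if (is.null(df$motif)) df$motif <- df$tf
  df[, c("tf", "motif", "target")]
}
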
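#' Construct a count matrix with sample metadata
#'
#' The universal carrier between pipeline stages: a non-negative integer
#' feature-by-sample count matrix together with per-sample metadata. The
#' design mirrors the `DGEList` idiom (counts plus a `samples` data frame)
#' so that every stage receives counts and design information as one object.
#'
#' @param counts Numeric matrix, features x samples, non-negative. Row names
#'   are feature ids (unique, required); column names are sample ids matching
#'   `samples$sample_id`.
#' @param samples Data frame of per-sample metadata with at least a
#'   `sample_id` column. Recognised columns: `condition` (e.g. "control" /
#'   "patient"), `assay` ("input", "IP" or "RIP"), `timepoint_h`
#'   (non-negative hours; `NA` outside time courses), `replicate`
#'   (positive integer), `batch`.
#' @param feature_kind Character scalar or vector (recycled), one of
#'   `"gene"`, `"peak"`, `"spikein"` per feature.
#' @param allow_fractional Permit non-integer counts. Only the noiseless
#'   simulator mode uses this (expected counts are continuous); file I/O and
#'   ordinary analysis keep the integer invariant.
#'
#' @return An object of class `"count_matrix"`: a list with elements
#'   `counts`, `samples`, `feature_kind`.
#' @export
count_matrix <- function(counts, samples, feature_kind = "gene",
                         allow_fractional = FALSE) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts))) stop("counts must have feature ids as row names")
  if (is.null(colnames(counts))) stop("counts must have sample ids as column names")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(samples)) stop("samples must contain a sample_id column")
  feature_kind <- rep_len(as.character(feature_kind), nrow(counts))
  obj <- structure(
    list(counts = counts, samples = samples, feature_kind = feature_kind),
    class = "count_matrix"
  )
  validate_count_matrix(obj, allow_fractional = allow_fractional)
  obj
}

#' Validate a count_matrix object
#'
#' Checks the invariants every stage relies on: unique feature and sample
#' ids, metadata present for every column, non-negative (integer) counts,
#' and joint uniqueness of (condition, assay, timepoint_h, replicate).
#'
#' @param x A `count_matrix`.
#' @param allow_fractional Permit non-integer counts (noiseless simulations).
#' @return `x`, invisibly; errors describe the offending cell or sample.
#' @export
validate_count_matrix <- function(x, allow_fractional = FALSE) {
  stopifnot(inherits(x, "count_matrix"))
  counts <- x$counts
  fid <- rownames(counts)
  if (anyDuplicated(fid)) {
    stop("duplicated feature ids: ", paste(unique(fid[duplicated(fid)]), collapse = ", "))
  }
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("negative or non-numeric count at feature '%s', sample '%s'",
                 fid[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  if (!allow_fractional) {
    frac <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
    if (nrow(frac) > 0) {
      stop(sprintf("non-integer count at feature '%s', sample '%s'",
                   fid[frac[1, 1]], colnames(counts)[frac[1, 2]]))
    }
  }
  sid <- x$samples$sample_id
  if (anyDuplicated(sid)) stop("duplicated sample_id in metadata")
  missing_meta <- setdiff(colnames(counts), sid)
  if (length(missing_meta) > 0) {
    stop("no metadata row for sample(s): ", paste(missing_meta, collapse = ", "))
  }
  if (!identical(colnames(counts), sid)) {
    stop("sample metadata must be in the same order as count columns")
  }
  if (length(x$feature_kind) != nrow(counts)) {
    stop("feature_kind length must match the number of features")
  }
  keys <- intersect(c("condition", "assay", "timepoint_h", "replicate"), names(x$samples))
  if (length(keys) == 4) {
    key <- do.call(paste, c(x$samples[keys], sep = "\r"))
    if (anyDuplicated(key)) {
      stop("(condition, assay, timepoint_h, replicate) not jointly unique")
    }
  }
  invisible(x)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  kinds <- table(x$feature_kind)
  cat("feature kinds:", paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n")
  for (col in intersect(c("condition", "assay", "timepoint_h"), names(x$samples))) {
    cat(sprintf("%s: %s\n", col,
                paste(unique(as.character(x$samples[[col]])), collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by features and/or samples
#'
#' @param x A `count_matrix`.
#' @param i Feature index (logical, integer or feature ids).
#' @param j Sample index (logical, integer or sample ids).
#' @param ... Ignored.
#' @return A `count_matrix` restricted to the selected features/samples,
#'   with metadata kept in step with the columns.
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  ridx <- seq_len(nrow(x$counts))
  names(ridx) <- rownames(x$counts)
  cidx <- seq_len(ncol(x$counts))
  names(cidx) <- colnames(x$counts)
  i <- if (missing(i)) ridx else ridx[i]
  j <- if (missing(j)) cidx else cidx[j]
  if (anyNA(i)) stop("unknown feature id(s) in subset")
  if (anyNA(j)) stop("unknown sample id(s) in subset")
  counts <- x$counts[i, j, drop = FALSE]
  samples <- x$samples[j, , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples,
                 feature_kind = x$feature_kind[i]),
            class = "count_matrix")
}

#' Read a count matrix and its sample metadata from TSV files
#'
#' The count table is tab-separated with a header row of sample ids and the
#' first column holding feature ids; lines starting with `#` are ignored.
#' The metadata table is keyed by `sample_id`. Every sample column must have
#' a metadata row; counts must be non-negative integers.
#'
#' @param path Path to the count TSV.
#' @param meta_path Path to the metadata TSV.
#' @param feature_kind Feature kind(s) for the rows, or the name of a
#'   metadata-free column `feature_kind` present in the count file is not
#'   supported -- pass explicitly (default "gene").
#' @return A validated [count_matrix()].
#' @export
read_count_matrix <- function(path, meta_path, feature_kind = "gene") {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("count table needs a feature id column plus >= 1 sample")
  ids <- as.character(tab[[1]])
  has_kind <- "feature_kind" %in% names(tab)[-1]
  kind_col <- if (has_kind) as.character(tab[["feature_kind"]]) else NULL
  num <- tab[, setdiff(names(tab)[-1], "feature_kind"), drop = FALSE]
  mat <- as.matrix(num)
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(num, 2, as.numeric))), arr.ind = TRUE)
    stop(sprintf("non-numeric count at feature '%s', sample '%s'",
                 ids[bad[1, 1]], colnames(num)[bad[1, 2]]))
  }
  rownames(mat) <- ids
  meta <- utils::read.delim(meta_path, header = TRUE, sep = "\t",
                            comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE)
  meta <- meta[match(colnames(mat), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) {
    stop("no metadata row for sample(s): ",
         paste(setdiff(colnames(mat), meta$sample_id), collapse = ", "))
  }
  rownames(meta) <- NULL
  count_matrix(mat, meta, feature_kind = if (has_kind) kind_col else feature_kind)
}

#' Write a count matrix and metadata to TSV files
#'
#' Inverse of [read_count_matrix()]: `write` then `read` reproduces counts
#' and metadata exactly. A `feature_kind` column is appended when the matrix
#' mixes kinds (e.g. genes plus spike-ins).
#'
#' @param x A `count_matrix`.
#' @param path,meta_path Output paths (tab-separated).
#' @return `x`, invisibly.
#' @export
write_count_matrix <- function(x, path, meta_path) {
  validate_count_matrix(x)
  df <- data.frame(feature_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (length(unique(x$feature_kind)) > 1) df$feature_kind <- x$feature_kind
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Read an ERCC-style spike-in reference table
#'
#' @param path TSV with columns `spike_id` and `amount_attomole`.
#' @return Data frame with unique spike ids and strictly positive amounts.
#' @export
read_spikein_reference <- function(path) {
  ref <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("spike_id", "amount_attomole") %in% names(ref))) {
    stop("spike-in reference needs columns spike_id, amount_attomole")
  }
  if (anyDuplicated(ref$spike_id)) stop("duplicated spike_id in reference")
  if (any(!is.finite(ref$amount_attomole) | ref$amount_attomole <= 0)) {
    stop("spike-in amounts must be strictly positive")
  }
  ref
}
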
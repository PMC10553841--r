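#' Count matrix with sample metadata
#'
#' The central container for all count data: an integer matrix of
#' units x samples plus a sample-metadata table. Units are either genes or
#' `gene|feature` identifiers (the five mRNA features). Size factors, once
#' estimated, are carried along and obey the geometric-mean-1 convention.
#'
#' @param counts non-negative integer matrix; rownames are unit ids,
#'   colnames sample ids.
#' @param samples data.frame with at least `sample_id`; recognised columns
#'   are `assay` (ribo/rna/polysome_fraction/total_input), `condition`,
#'   `fraction` (sub/low/high/total/none), `replicate`, `spike_total`.
#' @param size_factors optional positive numeric vector, one per sample,
#'   geometric mean 1.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples, size_factors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have unit ids as rownames")
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample_id
  storage.mode(counts) <- "double"
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(samples)) stop("samples needs a sample_id column")
  if (!all(colnames(counts) == samples$sample_id))
    samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  if (any(is.na(samples$sample_id)))
    stop("sample metadata does not cover all count columns")
  for (col in c("assay", "condition", "fraction")) {
    if (!col %in% names(samples)) samples[[col]] <- NA_character_
  }
  if (!"replicate" %in% names(samples)) samples$replicate <- 1L
  obj <- structure(list(counts = counts, samples = samples,
                        size_factors = NULL), class = "count_matrix")
  if (!is.null(size_factors)) obj <- set_size_factors(obj, size_factors)
  obj
}

set_size_factors <- function(cm, sf) {
  sf <- as.numeric(sf)
  if (length(sf) != ncol(cm$counts)) stop("one size factor per sample required")
  if (any(!is.finite(sf)) || any(sf <= 0)) stop("size factors must be positive")
  if (abs(log(geomean(sf))) > 1e-9)
    sf <- sf / geomean(sf)
  cm$size_factors <- setNames(sf, colnames(cm$counts))
  cm
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d units x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  assays <- unique(x$samples$assay)
  cat("  assays:", paste(assays[!is.na(assays)], collapse = ", "), "\n")
  cat("  size factors:",
      if (is.null(x$size_factors)) "not estimated" else
        paste(signif(x$size_factors, 3), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by units and/or samples
#' @param x count_matrix
#' @param units character or logical selector of rows
#' @param samples character (sample ids) or logical selector of columns
#' @export
subset_cm <- function(x, units = NULL, samples = NULL) {
  if (!is.null(units)) {
    x$counts <- x$counts[units, , drop = FALSE]
  }
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, colnames(x$counts))
    x$counts <- x$counts[, samples, drop = FALSE]
    x$samples <- x$samples[samples, , drop = FALSE]
    if (!is.null(x$size_factors)) {
      sf <- x$size_factors[samples]
      x$size_factors <- sf / geomean(sf)
    }
  }
  x
}

#' Normalized counts
#'
#' Counts divided by per-sample size factors.
#' @param cm count_matrix with size factors estimated.
#' @return numeric matrix.
#' @export
normalized_counts <- function(cm) {
  if (is.null(cm$size_factors))
    stop("size factors not estimated; call estimate_size_factors() first")
  sweep(cm$counts, 2, cm$size_factors, "/")
}

#' Combine two count matrices column-wise
#' @keywords internal
cbind_cm <- function(a, b) {
  common <- intersect(rownames(a$counts), rownames(b$counts))
  counts <- cbind(a$counts[common, , drop = FALSE], b$counts[common, , drop = FALSE])
  cols <- union(names(a$samples), names(b$samples))
  fill <- function(s) { for (cc in setdiff(cols, names(s))) s[[cc]] <- NA; s[cols] }
  count_matrix(counts, rbind(fill(a$samples), fill(b$samples)))
}
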
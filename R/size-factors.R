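#' Estimate per-sample size factors
#'
#' Two estimators are provided. `median_of_ratios` is the standard
#' RNA-seq normalization: each sample's factor is the median, over units,
#' of the ratio of its count to the unit's geometric mean across samples
#' (units with a zero in any sample are excluded from the median).
#' `spike_in` derives factors from exogenous spike-in totals recorded in
#' the sample metadata, the appropriate choice for polysome fractions
#' where true mRNA content differs between samples. Factors are always
#' rescaled to geometric mean 1.
#'
#' @param cm a [count_matrix()].
#' @param method `"median_of_ratios"`, `"spike_in"`, or `"none"` (unit
#'   factors).
#' @return the count matrix with `size_factors` set.
#' @export
estimate_size_factors <- function(cm,
                                  method = c("median_of_ratios", "spike_in", "none")) {
  method <- match.arg(method)
  n <- ncol(cm$counts)
  if (method != "none" && n < 2) stop("need at least 2 samples")
  sf <- switch(method,
    none = rep(1, n),
    spike_in = {
      st <- cm$samples$spike_total
      if (is.null(st) || any(is.na(st)))
        stop("spike_in normalization requires spike_total for every sample")
      if (any(st <= 0)) stop("spike totals must be positive")
      st / geomean(st)
    },
    median_of_ratios = {
      loggeo <- rowMeans(log(cm$counts))
      use <- is.finite(loggeo)
      if (!any(use)) {
        warning("no unit has positive counts in all samples; ",
                "falling back to total-count ratios")
        tot <- colSums(cm$counts)
        tot / geomean(tot)
      } else {
        apply(cm$counts[use, , drop = FALSE], 2, function(cnt)
          exp(median(log(cnt) - loggeo[use])))
      }
    })
  cm <- set_size_factors(cm, sf)
  attr(cm$size_factors, "method") <- method
  cm
}

#' Nonspecific expression filter
#'
#' Removes units whose mean normalized count (baseMean) falls below a
#' threshold before differential testing. The threshold may be a single
#' number or a named vector keyed by feature class (the text after the
#' `|` in a `gene|feature` unit id), realizing a dynamic, per-feature
#' filtering policy.
#'
#' @param cm count_matrix with size factors estimated.
#' @param min_basemean scalar threshold, or named vector such as
#'   `c(utr5 = 5, cds = 10)`; units whose class is not named fall back to
#'   the unnamed/first element or 0.
#' @return filtered count_matrix.
#' @export
nonspecific_filter <- function(cm, min_basemean = 10) {
  bm <- rowMeans(normalized_counts(cm))
  ids <- rownames(cm$counts)
  if (length(min_basemean) == 1L && is.null(names(min_basemean))) {
    thr <- rep(min_basemean, length(ids))
  } else {
    cls <- ifelse(grepl("|", ids, fixed = TRUE), sub("^.*\\|", "", ids), "")
    default <- if (is.null(names(min_basemean))) min_basemean[1] else {
      unnamed <- min_basemean[names(min_basemean) == ""]
      if (length(unnamed)) unnamed[1] else 0
    }
    thr <- ifelse(cls %in% names(min_basemean), min_basemean[cls], default)
  }
  keep <- bm >= thr
  msg("nonspecific filter kept %d / %d units", sum(keep), length(keep))
  subset_cm(cm, units = keep)
}
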
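#' Spike-in normalization of polysome fraction counts
#'
#' Sets size factors from exogenous (e.g. Drosophila) spike-in totals
#' recorded in the sample metadata, correcting sample-to-sample
#' differences in RNA extraction/recovery that endogenous library-size
#' normalization cannot distinguish from genuine global shifts in
#' polysome-associated mRNA. A composite mode additionally folds in the
#' endogenous library size (the product of both factor sets, renormalized
#' to geometric mean 1).
#'
#' @param cm count_matrix whose samples carry `spike_total`.
#' @param composite also scale by endogenous total counts.
#' @return count_matrix with size factors set.
#' @export
spikein_normalize <- function(cm, composite = FALSE) {
  cm <- estimate_size_factors(cm, "spike_in")
  if (composite) {
    tot <- colSums(cm$counts)
    cm <- set_size_factors(cm, cm$size_factors * tot / geomean(tot))
  }
  cm
}

#' Subset a polysome count matrix to given gradient fractions
#'
#' @param cm polysome [count_matrix()].
#' @param fractions fraction labels to keep (sub/low/high/total).
#' @return the subset count_matrix.
#' @export
fractions_cm <- function(cm, fractions) {
  sel <- cm$samples$fraction %in% fractions
  if (!any(sel)) stop("no samples with fraction(s): ",
                      paste(fractions, collapse = ", "))
  subset_cm(cm, samples = sel)
}

# split one polysome cm into a per-fraction "assay" pair for the
# ratio-of-ratios machinery; spike factors are carried per sample.
polysome_pair <- function(cm, num_fraction, den_fraction, normalization) {
  num <- fractions_cm(cm, num_fraction)
  den <- fractions_cm(cm, den_fraction)
  norm1 <- function(x) {
    switch(normalization,
           spike = estimate_size_factors(x, "spike_in"),
           median_of_ratios = estimate_size_factors(x, "median_of_ratios"),
           none = estimate_size_factors(x, "none"))
  }
  list(num = norm1(num), den = norm1(den))
}

#' Differential polysome association: fraction relative to total mRNA
#'
#' Formulation (1): for one gradient fraction, tests per gene
#' `H0: log2(fraction/total | treated) - log2(fraction/total | untreated) = 0`
#' as an NB interaction between the fraction samples and the total-input
#' samples. Genes transcriptionally altered by the treatment should be
#' supplied in `exclude_genes` so only steady-state mRNAs are tested.
#'
#' @param cm polysome count_matrix (fractions sub/low/high plus total).
#' @param fraction `"sub"`, `"low"` or `"high"`.
#' @param contrast a [contrast_spec()].
#' @param exclude_genes genes removed before testing.
#' @param normalization `"spike"` (default), `"median_of_ratios"`, or
#'   `"none"` (raw counts; depth-matched libraries only).
#' @param alpha optional fixed dispersion.
#' @return `nb_diff` table.
#' @export
fraction_vs_total_contrast <- function(cm, fraction, contrast,
                                       exclude_genes = NULL,
                                       normalization = c("spike", "median_of_ratios", "none"),
                                       alpha = NULL) {
  normalization <- match.arg(normalization)
  if (!fraction %in% c("sub", "low", "high"))
    stop("fraction must be one of sub, low, high")
  pr <- polysome_pair(cm, fraction, "total", normalization)
  pr <- lapply(pr, function(x)
    subset_cm(x, units = !(rownames(x$counts) %in% exclude_genes)))
  nb_interaction_test(pr$num, pr$den,
                      contrast_spec(contrast$name, contrast$treated,
                                    contrast$untreated,
                                    assays = c(fraction, "total")),
                      unit_key = identity, alpha = alpha)
}

#' Differential polysome association: high-to-sub polysome ratio
#'
#' Formulation (2): tests per gene
#' `H0: log2(high/sub | treated) - log2(high/sub | untreated) = 0`,
#' the ratio-of-ratios contrast sensitive to shifts of mRNA between heavy
#' polysomes and sub-polysomal complexes (a translation-initiation
#' readout). Transcriptionally altered genes should be excluded.
#'
#' @inheritParams fraction_vs_total_contrast
#' @return `nb_diff` table.
#' @export
high_over_sub_contrast <- function(cm, contrast, exclude_genes = NULL,
                                   normalization = c("spike", "median_of_ratios", "none"),
                                   alpha = NULL) {
  normalization <- match.arg(normalization)
  pr <- polysome_pair(cm, "high", "sub", normalization)
  pr <- lapply(pr, function(x)
    subset_cm(x, units = !(rownames(x$counts) %in% exclude_genes)))
  nb_interaction_test(pr$num, pr$den,
                      contrast_spec(contrast$name, contrast$treated,
                                    contrast$untreated,
                                    assays = c("high", "sub")),
                      unit_key = identity, alpha = alpha)
}

#' Differential gene expression within the high polysome fraction
#'
#' Formulation (3): a simple NB contrast of high-polysome abundance
#' between conditions ("high/high"), with treatment-induced genes
#' retained — the translatome comparison that reveals which mRNAs the
#' treatment loads onto polysomes.
#'
#' @inheritParams fraction_vs_total_contrast
#' @return `nb_diff` table.
#' @export
high_fraction_dge <- function(cm, contrast,
                              normalization = c("spike", "median_of_ratios", "none"),
                              alpha = NULL) {
  normalization <- match.arg(normalization)
  high <- fractions_cm(cm, "high")
  high <- switch(normalization,
                 spike = estimate_size_factors(high, "spike_in"),
                 median_of_ratios = estimate_size_factors(high, "median_of_ratios"),
                 none = estimate_size_factors(high, "none"))
  nb_contrast(high, contrast, alpha = alpha)
}

#' Shift of a gene set's polysome association against a background
#'
#' Summarizes the log2FC distribution of a gene set (e.g. 5' TOP mRNAs)
#' against a background set and tests for a location shift with a
#' two-sided Mann-Whitney U test.
#'
#' @param results `nb_diff` table with gene unit ids.
#' @param gene_set character vector of gene ids (>= 5 with results).
#' @param background character vector; default all other tested genes.
#' @return list with per-group `n`, `median`, `iqr`, the MWU `statistic`
#'   and `p_value`.
#' @export
gene_set_shift <- function(results, gene_set, background = NULL) {
  ok <- !is.na(results$log2FC)
  in_set <- ok & results$unit_id %in% gene_set
  if (sum(in_set) < 5)
    stop("gene set has fewer than 5 members with results")
  if (is.null(background)) {
    in_bg <- ok & !results$unit_id %in% gene_set
  } else {
    in_bg <- ok & results$unit_id %in% setdiff(background, gene_set)
  }
  if (!any(in_bg)) stop("background has no members with results")
  vals <- list(set = results$log2FC[in_set], background = results$log2FC[in_bg])
  ts <- group_shift_test(vals, "mwu")
  list(n = lengths(vals),
       median = vapply(vals, median, numeric(1)),
       iqr = vapply(vals, function(v) unname(diff(quantile(v, c(.25, .75)))),
                    numeric(1)),
       statistic = ts$statistic, p_value = ts$p_value)
}
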
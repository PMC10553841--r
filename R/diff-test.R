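#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; missing values
#' propagate and do not count toward the number of tests.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  padj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  n <- sum(ok)
  if (n) {
    pp <- p[ok]
    o <- order(pp, decreasing = TRUE)
    padj[ok] <- pmin(1, cummin(n / (n:1) * pp[o]))[order(o)]
  }
  padj
}

#' Contrast specification
#'
#' Names the two condition labels (and the two assay/fraction labels for
#' ratio-of-ratios designs) a differential contrast compares.
#'
#' @param name short label for the contrast.
#' @param treated,untreated condition labels (numerator, denominator).
#' @param assays length-2 character: the numerator and denominator assay
#'   (or fraction) for an interaction contrast, e.g. `c("ribo", "rna")`
#'   or `c("high", "sub")`. Ignored for simple contrasts.
#' @param type `"interaction"` (ratio of ratios) or `"simple"`.
#' @export
contrast_spec <- function(name, treated, untreated,
                          assays = c("ribo", "rna"),
                          type = c("interaction", "simple")) {
  type <- match.arg(type)
  if (type == "interaction" && length(assays) != 2)
    stop("interaction contrasts reference exactly 2 assays")
  structure(list(name = name, treated = treated, untreated = untreated,
                 assays = assays, type = type), class = "contrast_spec")
}

# Shared engine for ratio-of-ratios (interaction) NB tests between two
# count matrices whose samples represent the two "assays" of the design.
# Units must be matchable 1:1 after applying `unit_key` to the numerator
# matrix row names (gene|feature -> gene for the TE test).
nb_interaction_test <- function(num_cm, den_cm, contrast,
                                unit_key = function(x) sub("\\|.*$", "", x),
                                alpha = NULL) {
  num_cm <- subset_cm(num_cm, samples = num_cm$samples$condition %in%
                        c(contrast$treated, contrast$untreated))
  den_cm <- subset_cm(den_cm, samples = den_cm$samples$condition %in%
                        c(contrast$treated, contrast$untreated))
  if (is.null(num_cm$size_factors)) num_cm <- estimate_size_factors(num_cm)
  if (is.null(den_cm$size_factors)) den_cm <- estimate_size_factors(den_cm)

  genes_num <- unit_key(rownames(num_cm$counts))
  genes_den <- rownames(den_cm$counts)
  common <- intersect(genes_num, genes_den)
  dropped <- sum(!(genes_num %in% common)) + sum(!(genes_den %in% common))
  if (dropped) msg("%d units absent from one assay excluded", dropped)
  keep_num <- genes_num %in% common
  num_cm <- subset_cm(num_cm, units = keep_num)
  genes_num <- genes_num[keep_num]

  counts <- cbind(num_cm$counts,
                  den_cm$counts[genes_num, , drop = FALSE])
  colnames(counts) <- c(colnames(num_cm$counts), colnames(den_cm$counts))
  sf <- c(num_cm$size_factors, den_cm$size_factors)
  assay <- factor(rep(c("num", "den"),
                      c(ncol(num_cm$counts), ncol(den_cm$counts))),
                  levels = c("den", "num"))
  condition <- factor(c(num_cm$samples$condition, den_cm$samples$condition),
                      levels = c(contrast$untreated, contrast$treated))
  design <- model.matrix(~ assay + condition + assay:condition)
  coef_name <- colnames(design)[4]

  if (is.null(alpha)) {
    tmp <- count_matrix(counts,
                        data.frame(sample_id = colnames(counts),
                                   assay = as.character(assay),
                                   condition = as.character(condition)))
    tmp <- set_size_factors(tmp, sf / geomean(sf))
    alpha <- estimate_dispersion(tmp, groups = interaction(assay, condition))
  } else if (length(alpha) == 1L) {
    alpha <- rep(alpha, nrow(counts))
  }
  tab <- nb_wald_table(counts, design, sf, alpha, coef_name)
  tab$unit_id <- rownames(num_cm$counts)
  new_nb_diff(tab, contrast$name, "interaction")
}

#' Differential translation efficiency by NB interaction test
#'
#' Tests, per unit, the null hypothesis that the treated/untreated count
#' ratio is the same in Ribo-seq as in RNA-seq:
#' `H0: log2(treated/untreated | ribo) - log2(treated/untreated | rna) = 0`.
#' Both assays enter a joint NB GLM with design
#' `~ assay + condition + assay:condition` and per-assay size-factor
#' offsets; the interaction coefficient is the log2 change in translation
#' efficiency and is tested by Wald statistic with BH adjustment.
#'
#' Ribo-seq units may be feature-level (`gene|feature`); they are matched
#' to RNA-seq gene units by the gene part of the id.
#'
#' @param ribo_cm,rna_cm [count_matrix()] objects for the two assays.
#' @param contrast a [contrast_spec()] naming treated/untreated conditions.
#' @param alpha optional fixed dispersion (scalar or per-unit); estimated
#'   from the joint matrix when NULL.
#' @return an `nb_diff` data frame (unit_id, baseMean, log2FC, SE,
#'   wald_stat, p, padj).
#' @export
test_te_interaction <- function(ribo_cm, rna_cm, contrast, alpha = NULL) {
  nb_interaction_test(ribo_cm, rna_cm, contrast, alpha = alpha)
}

#' Run the TE interaction test independently for each mRNA feature
#'
#' Splits a feature-level Ribo-seq count matrix by feature class and runs
#' [test_te_interaction()] (with its own filtering and BH adjustment)
#' within each of the five features.
#'
#' @param ribo_cm feature-level count matrix (`gene|feature` units).
#' @param rna_cm gene-level RNA-seq count matrix.
#' @param contrast a [contrast_spec()].
#' @param min_basemean per-feature nonspecific filter threshold (scalar or
#'   named by feature).
#' @param exclude_genes genes (e.g. DUX4- or IFNg-altered) removed before
#'   testing.
#' @param alpha optional fixed dispersion.
#' @return named list of `nb_diff` tables, one per feature class.
#' @export
te_tests_by_feature <- function(ribo_cm, rna_cm, contrast,
                                min_basemean = 10, exclude_genes = NULL,
                                alpha = NULL) {
  ids <- rownames(ribo_cm$counts)
  feat <- sub("^.*\\|", "", ids)
  gene <- sub("\\|.*$", "", ids)
  keep <- !(gene %in% exclude_genes)
  ribo_cm <- subset_cm(ribo_cm, units = keep)
  feat <- feat[keep]
  if (!is.null(exclude_genes)) {
    rna_keep <- !(rownames(rna_cm$counts) %in% exclude_genes)
    rna_cm <- subset_cm(rna_cm, units = rna_keep)
  }
  res <- list()
  for (f in unique(feat)) {
    sub <- subset_cm(ribo_cm, units = feat == f)
    sub <- estimate_size_factors(sub)
    thr <- if (length(min_basemean) > 1 && f %in% names(min_basemean))
      min_basemean[[f]] else if (is.null(names(min_basemean)))
        min_basemean[1] else 0
    sub <- nonspecific_filter(sub, thr)
    if (!nrow(sub$counts)) next
    res[[f]] <- test_te_interaction(sub, rna_cm, contrast, alpha = alpha)
  }
  res
}

#' Simple two-condition NB contrast
#'
#' Ordinary differential abundance between two conditions within one
#' assay: design `~ condition`, Wald test on the condition coefficient.
#'
#' @param cm count_matrix containing samples of both conditions.
#' @param contrast a [contrast_spec()] (type `"simple"`).
#' @param alpha optional fixed dispersion.
#' @return `nb_diff` table.
#' @export
nb_contrast <- function(cm, contrast, alpha = NULL) {
  cm <- subset_cm(cm, samples = cm$samples$condition %in%
                    c(contrast$treated, contrast$untreated))
  if (is.null(cm$size_factors)) cm <- estimate_size_factors(cm)
  condition <- factor(cm$samples$condition,
                      levels = c(contrast$untreated, contrast$treated))
  design <- model.matrix(~ condition)
  if (is.null(alpha)) {
    alpha <- estimate_dispersion(cm, groups = condition)
  } else if (length(alpha) == 1L) alpha <- rep(alpha, nrow(cm$counts))
  tab <- nb_wald_table(cm$counts, design, cm$size_factors, alpha,
                       colnames(design)[2])
  new_nb_diff(tab, contrast$name, "simple")
}

#' Classify condition-altered genes from RNA-level results
#'
#' Genes whose RNA abundance changed between conditions
#' (`|log2FC| > lfc_thresh` and `padj < padj_thresh`, strict
#' inequalities); used to exclude transcriptionally perturbed genes from
#' steady-state translational analyses.
#'
#' @param rna_results an `nb_diff` table from an RNA-level contrast.
#' @param lfc_thresh,padj_thresh thresholds (strict).
#' @return character vector of gene ids.
#' @export
classify_altered_genes <- function(rna_results, lfc_thresh = 1,
                                   padj_thresh = 0.05) {
  ok <- !is.na(rna_results$padj) & !is.na(rna_results$log2FC)
  alt <- ok & abs(rna_results$log2FC) > lfc_thresh &
    rna_results$padj < padj_thresh
  rna_results$unit_id[alt]
}

#' Compare distributions of per-feature changes between groups
#'
#' One-way ANOVA across feature groups (as used for box-plot comparisons
#' of feature-level log2 changes) or a two-sided Mann-Whitney U test for
#' two groups.
#'
#' @param values_by_group named list of numeric vectors.
#' @param test `"anova"` or `"mwu"`.
#' @return list with `statistic`, `p_value`, `method` and per-group
#'   `medians`.
#' @export
group_shift_test <- function(values_by_group, test = c("anova", "mwu")) {
  test <- match.arg(test)
  values_by_group <- lapply(values_by_group, function(v) v[!is.na(v)])
  lens <- lengths(values_by_group)
  meds <- vapply(values_by_group, median, numeric(1))
  all_vals <- unlist(values_by_group, use.names = FALSE)
  if (length(unique(all_vals)) == 1L) {
    warning("all values identical; test degenerate")
    return(list(statistic = NA_real_, p_value = 1,
                method = test, medians = meds))
  }
  if (test == "anova") {
    if (length(values_by_group) < 2 || any(lens < 2))
      stop("anova needs >= 2 groups with >= 2 values each")
    g <- factor(rep(names(values_by_group), lens))
    ft <- oneway.test(all_vals ~ g, var.equal = TRUE)
    list(statistic = unname(ft$statistic), p_value = ft$p.value,
         method = "one-way ANOVA", medians = meds)
  } else {
    if (length(values_by_group) != 2)
      stop("Mann-Whitney test needs exactly 2 groups")
    wt <- wilcox.test(values_by_group[[1]], values_by_group[[2]],
                      alternative = "two.sided")
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         method = "Mann-Whitney U", medians = meds)
  }
}
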
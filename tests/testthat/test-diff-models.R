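mk_cm <- function(counts, condition, assay = "rna", spike = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("u%03d", seq_len(nrow(counts)))
  colnames(counts) <- paste0(assay, "_s", seq_len(ncol(counts)))
  samples <- data.frame(sample_id = colnames(counts), assay = assay,
                        condition = condition, stringsAsFactors = FALSE)
  if (!is.null(spike)) samples$spike_total <- spike
  count_matrix(counts, samples)
}

test_that("BH adjustment matches closed forms and the reference implementation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.01, 0.04, 0.9)), c(0.03, 0.06, 0.9))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(bh_adjust(c(0.2, NA, 0.01)), c(0.2, NA, 0.02))

  set.seed(17)
  for (i in 1:100) {
    p <- runif(sample(5:200, 1))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("size factor estimators satisfy their closed forms", {
  c1 <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2)
  cm <- estimate_size_factors(mk_cm(c1, c("a", "b")))
  expect_equal(as.numeric(cm$size_factors), c(1 / sqrt(2), sqrt(2)))

  cm2 <- estimate_size_factors(
    mk_cm(matrix(c(100, 100), 1), c("a", "b"), spike = c(1e6, 2e6)), "spike_in")
  expect_equal(as.numeric(cm2$size_factors), c(1 / sqrt(2), sqrt(2)))
  expect_equal(unname(normalized_counts(cm2)[1, ]),
               c(100 * sqrt(2), 100 / sqrt(2)), tolerance = 1e-9)

  cm3 <- estimate_size_factors(mk_cm(c1[, c(1, 1)], c("a", "b")))
  expect_equal(as.numeric(cm3$size_factors), c(1, 1))

  expect_error(estimate_size_factors(mk_cm(c1, c("a", "b")), "spike_in"),
               "spike_total")
  # geometric mean-1 convention
  expect_equal(exp(mean(log(cm$size_factors))), 1, tolerance = 1e-9)
})

test_that("the nonspecific filter applies scalar and per-class thresholds", {
  counts <- matrix(c(0, 10, 100, 1, 10, 100), ncol = 2)
  rownames(counts) <- c("g1|utr5", "g2|utr5", "g3|cds")
  cm <- estimate_size_factors(mk_cm(counts, c("a", "b")), "none")
  suppressMessages({
    expect_equal(nrow(nonspecific_filter(cm, 10)$counts), 2L)
    expect_equal(nrow(nonspecific_filter(cm, 0)$counts), 3L)
    kept <- nonspecific_filter(cm, c(utr5 = 5, cds = 150))
  })
  expect_equal(rownames(kept$counts), "g2|utr5")
})

test_that("dispersion estimation is calibrated on known generators", {
  set.seed(23)
  n <- 600
  mu <- rep(c(50, 200, 800), length.out = n)
  pois <- t(vapply(mu, function(m) rpois(6, m), numeric(6)))
  rownames(pois) <- sprintf("u%03d", 1:n)
  cm <- estimate_size_factors(mk_cm(pois, rep(c("a", "b"), each = 3)), "none")
  a_hat <- estimate_dispersion(cm)
  expect_gt(mean(a_hat[mu >= 50] <= 0.01), 0.95)

  nb <- t(vapply(rep(200, n), function(m)
    rpois(6, m * rgamma(6, shape = 10, rate = 10)), numeric(6)))
  rownames(nb) <- sprintf("u%03d", 1:n)
  cm2 <- estimate_size_factors(mk_cm(nb, rep(c("a", "b"), each = 3)), "none")
  a2 <- estimate_dispersion(cm2)
  expect_gt(median(a2), 0.05)
  expect_lt(median(a2), 0.2)

  const <- matrix(100, nrow = 30, ncol = 6)
  rownames(const) <- sprintf("u%03d", 1:30)
  cm3 <- estimate_size_factors(mk_cm(const, rep(c("a", "b"), each = 3)), "none")
  a3 <- estimate_dispersion(cm3)
  expect_true(all(a3 <= 1e-6))
})

test_that("the NB GLM reproduces saturated closed forms and flags degenerate fits", {
  design <- cbind(1, rep(c(0, 1), each = 3))
  colnames(design) <- c("i", "grp")
  f <- fit_nb_glm(c(100, 100, 100, 200, 200, 200), design, rep(1, 6), 1e-10)
  expect_equal(unname(f$log2_coef["grp"]), 1, tolerance = 1e-9)

  f0 <- fit_nb_glm(rep(0L, 6), design, rep(1, 6), 0.05)
  expect_false(f0$converged)
  expect_true(all(is.na(f0$coef)))
})

test_that("NB GLM estimates a planted two-group fold change accurately", {
  set.seed(29)
  design <- cbind(1, rep(c(0, 1), each = 3))
  colnames(design) <- c("i", "grp")
  hits <- replicate(200, {
    y <- rpois(6, c(rep(500, 3), rep(1000, 3)) *
                 rgamma(6, shape = 100, rate = 100))
    f <- fit_nb_glm(y, design, rep(1, 6), 0.01)
    abs(f$log2_coef["grp"] - 1) < 0.3
  })
  expect_gte(mean(hits), 0.9)
})

test_that("the TE interaction test equals the ratio of ratios for saturated designs", {
  ribo <- mk_cm(matrix(c(200, 200, 200, 100, 100, 100), 1),
                rep(c("untr", "tr"), each = 3), assay = "ribo")
  rna <- mk_cm(matrix(rep(100, 6), 1), rep(c("untr", "tr"), each = 3))
  ribo$size_factors <- setNames(rep(1, 6), colnames(ribo$counts))
  rna$size_factors <- setNames(rep(1, 6), colnames(rna$counts))
  res <- test_te_interaction(ribo, rna, contrast_spec("te", "tr", "untr"),
                             alpha = 1e-10)
  expect_equal(res$log2FC, -1, tolerance = 1e-9)

  # both assays change identically: the H0 case
  ribo2 <- mk_cm(matrix(c(100, 100, 100, 200, 200, 200), 1),
                 rep(c("untr", "tr"), each = 3), assay = "ribo")
  rna2 <- mk_cm(matrix(c(50, 50, 50, 100, 100, 100), 1),
                rep(c("untr", "tr"), each = 3))
  ribo2$size_factors <- setNames(rep(1, 6), colnames(ribo2$counts))
  rna2$size_factors <- setNames(rep(1, 6), colnames(rna2$counts))
  res2 <- test_te_interaction(ribo2, rna2, contrast_spec("te", "tr", "untr"),
                              alpha = 1e-10)
  expect_equal(res2$log2FC, 0, tolerance = 1e-9)
})

test_that("label swap negates log2FC and preserves p-values", {
  s <- simulate_te_counts(n_units = 150, alpha = 0.02, seed = 31)
  fwd <- test_te_interaction(s$ribo, s$rna,
                             contrast_spec("f", "DUX4_pulse_IFNg", "IFNg"))
  rev <- test_te_interaction(s$ribo, s$rna,
                             contrast_spec("r", "IFNg", "DUX4_pulse_IFNg"))
  ok <- !is.na(fwd$log2FC) & !is.na(rev$log2FC)
  expect_gt(sum(ok), 100)
  expect_equal(fwd$log2FC[ok], -rev$log2FC[ok], tolerance = 1e-6)
  expect_equal(fwd$p[ok], rev$p[ok], tolerance = 1e-6)
})

test_that("scaling one sample's counts is absorbed by its size factor", {
  s <- simulate_te_counts(n_units = 150, alpha = 0.02, seed = 37)
  base <- test_te_interaction(s$ribo, s$rna,
                              contrast_spec("f", "DUX4_pulse_IFNg", "IFNg"))
  scaled <- s
  scaled$ribo$counts[, 1] <- scaled$ribo$counts[, 1] * 4L
  # normalized counts are invariant up to one global constant (the
  # geometric-mean-1 convention re-anchors the scale)
  a <- estimate_size_factors(s$ribo)
  b <- estimate_size_factors(scaled$ribo)
  r <- normalized_counts(b) / normalized_counts(a)
  r <- r[is.finite(r)]
  expect_lt(diff(range(r)), 1e-9)
  # estimates and p-values are invariant up to the change in the sample's
  # likelihood weight (raw counts carry the information)
  res <- test_te_interaction(scaled$ribo, scaled$rna,
                             contrast_spec("f", "DUX4_pulse_IFNg", "IFNg"))
  ok <- !is.na(base$log2FC) & !is.na(res$log2FC)
  expect_lt(median(abs(base$log2FC[ok] - res$log2FC[ok])), 0.05)
  expect_gt(cor(base$log2FC[ok], res$log2FC[ok]), 0.995)
})

test_that("altered-gene classification uses strict thresholds", {
  res <- data.frame(unit_id = c("a", "b", "c"),
                    log2FC = c(1.5, 1.0, -2),
                    padj = c(0.01, 0.01, 0.2))
  expect_equal(classify_altered_genes(res), "a")
})

test_that("group shift tests match exact and algebraic references", {
  mwu <- group_shift_test(list(a = c(1, 2, 3), b = c(4, 5, 6)), "mwu")
  expect_equal(mwu$statistic, 0)
  expect_equal(mwu$p_value, 0.1)

  set.seed(41)
  x <- rnorm(12); y <- rnorm(12, 0.5)
  an <- group_shift_test(list(x = x, y = y), "anova")
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(an$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(an$p_value, tt$p.value, tolerance = 1e-9)

  expect_warning(deg <- group_shift_test(list(a = rep(1, 3), b = rep(1, 3)),
                                         "anova"), "identical")
  expect_equal(deg$p_value, 1)
})

test_that("anova on permuted identical groups is null-calibrated", {
  set.seed(43)
  v <- rnorm(30)
  ps <- replicate(300, {
    perm <- sample(v)
    group_shift_test(list(a = perm[1:10], b = perm[11:20], c = perm[21:30]),
                     "anova")$p_value
  })
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("simple NB contrasts agree with an independent reference implementation", {
  set.seed(47)
  n <- 150
  mu <- rlnorm(n, log(400), 0.7)
  lfc <- sample(c(0, 1, -1), n, replace = TRUE, prob = c(0.7, 0.15, 0.15))
  counts <- t(vapply(seq_len(n), function(i)
    rpois(6, mu[i] * 2^(lfc[i] * rep(c(0, 1), each = 3)) *
            rgamma(6, 50, 50)), numeric(6)))
  mode(counts) <- "integer"
  rownames(counts) <- sprintf("u%03d", seq_len(n))
  cm <- mk_cm(counts, rep(c("ctrl", "trt"), each = 3))
  ours <- nb_contrast(cm, contrast_spec("x", "trt", "ctrl"))

  dds <- DESeq2::DESeqDataSetFromMatrix(
    counts, data.frame(condition = factor(rep(c("ctrl", "trt"), each = 3))),
    ~ condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds, contrast = c("condition", "trt", "ctrl"))
  common <- intersect(ours$unit_id, rownames(ref))
  d <- ours$log2FC[match(common, ours$unit_id)] - ref[common, "log2FoldChange"]
  expect_lt(median(abs(d), na.rm = TRUE), 0.05)
  expect_gt(cor(ours$log2FC[match(common, ours$unit_id)],
                ref[common, "log2FoldChange"], use = "complete.obs"), 0.98)
})
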
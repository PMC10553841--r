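# In-code fixtures shared across test files.

# hand-built transcript: + strand, single exon at [100, 200), CDS [130, 190)
tiny_tx_plus <- function() {
  structure(list(
    transcript_id = "txP", gene_id = "gP", chrom = "chrT", strand = "+",
    exons = cbind(start = 100L, end = 200L),
    cds_start_tx = 30L, cds_end_tx = 90L,
    sequence = paste(rep("A", 100), collapse = ""),
    utr5_source = "annotated"), class = "transcript_model")
}

# a random coding transcript with given structure, for property tests
random_tx <- function(L = NULL, utr5 = NULL, cds = NULL, n_exons = NULL) {
  utr5 <- utr5 %||% sample(5:80, 1)
  cds <- cds %||% (3 * sample(20:120, 1))
  utr3 <- sample(10:120, 1)
  L <- utr5 + cds + utr3
  n_exons <- n_exons %||% sample(1:4, 1)
  cuts <- if (n_exons > 1) sort(sample(seq_len(L - 1), n_exons - 1)) else integer(0)
  bounds <- c(0L, cuts, L)
  widths <- diff(bounds)
  strand <- sample(c("+", "-"), 1)
  # genomic layout with random introns
  introns <- if (n_exons > 1) sample(30:200, n_exons - 1, replace = TRUE) else integer(0)
  gw <- if (strand == "-") rev(widths) else widths
  starts <- cumsum(c(50L, head(gw, -1) + introns))
  exons <- cbind(start = starts, end = starts + gw)
  structure(list(
    transcript_id = "txR", gene_id = "gR", chrom = "chrR", strand = strand,
    exons = exons, cds_start_tx = as.integer(utr5),
    cds_end_tx = as.integer(utr5 + cds),
    sequence = paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                     collapse = ""),
    utr5_source = "annotated"), class = "transcript_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force MFE over all pseudoknot-free structures (loop >= min_loop)
brute_force_mfe <- function(seq, min_loop = 3, wobble = TRUE) {
  s <- strsplit(seq, "")[[1]]
  pe <- function(a, b) {
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(-3)
    if ((a == "A" && b == "U") || (a == "U" && b == "A")) return(-2)
    if (wobble && ((a == "G" && b == "U") || (a == "U" && b == "G"))) return(-1)
    NA_real_
  }
  n <- length(s)
  best <- 0
  rec <- function(i, j) {
    # min energy on [i, j] by exhaustive recursion (memo-free; n <= 12)
    if (j - i <= min_loop) return(0)
    e <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      pk <- pe(s[i], s[k])
      if (is.na(pk)) next
      inner <- if (k - i > min_loop + 1) rec(i + 1, k - 1) else 0
      outer <- if (k < j) rec(k + 1, j) else 0
      e <- min(e, pk + inner + outer)
    }
    e
  }
  if (n <= min_loop + 1) return(0)
  rec(1, n)
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                collapse = "")

# deterministic 2x2 saturated polysome-style count matrix builder
saturated_cm <- function(means, conditions, fraction, n_rep = 3,
                         assay = "polysome_fraction") {
  samples <- data.frame(
    sample_id = sprintf("%s_%s_r%d", rep(conditions, each = n_rep), fraction,
                        rep(seq_len(n_rep), 2)),
    assay = assay, condition = rep(conditions, each = n_rep),
    fraction = fraction, replicate = rep(seq_len(n_rep), 2),
    spike_total = 1e6, stringsAsFactors = FALSE)
  counts <- matrix(c(rep(means[1], n_rep), rep(means[2], n_rep)), 1)
  rownames(counts) <- "gA"
  colnames(counts) <- samples$sample_id
  count_matrix(counts, samples, size_factors = rep(1, 2 * n_rep))
}

# deterministic polysome count matrix with exact cell means
exact_poly_cm <- function(means, n_rep = 3,
                          conditions = c("IFNg", "DUX4_pulse_IFNg")) {
  # means: named list fraction -> c(untreated, treated)
  fractions <- names(means)
  samples <- expand.grid(replicate = seq_len(n_rep), fraction = fractions,
                         condition = conditions, stringsAsFactors = FALSE)
  samples$assay <- ifelse(samples$fraction == "total", "total_input",
                          "polysome_fraction")
  samples$sample_id <- sprintf("%s_%s_r%d", samples$condition,
                               samples$fraction, samples$replicate)
  samples$spike_total <- 1e6
  counts <- vapply(seq_len(nrow(samples)), function(i) {
    m <- means[[samples$fraction[i]]]
    if (samples$condition[i] == conditions[1]) m[1] else m[2]
  }, numeric(1))
  counts <- matrix(counts, nrow = 1)
  rownames(counts) <- "gA"
  colnames(counts) <- samples$sample_id
  count_matrix(counts, samples)
}

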
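#' Define the planted truth of a synthetic translational-profiling study
#'
#' Draws per-gene classes, expression levels and planted effects for a
#' two-condition (control vs. pulse) study emulating a burst of a
#' transcription factor that suppresses translation initiation:
#'
#' * `te_affected` genes carry a planted translation-efficiency drop
#'   (`dte` log2 units) concentrated at the 5' end of the CDS-proximal
#'   region (5'UTR and the first `dte_cds_nt` nt of CDS);
#' * `dux4_target` genes are transcriptionally induced in the pulse
#'   condition and polysome-loaded (`dux4_induced` polysome mode);
#' * `top` genes (TOP-mRNA-like) retain polysome association;
#' * a fraction of the remaining genes is `initiation_blocked` in the
#'   pulse condition (high-to-sub polysome ratio scaled by
#'   `2^init_block_lfc`) and a small fraction `elongation_stalled`
#'   (polysome-retained).
#'
#' @param n_genes number of genes (>= 10).
#' @param seed RNG seed; the truth (and everything generated from it) is
#'   byte-identical for a fixed seed.
#' @param frac_te_affected fraction of genes with the planted TE drop.
#' @param dte planted log2 TE change at 5' features.
#' @param dte_cds_nt nt of CDS (from the start codon) sharing the drop.
#' @param frac_top,frac_dux4 gene-class fractions.
#' @param frac_init_block,frac_elong_stall polysome-mode fractions among
#'   remaining genes.
#' @param init_block_lfc planted log2 change of the high/sub ratio for
#'   initiation-blocked genes.
#' @param alpha NB dispersion shared across genes.
#' @param frame_fidelity probability that a CDS P-site falls in frame 0
#'   (the remainder splits 2:1 between frames 1 and 2).
#' @param psite_offset true 5'-end-to-P-site offset used to emit reads.
#' @param extraction_multiplier RNA extraction-efficiency multiplier of
#'   the pulse condition relative to control (encoded in the spike-in
#'   totals of the polysome design).
#' @param dux4_lfc transcriptional log2FC of target genes in the pulse.
#' @param expression_sdlog log-normal sd of relative expression.
#' @return a `simulation_truth` list: `genes` data.frame, `params`, `seed`.
#' @export
simulation_truth <- function(n_genes = 2000, seed = 1,
                             frac_te_affected = 0.2, dte = -2,
                             dte_cds_nt = 39,
                             frac_top = 0.05, frac_dux4 = 0.035,
                             frac_init_block = 0.3, frac_elong_stall = 0.05,
                             init_block_lfc = -2,
                             alpha = 0.02, frame_fidelity = 0.85,
                             psite_offset = 12,
                             extraction_multiplier = 2,
                             dux4_lfc = 4, expression_sdlog = 1) {
  stopifnot(n_genes >= 10)
  set_sim_seed(seed)
  gene_id <- sprintf("g%04d", seq_len(n_genes))
  class <- rep("normal", n_genes)
  n_top <- round(frac_top * n_genes)
  n_dux <- round(frac_dux4 * n_genes)
  class[seq_len(n_top)] <- "top"
  class[n_top + seq_len(n_dux)] <- "dux4_target"
  class <- sample(class)  # shuffle assignments over gene ids

  mode <- rep("normal", n_genes)
  mode[class == "dux4_target"] <- "dux4_induced"
  free <- which(class == "normal")
  n_ib <- round(frac_init_block * length(free))
  n_es <- round(frac_elong_stall * length(free))
  picked <- sample(free, n_ib + n_es)
  mode[picked[seq_len(n_ib)]] <- "initiation_blocked"
  if (n_es) mode[picked[n_ib + seq_len(n_es)]] <- "elongation_stalled"

  te_affected <- rep(FALSE, n_genes)
  eligible <- which(class != "dux4_target")
  te_affected[sample(eligible, round(frac_te_affected * n_genes))] <- TRUE

  genes <- data.frame(
    gene_id = gene_id, class = class, polysome_mode = mode,
    te_affected = te_affected,
    expression = rlnorm(n_genes, meanlog = 0, sdlog = expression_sdlog),
    transcriptional_lfc = ifelse(class == "dux4_target", dux4_lfc, 0),
    dte = ifelse(te_affected, dte, 0),
    stringsAsFactors = FALSE)
  structure(list(genes = genes,
                 params = list(frac_te_affected = frac_te_affected,
                               dte = dte, dte_cds_nt = dte_cds_nt,
                               init_block_lfc = init_block_lfc,
                               alpha = alpha,
                               frame_fidelity = frame_fidelity,
                               psite_offset = psite_offset,
                               extraction_multiplier = extraction_multiplier,
                               dux4_lfc = dux4_lfc),
                 seed = seed),
            class = "simulation_truth")
}

#' Serialize / restore a simulation truth
#' @param truth a `simulation_truth`.
#' @param path JSON file path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "simulation_truth")
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a synthetic transcriptome matching a simulation truth
#'
#' Builds coding transcripts (one per gene, 1-4 exons, both strands) with
#' log-normal UTR/CDS lengths. 5'UTR base composition follows gene class:
#' target-like genes get AU-rich 5'UTRs, initiation-blocked ("repressed")
#' genes GC-rich ones, so that structure analysis has a planted
#' composition difference. With `outdir` set, writes `annotation.gtf`,
#' `genome.fa` and `gene_classes.tsv`; the files round-trip through
#' [parse_annotation()].
#'
#' @param truth a [simulation_truth()].
#' @param outdir optional output directory for GTF/FASTA/class table.
#' @param length_params list with `utr5_meanlog/sdlog`,
#'   `codons_meanlog/sdlog`, `utr3_meanlog/sdlog`.
#' @param gc_params named GC targets per class
#'   (`dux4_target`, `repressed`, `normal`).
#' @param seed RNG seed for sequence generation.
#' @return a `transcript_set` (invisibly also written to `outdir`).
#' @export
generate_transcriptome <- function(truth, outdir = NULL,
                                   length_params = list(
                                     utr5_meanlog = log(120), utr5_sdlog = 0.45,
                                     codons_meanlog = log(200), codons_sdlog = 0.5,
                                     utr3_meanlog = log(200), utr3_sdlog = 0.6),
                                   gc_params = c(dux4_target = 0.3,
                                                 repressed = 0.7,
                                                 normal = 0.5),
                                   seed = truth$seed + 1000L) {
  set_sim_seed(seed)
  g <- truth$genes
  n <- nrow(g)
  lp <- length_params
  utr5_len <- pmin(pmax(round(rlnorm(n, lp$utr5_meanlog, lp$utr5_sdlog)), 10), 400)
  codons <- pmin(pmax(round(rlnorm(n, lp$codons_meanlog, lp$codons_sdlog)), 40), 600)
  cds_len <- 3L * codons + 3L
  utr3_len <- pmin(pmax(round(rlnorm(n, lp$utr3_meanlog, lp$utr3_sdlog)), 30), 600)
  gc_class <- ifelse(g$class == "dux4_target", gc_params["dux4_target"],
                     ifelse(g$polysome_mode == "initiation_blocked",
                            gc_params["repressed"], gc_params["normal"]))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  n_exons <- sample(1:4, n, replace = TRUE)
  chroms <- paste0("chr", (seq_len(n) - 1L) %% 4 + 1L)

  txs <- list()
  chrom_parts <- list(chr1 = list(), chr2 = list(), chr3 = list(), chr4 = list())
  chrom_pos <- c(chr1 = 0L, chr2 = 0L, chr3 = 0L, chr4 = 0L)
  gtf <- character(0)

  for (i in seq_len(n)) {
    L <- utr5_len[i] + cds_len[i] + utr3_len[i]
    seq <- paste0(random_dna(utr5_len[i], gc_class[i]),
                  "ATG", random_dna(cds_len[i] - 6L, 0.5), "TAA",
                  random_dna(utr3_len[i], 0.5))
    cds_s <- as.integer(utr5_len[i])
    cds_e <- as.integer(utr5_len[i] + cds_len[i])

    # split into exons (each >= 20 nt)
    k <- n_exons[i]
    if (k > 1 && L >= 20 * k) {
      cuts <- sort(sample(seq(20L, L - 20L), k - 1))
      cuts <- cuts[c(TRUE, diff(cuts) >= 20)]
    } else cuts <- integer(0)
    bounds <- c(0L, cuts, L)
    widths <- diff(bounds)
    k <- length(widths)
    introns <- if (k > 1) sample(50:500, k - 1, replace = TRUE) else integer(0)

    # genomic layout on the chromosome
    chrom <- chroms[i]
    gap <- sample(100:1000, 1)
    gstart <- chrom_pos[chrom] + gap
    pieces_tx <- substring(seq, bounds[-length(bounds)] + 1L, bounds[-1])
    if (strand[i] == "+") {
      gpieces <- pieces_tx
    } else {
      gpieces <- rev(vapply(pieces_tx, revcomp_chr, character(1)))
      widths <- rev(widths)
    }
    exon_g <- matrix(0L, nrow = k, ncol = 2)
    widths <- as.integer(widths)
    pos <- as.integer(gstart)
    region <- character(0)
    for (e in seq_len(k)) {
      exon_g[e, ] <- c(pos, pos + widths[e])
      region <- c(region, gpieces[e])
      pos <- pos + widths[e]
      if (e < k) {
        region <- c(region, random_dna(introns[e], 0.4))
        pos <- pos + introns[e]
      }
    }
    chrom_parts[[chrom]] <- c(chrom_parts[[chrom]],
                              list(random_dna(gap, 0.4)), list(paste(region, collapse = "")))
    chrom_pos[chrom] <- pos

    tid <- paste0(g$gene_id[i], ".t1")
    tx <- structure(list(transcript_id = tid, gene_id = g$gene_id[i],
                         chrom = chrom, strand = strand[i], exons = exon_g,
                         cds_start_tx = cds_s, cds_end_tx = cds_e,
                         sequence = seq, utr5_source = "annotated"),
                    class = "transcript_model")
    txs[[tid]] <- tx

    if (!is.null(outdir)) {
      spans <- exon_tx_spans(tx)
      attr_str <- sprintf('gene_id "%s"; transcript_id "%s";', g$gene_id[i], tid)
      for (e in seq_len(k)) {
        gtf <- c(gtf, sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
                              chrom, exon_g[e, 1] + 1L, exon_g[e, 2],
                              strand[i], attr_str))
        # CDS slice of this exon, in transcript space
        cs <- max(spans[e, 1], cds_s); ce <- min(spans[e, 2], cds_e)
        if (cs < ce) {
          gpos <- sort(tx_to_genome(tx, c(cs, ce - 1L)))
          gtf <- c(gtf, sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                                chrom, gpos[1] + 1L, gpos[2] + 1L,
                                strand[i], attr_str))
        }
      }
    }
  }
  txs <- structure(txs, class = "transcript_set")

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeLines(gtf, file.path(outdir, "annotation.gtf"))
    genome <- Biostrings::DNAStringSet(vapply(chrom_parts, function(p)
      paste(unlist(p), collapse = ""), character(1)))
    names(genome) <- names(chrom_parts)
    Biostrings::writeXStringSet(genome, file.path(outdir, "genome.fa"))
    write.table(truth$genes, file.path(outdir, "gene_classes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  txs
}

# per-position P-site sampling weights for one gene/condition
psite_weights <- function(tx, affected, params, treated,
                          rates = c(utr5 = 0.4, cds = 1, utr3 = 0.05)) {
  L <- tx_length(tx)
  s <- tx$cds_start_tx; e <- tx$cds_end_tx
  w <- numeric(L)
  if (s > 0) w[1:s] <- rates["utr5"]
  w[(s + 1):e] <- rates["cds"]
  if (e < L) w[(e + 1):L] <- rates["utr3"]
  # initiation peak over the start codon, the usual metagene landmark
  w[(s + 1):(s + 3)] <- w[(s + 1):(s + 3)] * 10
  if (affected && treated) {
    # graded 5'->3' depletion: full effect over the 5'UTR, decaying into
    # the CDS (70% of the log2 effect over the first 13 nt, 40% over the
    # next), emulating start-proximal loss of ribosome occupancy
    if (s > 0) w[1:s] <- w[1:s] * 2^params$dte
    h1 <- min(e, s + 13L)
    h2 <- min(e, s + params$dte_cds_nt)
    w[(s + 1):h1] <- w[(s + 1):h1] * 2^(0.7 * params$dte)
    if (h2 > h1) w[(h1 + 1):h2] <- w[(h1 + 1):h2] * 2^(0.4 * params$dte)
  }
  w
}

#' Simulate Ribo-seq reads and RNA-seq counts
#'
#' Emits RPF read records (transcript coordinates) and an RNA-seq gene
#' count matrix for a two-condition design with replicates. Read counts
#' per gene are gamma-Poisson (NB) around depth-proportional means; CDS
#' P-sites land in frame 0 with probability `frame_fidelity` (remainder
#' 2:1 in frames 1/2); read 5' ends are placed `psite_offset` nt upstream
#' of the P-site with lengths uniform on 26-29 nt plus a small
#' out-of-range contaminant fraction. Under the treated condition,
#' occupancy of the 5'UTR and the first `dte_cds_nt` nt of CDS of
#' te-affected genes is scaled by `2^dte`.
#'
#' @param truth a [simulation_truth()].
#' @param txs transcript set from [generate_transcriptome()].
#' @param n_rep replicates per condition.
#' @param depth_rpf RPF reads per sample.
#' @param depth_rna expected RNA counts per sample.
#' @param conditions length-2 character: control, treated labels.
#' @param contaminant_fraction fraction of reads with out-of-range length.
#' @param seed RNG seed.
#' @return list with `reads` (RPF table), `rna` (gene-level
#'   [count_matrix()]), `samples` (Ribo-seq sample metadata).
#' @export
simulate_ribo_rna <- function(truth, txs, n_rep = 3, depth_rpf = 2e6,
                              depth_rna = 1e6,
                              conditions = c("IFNg", "DUX4_pulse_IFNg"),
                              contaminant_fraction = 0.02,
                              seed = truth$seed + 2000L) {
  set_sim_seed(seed)
  g <- truth$genes
  p <- truth$params
  n <- nrow(g)
  tids <- names(txs)
  gene_of_tx <- vapply(txs, `[[`, "", "gene_id")
  tid_of_gene <- setNames(names(txs), gene_of_tx)[g$gene_id]
  alpha <- p$alpha

  # per-condition weights
  wlist <- list()
  totw <- list()
  for (cond in 1:2) {
    treated <- cond == 2
    wl <- lapply(seq_len(n), function(i)
      psite_weights(txs[[tid_of_gene[i]]], g$te_affected[i], p, treated))
    expr <- g$expression * 2^(g$transcriptional_lfc * treated)
    wlist[[cond]] <- wl
    totw[[cond]] <- expr * vapply(wl, sum, numeric(1))
  }

  samples <- data.frame(
    sample_id = paste0("ribo_", rep(conditions, each = n_rep), "_r",
                       rep(seq_len(n_rep), 2)),
    assay = "ribo",
    condition = rep(conditions, each = n_rep),
    replicate = rep(seq_len(n_rep), 2), stringsAsFactors = FALSE)

  read_chunks <- list()
  for (si in seq_len(nrow(samples))) {
    cond <- match(samples$condition[si], conditions)
    share <- totw[[cond]] / sum(totw[[cond]])
    u <- rgamma(n, shape = 1 / alpha, rate = 1 / alpha)
    n_g <- rpois(n, depth_rpf * share * u)
    gene_idx <- rep(seq_len(n), n_g)
    pos <- unlist(lapply(which(n_g > 0), function(i) {
      w <- wlist[[cond]][[i]]
      sample.int(length(w), n_g[i], replace = TRUE, prob = w) - 1L
    }))
    # frame jitter for CDS positions: snap to codon start, then offset
    tx_s <- vapply(txs, function(t) t$cds_start_tx, integer(1))[tid_of_gene[gene_idx]]
    tx_e <- vapply(txs, function(t) t$cds_end_tx, integer(1))[tid_of_gene[gene_idx]]
    in_cds <- pos >= tx_s & pos < tx_e
    codon0 <- tx_s + ((pos - tx_s) %/% 3L) * 3L
    fshift <- sample(0:2, length(pos), replace = TRUE,
                     prob = c(p$frame_fidelity,
                              2 / 3 * (1 - p$frame_fidelity),
                              1 / 3 * (1 - p$frame_fidelity)))
    pos[in_cds] <- pmin(codon0[in_cds] + fshift[in_cds], tx_e[in_cds] - 1L)

    nn <- length(pos)
    len <- sample(26:29, nn, replace = TRUE)
    contam <- runif(nn) < contaminant_fraction
    if (any(contam))
      len[contam] <- sample(c(22:25, 30:34), sum(contam), replace = TRUE)
    fp <- pos - p$psite_offset
    keep <- fp >= 0
    read_chunks[[si]] <- data.frame(
      transcript_id = tid_of_gene[gene_idx][keep],
      five_prime_pos = fp[keep], length = len[keep],
      sample_id = samples$sample_id[si], stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, read_chunks)
  rownames(reads) <- NULL

  # RNA-seq gene counts
  rna_samples <- data.frame(
    sample_id = paste0("rna_", rep(conditions, each = n_rep), "_r",
                       rep(seq_len(n_rep), 2)),
    assay = "rna",
    condition = rep(conditions, each = n_rep),
    replicate = rep(seq_len(n_rep), 2), stringsAsFactors = FALSE)
  rna_counts <- matrix(0L, nrow = n, ncol = nrow(rna_samples),
                       dimnames = list(g$gene_id, rna_samples$sample_id))
  for (si in seq_len(nrow(rna_samples))) {
    treated <- rna_samples$condition[si] == conditions[2]
    expr <- g$expression * 2^(g$transcriptional_lfc * treated)
    mu <- depth_rna * expr / sum(expr)
    u <- rgamma(n, shape = 1 / alpha, rate = 1 / alpha)
    rna_counts[, si] <- rpois(n, mu * u)
  }
  list(reads = reads,
       rna = count_matrix(rna_counts, rna_samples),
       samples = samples)
}

#' Simulate NB count matrices with a planted TE effect
#'
#' A count-level generator for benchmarking the differential TE test
#' directly: paired Ribo-seq/RNA-seq unit counts for two conditions with
#' a planted log2 TE change on a fraction of units and log-normal
#' per-sample library factors.
#'
#' @param n_units number of units.
#' @param n_rep replicates per condition per assay.
#' @param alpha NB dispersion.
#' @param planted_fraction fraction of units with the effect.
#' @param dte planted log2 TE change.
#' @param mean_meanlog,mean_sdlog log-normal parameters of unit means.
#' @param ribo_scale ratio of ribo to rna mean counts.
#' @param conditions condition labels (control, treated).
#' @param seed RNG seed.
#' @return list with `ribo`, `rna` ([count_matrix()]s), `planted`
#'   (logical per unit), `contrast` (a [contrast_spec()]).
#' @export
simulate_te_counts <- function(n_units = 2000, n_rep = 3, alpha = 0.01,
                               planted_fraction = 0.2, dte = -1,
                               mean_meanlog = log(300), mean_sdlog = 0.8,
                               ribo_scale = 0.8,
                               conditions = c("IFNg", "DUX4_pulse_IFNg"),
                               seed = 1) {
  set_sim_seed(seed)
  units <- sprintf("u%05d", seq_len(n_units))
  m <- rlnorm(n_units, mean_meanlog, mean_sdlog)
  planted <- rep(FALSE, n_units)
  planted[sample.int(n_units, round(planted_fraction * n_units))] <- TRUE

  mk_samples <- function(assay) data.frame(
    sample_id = paste0(assay, "_", rep(conditions, each = n_rep), "_r",
                       rep(seq_len(n_rep), 2)),
    assay = assay, condition = rep(conditions, each = n_rep),
    replicate = rep(seq_len(n_rep), 2), stringsAsFactors = FALSE)

  draw <- function(mu_mat) {
    libf <- exp(rnorm(ncol(mu_mat), 0, 0.1))
    cnt <- vapply(seq_len(ncol(mu_mat)), function(s) {
      u <- rgamma(nrow(mu_mat), shape = 1 / alpha, rate = 1 / alpha)
      rpois(nrow(mu_mat), mu_mat[, s] * libf[s] * u)
    }, numeric(nrow(mu_mat)))
    rownames(cnt) <- units
    cnt
  }
  rna_mu <- matrix(m, n_units, 2 * n_rep)
  ribo_mu <- cbind(matrix(m * ribo_scale, n_units, n_rep),
                   matrix(m * ribo_scale * 2^(dte * planted), n_units, n_rep))
  rna_s <- mk_samples("rna"); ribo_s <- mk_samples("ribo")
  rna_cnt <- draw(rna_mu); colnames(rna_cnt) <- rna_s$sample_id
  ribo_cnt <- draw(ribo_mu); colnames(ribo_cnt) <- ribo_s$sample_id
  list(ribo = count_matrix(ribo_cnt, ribo_s),
       rna = count_matrix(rna_cnt, rna_s),
       planted = setNames(planted, units),
       contrast = contrast_spec("te", conditions[2], conditions[1]))
}

#' Simulate spike-in polysome fraction counts
#'
#' Per gene and condition, mRNA mass is distributed over sub/low/high
#' polysome fractions according to the gene's polysome mode:
#' `normal` (0.2, 0.3, 0.5); `initiation_blocked` shifts mass from high
#' to sub in the pulse so that the high/sub ratio scales by
#' `2^init_block_lfc`; `elongation_stalled` keeps heavy-polysome mass in
#' both conditions; `dux4_induced` is near-silent in control and
#' high-fraction-heavy in the pulse. Counts are NB around
#' depth-proportional absolute abundances; sequencing yield tracks
#' recovered RNA, so a per-condition extraction-efficiency multiplier
#' scales both the gene counts and the spike-in totals of the affected
#' samples — spike-in size factors remove it, raw-count analysis does
#' not.
#'
#' @param truth a [simulation_truth()].
#' @param n_rep replicates per condition per fraction.
#' @param depth expected total counts per sample at efficiency 1.
#' @param spike_base expected spike-in total at efficiency 1.
#' @param conditions control, treated labels.
#' @param seed RNG seed.
#' @return a [count_matrix()] with samples for
#'   `{sub, low, high, total} x 2 conditions x n_rep`, spike totals in
#'   the metadata.
#' @export
simulate_polysome <- function(truth, n_rep = 3, depth = 6e5,
                              spike_base = 1e6,
                              conditions = c("IFNg", "DUX4_pulse_IFNg"),
                              seed = truth$seed + 3000L) {
  set_sim_seed(seed)
  g <- truth$genes
  p <- truth$params
  n <- nrow(g)
  base_mass <- c(sub = 0.2, low = 0.3, high = 0.5)
  # initiation block: high/sub ratio scaled by 2^init_block_lfc, mass
  # moving from high into sub; low untouched.
  r0 <- base_mass["high"] / base_mass["sub"]
  r1 <- r0 * 2^p$init_block_lfc
  hs <- base_mass["sub"] + base_mass["high"]
  ib_mass <- c(sub = unname(hs / (1 + r1)), low = unname(base_mass["low"]),
               high = unname(hs * r1 / (1 + r1)))
  dux_mass <- c(sub = 0.1, low = 0.2, high = 0.7)

  mass_for <- function(mode, treated) {
    if (!treated) return(base_mass)
    switch(mode,
           normal = base_mass,
           elongation_stalled = base_mass,
           initiation_blocked = ib_mass,
           dux4_induced = dux_mass)
  }

  fractions <- c("sub", "low", "high", "total")
  samples <- expand.grid(replicate = seq_len(n_rep), fraction = fractions,
                         condition = conditions, stringsAsFactors = FALSE)
  samples$assay <- ifelse(samples$fraction == "total",
                          "total_input", "polysome_fraction")
  samples$sample_id <- sprintf("%s_%s_r%d", samples$condition,
                               samples$fraction, samples$replicate)
  scale <- depth / sum(g$expression)

  counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                   dimnames = list(g$gene_id, samples$sample_id))
  spike_total <- numeric(nrow(samples))
  mass_mat <- list()
  for (cond in conditions) {
    treated <- cond == conditions[2]
    mm <- t(vapply(g$polysome_mode, mass_for, numeric(3), treated = treated))
    colnames(mm) <- c("sub", "low", "high")
    mass_mat[[cond]] <- mm
  }
  for (si in seq_len(nrow(samples))) {
    cond <- samples$condition[si]
    treated <- cond == conditions[2]
    eff <- (if (treated) p$extraction_multiplier else 1) * exp(rnorm(1, 0, 0.05))
    abund <- g$expression *
      ifelse(g$polysome_mode == "dux4_induced" & !treated, 0.02, 1)
    frac <- samples$fraction[si]
    mass <- if (frac == "total") rep(1, n) else mass_mat[[cond]][, frac]
    mu <- scale * abund * mass * eff
    u <- rgamma(n, shape = 1 / p$alpha, rate = 1 / p$alpha)
    counts[, si] <- rpois(n, mu * u)
    spike_total[si] <- round(spike_base * eff)
  }
  samples$spike_total <- spike_total
  count_matrix(counts, samples[, c("sample_id", "assay", "condition",
                                   "fraction", "replicate", "spike_total")])
}
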
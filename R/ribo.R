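#' Filter ribosome-protected fragments by length
#'
#' Restricts an RPF read table to the dominant fragment size class
#' (26-29 nt by default); fragments outside this range are dominated by
#' contaminants and degradation products.
#'
#' @param reads data.frame with columns `transcript_id`,
#'   `five_prime_pos` (0-based transcript coordinate of the read 5' end),
#'   `length`, `sample_id`.
#' @param lo,hi inclusive length bounds.
#' @return the filtered read table.
#' @export
filter_rpf_lengths <- function(reads, lo = 26, hi = 29) {
  if (lo > hi) stop("lo must not exceed hi")
  keep <- reads$length >= lo & reads$length <= hi
  msg("RPF length filter [%d, %d]: kept %d, dropped %d",
      lo, hi, sum(keep), sum(!keep))
  reads[keep, , drop = FALSE]
}

#' Calibrate the P-site offset per read length
#'
#' For each read length class, scans candidate offsets and picks the one
#' that maximizes the fraction of putative P-sites landing in reading
#' frame 0 over CDS positions; ties are broken toward the default
#' offset. Length classes with fewer than `min_reads` start-codon-
#' overlapping reads fall back to the default with a warning.
#'
#' @param reads RPF read table (after length filtering).
#' @param txs a `transcript_set` (for CDS annotation).
#' @param candidates candidate offsets to scan.
#' @param min_reads minimum start-codon-overlapping reads per length.
#' @param default fallback (and tie-break) offset.
#' @return named integer vector: length -> offset.
#' @export
calibrate_psite_offset <- function(reads, txs, candidates = 10:14,
                                   min_reads = 100, default = 12) {
  cds_start <- vapply(txs, function(tx)
    if (is_coding(tx)) tx$cds_start_tx else NA_integer_, integer(1))
  cds_end <- vapply(txs, function(tx)
    if (is_coding(tx)) tx$cds_end_tx else NA_integer_, integer(1))
  idx <- match(reads$transcript_id, names(txs))
  s <- cds_start[idx]
  e <- cds_end[idx]
  lens <- sort(unique(reads$length))
  offsets <- setNames(rep(as.integer(default), length(lens)), lens)
  # candidate order implements the tie-break: nearest to default, then lower
  cand <- candidates[order(abs(candidates - default), candidates)]
  for (len in lens) {
    sel <- reads$length == len & !is.na(s)
    fp <- reads$five_prime_pos[sel]
    ss <- s[sel]; ee <- e[sel]
    n_start <- sum(fp <= ss + 2 & fp + len > ss)
    if (n_start < min_reads) {
      warning("length ", len, ": only ", n_start,
              " start-codon reads; default offset ", default, " used")
      next
    }
    frac <- vapply(cand, function(o) {
      pos <- fp + o
      in_cds <- pos >= ss & pos < ee
      if (!any(in_cds)) return(0)
      mean((pos[in_cds] - ss[in_cds]) %% 3 == 0)
    }, numeric(1))
    offsets[as.character(len)] <- cand[which.max(frac)]
  }
  offsets
}

#' Assign P-site positions to RPF reads
#'
#' `pos = five_prime_pos + offset(length)`. Reads whose P-site falls off
#' the transcript are dropped (count logged); the reading frame relative
#' to the start codon is annotated for coding transcripts.
#'
#' @param reads RPF read table.
#' @param offsets named vector from [calibrate_psite_offset()], or a
#'   single offset applied to all lengths.
#' @param txs a `transcript_set`.
#' @return data.frame: transcript_id, pos, sample_id, frame.
#' @export
assign_psites <- function(reads, offsets, txs) {
  if (length(offsets) == 1L && is.null(names(offsets))) {
    off <- rep(as.integer(offsets), nrow(reads))
  } else {
    off <- offsets[as.character(reads$length)]
    if (anyNA(off))
      stop("no offset defined for read length(s): ",
           paste(unique(reads$length[is.na(off)]), collapse = ", "))
  }
  pos <- reads$five_prime_pos + as.integer(off)
  L <- vapply(txs, tx_length, integer(1))[reads$transcript_id]
  cds_start <- vapply(txs, function(tx)
    if (is_coding(tx)) tx$cds_start_tx else NA_integer_,
    integer(1))[reads$transcript_id]
  keep <- !is.na(L) & pos >= 0 & pos < L
  if (any(!keep)) msg("%d P-sites fell outside their transcript; dropped",
                      sum(!keep))
  data.frame(transcript_id = reads$transcript_id[keep],
             pos = pos[keep],
             sample_id = reads$sample_id[keep],
             frame = (pos[keep] - cds_start[keep]) %% 3,
             stringsAsFactors = FALSE)
}

#' Count P-sites per mRNA feature
#'
#' Tallies P-sites into the five feature intervals of each gene's
#' representative transcript. Because the TIS window overlaps the 5'UTR
#' and CDS (and the first coding exon is part of the CDS), one P-site can
#' contribute to several features; within one feature each P-site counts
#' once. Genes with no P-sites keep all-zero rows.
#'
#' @param psites output of [assign_psites()].
#' @param features output of [feature_table()].
#' @param sample_ids optional sample ordering for the output columns.
#' @return a [count_matrix()] with `gene|feature` units.
#' @export
count_psites_by_feature <- function(psites, features, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- sort(unique(psites$sample_id))
  known <- psites$transcript_id %in% features$transcript_id
  if (any(!known))
    msg("%d P-sites on transcripts without features ignored", sum(!known))
  psites <- psites[known, , drop = FALSE]

  units <- paste0(features$gene_id, "|", features$feature)
  counts <- matrix(0L, nrow = length(units), ncol = length(sample_ids),
                   dimnames = list(units, sample_ids))
  samp <- as.integer(factor(psites$sample_id, levels = sample_ids))
  feat_by_tx <- split(seq_len(nrow(features)), features$transcript_id)
  ps_by_tx <- split(seq_len(nrow(psites)), psites$transcript_id)
  for (tid in names(ps_by_tx)) {
    pi <- ps_by_tx[[tid]]
    pos <- psites$pos[pi]
    sm <- samp[pi]
    for (k in feat_by_tx[[tid]]) {
      sel <- pos >= features$start[k] & pos < features$end[k]
      if (any(sel))
        counts[k, ] <- tabulate(sm[sel], nbins = length(sample_ids))
    }
  }
  count_matrix(counts,
               data.frame(sample_id = sample_ids, assay = "ribo",
                          stringsAsFactors = FALSE))
}

#' Metagene P-site profile around a codon anchor
#'
#' Sums P-site counts per position (and reading frame) across transcripts
#' aligned at the start or stop codon. Frame fractions are computed over
#' CDS-located P-sites; with intact 3-nt periodicity most P-sites fall in
#' frame 0.
#'
#' @param psites output of [assign_psites()].
#' @param txs a `transcript_set`.
#' @param anchor `"start_codon"` or `"stop_codon"`.
#' @param upstream,downstream window half-widths in nt.
#' @return a `metagene_profile`: positions (relative to anchor), counts,
#'   per-frame counts, `frame_fractions`.
#' @export
metagene_profile <- function(psites, txs,
                             anchor = c("start_codon", "stop_codon"),
                             upstream = 50, downstream = 100) {
  anchor <- match.arg(anchor)
  cds_start <- vapply(txs, function(tx)
    if (is_coding(tx)) tx$cds_start_tx else NA_integer_, integer(1))
  cds_end <- vapply(txs, function(tx)
    if (is_coding(tx)) tx$cds_end_tx else NA_integer_, integer(1))
  a <- if (anchor == "start_codon") cds_start else cds_end - 3L
  rel <- psites$pos - a[psites$transcript_id]
  inwin <- !is.na(rel) & rel >= -upstream & rel <= downstream
  rel_in <- rel[inwin]
  positions <- seq(-upstream, downstream)
  cover <- tabulate(rel_in + upstream + 1L, nbins = length(positions))
  frame_of_pos <- ((positions %% 3) + 3) %% 3
  per_frame <- vapply(0:2, function(f) {
    v <- integer(length(positions))
    v[frame_of_pos == f] <- cover[frame_of_pos == f]
    v
  }, integer(length(positions)))
  colnames(per_frame) <- paste0("frame", 0:2)

  s <- cds_start[psites$transcript_id]
  e <- cds_end[psites$transcript_id]
  in_cds <- !is.na(s) & psites$pos >= s & psites$pos < e
  ff <- if (any(in_cds)) {
    tab <- table(factor(psites$frame[in_cds], levels = 0:2))
    as.numeric(tab / sum(tab))
  } else rep(NA_real_, 3)

  structure(list(anchor = anchor, window = c(-upstream, downstream),
                 positions = positions, coverage = cover,
                 per_frame = per_frame,
                 frame_fractions = setNames(ff, paste0("frame", 0:2)),
                 n_psites = sum(inwin)),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("metagene profile at %s, window [%d, %d], %d P-sites\n",
              x$anchor, x$window[1], x$window[2], x$n_psites))
  cat("frame fractions:", paste(sprintf("%.3f", x$frame_fractions),
                                collapse = " / "), "\n")
  invisible(x)
}

#' @method plot metagene_profile
#' @export
plot.metagene_profile <- function(x, ...) {
  cols <- c("#1b9e77", "#d95f02", "#7570b3")
  graphics::plot(x$positions, x$coverage, type = "h", col = cols[
    ((x$positions %% 3) + 3) %% 3 + 1],
    xlab = sprintf("nt from %s", x$anchor), ylab = "P-site count", ...)
  graphics::legend("topright", legend = paste0("frame ", 0:2), col = cols,
                   lty = 1, bty = "n")
  invisible(x)
}

#' Read an RPF table from TSV
#' @param path TSV with columns transcript_id, five_prime_pos, length, sample_id.
#' @return data.frame of reads.
#' @export
read_rpf_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
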
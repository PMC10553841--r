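#' Transcript models from GTF annotation and genome sequence
#'
#' Builds one transcript model per transcript from a Gencode-dialect GTF
#' (exon and CDS records keyed by `transcript_id`/`gene_id`) and a genome
#' FASTA. Exon sequences are spliced and minus-strand transcripts
#' reverse-complemented so that transcript coordinates always run 5' to
#' 3'. All internal coordinates are 0-based, half-open (GTF's 1-based
#' closed intervals are converted on import). CDS coordinates are
#' expressed as transcript-coordinate offsets `cds_start_tx`/`cds_end_tx`.
#'
#' Transcripts whose CDS falls outside the exon union, or that have CDS
#' records but no exons, are rejected with a warning. A chromosome
#' referenced by the GTF but absent from the FASTA is a hard error.
#'
#' @param gtf_path path to the GTF file.
#' @param fasta_path path to the genome FASTA (contig names matched on
#'   the first whitespace-delimited token).
#' @return a named list of `transcript_model` objects (class
#'   `transcript_set`).
#' @export
parse_annotation <- function(gtf_path, fasta_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))

  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    transcript_id = gr$transcript_id,
    gene_id = gr$gene_id,
    stringsAsFactors = FALSE)
  df <- df[!is.na(df$transcript_id), , drop = FALSE]

  txs <- list()
  rejected <- 0L
  for (tid in unique(df$transcript_id)) {
    rec <- df[df$transcript_id == tid, , drop = FALSE]
    ex <- rec[rec$type == "exon", , drop = FALSE]
    cds <- rec[rec$type == "CDS", , drop = FALSE]
    if (!nrow(ex)) {
      warning("transcript ", tid, " has CDS but no exons; rejected")
      rejected <- rejected + 1L
      next
    }
    chrom <- ex$chrom[1]
    if (!chrom %in% names(seqs))
      stop("sequence for contig '", chrom, "' missing from FASTA")
    ex <- ex[order(ex$start), , drop = FALSE]
    exons <- cbind(start = ex$start, end = ex$end)
    strand <- ex$strand[1]

    # spliced sequence, 5'->3'
    chrseq <- seqs[[chrom]]
    pieces <- apply(exons, 1, function(iv)
      as.character(Biostrings::subseq(chrseq, iv[1] + 1L, iv[2])))
    seq <- paste(pieces, collapse = "")
    if (strand == "-") seq <- revcomp_chr(seq)

    tx <- structure(list(
      transcript_id = tid, gene_id = rec$gene_id[1], chrom = chrom,
      strand = strand, exons = exons,
      cds_start_tx = NA_integer_, cds_end_tx = NA_integer_,
      sequence = seq, utr5_source = "annotated"),
      class = "transcript_model")

    if (nrow(cds)) {
      inside <- vapply(seq_len(nrow(cds)), function(i)
        any(cds$start[i] >= exons[, 1] & cds$end[i] <= exons[, 2]),
        logical(1))
      if (!all(inside)) {
        warning("transcript ", tid, " has CDS outside its exon union; rejected")
        rejected <- rejected + 1L
        next
      }
      g5 <- if (strand == "+") min(cds$start) else max(cds$end) - 1L
      g3 <- if (strand == "+") max(cds$end) - 1L else min(cds$start)
      tx$cds_start_tx <- genome_to_tx(tx, g5)
      tx$cds_end_tx <- genome_to_tx(tx, g3) + 1L
    }
    txs[[tid]] <- tx
  }
  if (rejected) msg("%d transcripts rejected during parsing", rejected)
  structure(txs, class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  coding <- sum(vapply(x, is_coding, logical(1)))
  cat(sprintf("transcript_set: %d transcripts (%d coding)\n", length(x), coding))
  invisible(x)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("%s (%s) %s%s, %d nt", x$transcript_id, x$gene_id, x$chrom,
              x$strand, nchar(x$sequence)))
  if (!is.na(x$cds_start_tx))
    cat(sprintf(", CDS [%d,%d)", x$cds_start_tx, x$cds_end_tx))
  cat("\n")
  invisible(x)
}

tx_length <- function(tx) nchar(tx$sequence)
is_coding <- function(tx) !is.na(tx$cds_start_tx)

# exon spans in transcript coordinates, 5'->3' order
exon_tx_spans <- function(tx) {
  if (is.null(tx$exons))
    return(cbind(start = 0L, end = tx_length(tx)))
  w <- tx$exons[, 2] - tx$exons[, 1]
  if (tx$strand == "-") w <- rev(w)
  ends <- cumsum(w)
  cbind(start = c(0L, ends[-length(ends)]), end = ends)
}

#' Map a genomic position into transcript coordinates
#'
#' @param tx a `transcript_model`.
#' @param gpos genomic position(s), 0-based.
#' @return transcript coordinate(s), 0-based 5'->3'; NA for positions not
#'   covered by an exon.
#' @export
genome_to_tx <- function(tx, gpos) {
  if (is.null(tx$exons)) stop("transcript has no genomic exon structure")
  spans <- exon_tx_spans(tx)
  exons <- tx$exons
  if (tx$strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_len(nrow(exons))) {
    hit <- gpos >= exons[i, 1] & gpos < exons[i, 2]
    if (!any(hit)) next
    out[hit] <- if (tx$strand == "+")
      spans[i, 1] + (gpos[hit] - exons[i, 1])
    else
      spans[i, 1] + (exons[i, 2] - 1L - gpos[hit])
  }
  as.integer(out)
}

#' Map a transcript coordinate back to the genome
#'
#' Inverse of [genome_to_tx()] on exonic positions.
#' @param tx a `transcript_model`.
#' @param pos transcript coordinate(s), 0-based.
#' @return genomic position(s), 0-based.
#' @export
tx_to_genome <- function(tx, pos) {
  if (is.null(tx$exons)) stop("transcript has no genomic exon structure")
  spans <- exon_tx_spans(tx)
  exons <- tx$exons
  if (tx$strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(spans))) {
    hit <- pos >= spans[i, 1] & pos < spans[i, 2]
    if (!any(hit)) next
    out[hit] <- if (tx$strand == "+")
      exons[i, 1] + (pos[hit] - spans[i, 1])
    else
      exons[i, 2] - 1L - (pos[hit] - spans[i, 1])
  }
  as.integer(out)
}
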
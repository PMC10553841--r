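#' Derive the five mRNA features of a coding transcript
#'
#' In transcript coordinates (0-based, half-open):
#' * `utr5`  = `[0, cds_start)`
#' * `tis_window` = `[cds_start - tis_flank, cds_start + 3 + tis_flank)`
#'   clipped to the transcript — the start codon plus `tis_flank` nt of
#'   flank on each side (width `2*tis_flank + 3` when unclipped)
#' * `first_cds_exon` = the CDS portion of the exon containing the start
#'   codon
#' * `cds`   = `[cds_start, cds_end)`
#' * `utr3`  = `[cds_end, L)`
#'
#' `utr5`, `cds` and `utr3` partition the transcript exactly; the TIS
#' window deliberately overlaps the 5'UTR and CDS.
#'
#' @param tx a coding `transcript_model`.
#' @param tis_flank nt of flank on each side of the start codon.
#' @return a `feature_intervals` list of `c(start, end)` intervals, or
#'   NULL (with a message) for non-coding transcripts.
#' @export
derive_features <- function(tx, tis_flank = 13) {
  if (!is_coding(tx)) {
    msg("transcript %s is non-coding; no features derived", tx$transcript_id)
    return(NULL)
  }
  L <- tx_length(tx)
  s <- tx$cds_start_tx
  e <- tx$cds_end_tx
  tis <- c(max(0L, s - as.integer(tis_flank)),
           min(L, s + 3L + as.integer(tis_flank)))
  spans <- exon_tx_spans(tx)
  hit <- which(spans[, 1] <= s & s < spans[, 2])
  fce <- c(max(s, spans[hit, 1]), min(e, spans[hit, 2]))
  structure(list(transcript_id = tx$transcript_id, gene_id = tx$gene_id,
                 utr5 = c(0L, s), tis_window = tis, first_cds_exon = fce,
                 cds = c(s, e), utr3 = c(e, L), L = L),
            class = "feature_intervals")
}

feature_names <- c("utr5", "tis", "first_cds_exon", "cds", "utr3")

#' Feature interval table for a transcript set
#'
#' Derives features for one transcript per gene (by default the longest
#' coding transcript, ties broken by transcript id) and returns them in
#' long format for counting and export.
#'
#' @param txs a `transcript_set`.
#' @param tis_flank see [derive_features()].
#' @param isoforms `"longest"` (one transcript per gene) or `"all"`.
#' @return data.frame: transcript_id, gene_id, feature, start, end.
#' @export
feature_table <- function(txs, tis_flank = 13,
                          isoforms = c("longest", "all")) {
  isoforms <- match.arg(isoforms)
  use <- Filter(is_coding, txs)
  if (isoforms == "longest") {
    df <- data.frame(tid = vapply(use, `[[`, "", "transcript_id"),
                     gid = vapply(use, `[[`, "", "gene_id"),
                     len = vapply(use, tx_length, integer(1)))
    df <- df[order(df$gid, -df$len, df$tid), , drop = FALSE]
    use <- use[df$tid[!duplicated(df$gid)]]
  }
  rows <- lapply(use, function(tx) {
    fi <- derive_features(tx, tis_flank)
    iv <- rbind(fi$utr5, fi$tis_window, fi$first_cds_exon, fi$cds, fi$utr3)
    data.frame(transcript_id = fi$transcript_id, gene_id = fi$gene_id,
               feature = c("utr5", "tis", "first_cds_exon", "cds", "utr3"),
               start = iv[, 1], end = iv[, 2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Replace annotated 5'UTRs with experimentally determined ones
#'
#' Applies an override table (e.g. re-annotated 5'UTRs of direct target
#' genes inferred from RNA-seq alignments) to a transcript set: for each
#' listed gene the 5'UTR sequence of its coding transcripts is replaced
#' and the CDS offsets shifted accordingly. Overridden transcripts lose
#' their genomic exon structure (the new UTR has no genomic projection)
#' and are marked `utr5_source = "override"`. Rows for unknown genes or
#' with non-ACGT/U characters are skipped with a warning.
#'
#' @param txs a `transcript_set`.
#' @param override_table data.frame with `gene_id` and `utr5_sequence`.
#' @return the modified `transcript_set`.
#' @export
apply_utr_overrides <- function(txs, override_table) {
  if (is.null(override_table) || !nrow(override_table)) return(txs)
  genes <- vapply(txs, `[[`, "", "gene_id")
  for (i in seq_len(nrow(override_table))) {
    gid <- override_table$gene_id[i]
    new_utr <- toupper(override_table$utr5_sequence[i])
    if (grepl("[^ACGTU]", new_utr)) {
      warning("override for gene ", gid, " contains non-ACGT/U characters; skipped")
      next
    }
    hits <- which(genes == gid)
    if (!length(hits)) {
      warning("override for unknown gene ", gid, " skipped")
      next
    }
    for (j in hits) {
      tx <- txs[[j]]
      if (!is_coding(tx)) next
      body <- substr(tx$sequence, tx$cds_start_tx + 1L, tx_length(tx))
      shift <- nchar(new_utr) - tx$cds_start_tx
      tx$sequence <- paste0(gsub("U", "T", new_utr, fixed = TRUE), body)
      tx$cds_end_tx <- tx$cds_end_tx + shift
      tx$cds_start_tx <- nchar(new_utr)
      tx$exons <- NULL  # genomic projection no longer defined
      tx$utr5_source <- "override"
      txs[[j]] <- tx
    }
  }
  txs
}

#' Extract the filtered 5'UTR sequence set
#'
#' 5'UTR sequences of coding transcripts of expressed genes, with short
#' UTRs removed and (optionally) duplicate sequences collapsed — the
#' input set for structure analysis.
#'
#' @param txs a `transcript_set` (after any overrides).
#' @param expressed_genes character vector of expressed gene ids, or NULL
#'   to keep all genes.
#' @param min_len minimum UTR length (shorter UTRs excluded).
#' @param dedupe collapse duplicate sequences (first transcript id kept).
#' @return data.frame: gene_id, transcript_id, sequence, source.
#' @export
extract_utr5_set <- function(txs, expressed_genes = NULL, min_len = 4,
                             dedupe = TRUE) {
  use <- Filter(is_coding, txs)
  rows <- lapply(use, function(tx) {
    data.frame(gene_id = tx$gene_id, transcript_id = tx$transcript_id,
               sequence = substr(tx$sequence, 1L, tx$cds_start_tx),
               source = tx$utr5_source, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(gene_id = character(), transcript_id = character(),
                                      sequence = character(), source = character()))
  rownames(out) <- NULL
  if (!is.null(expressed_genes)) out <- out[out$gene_id %in% expressed_genes, ]
  out <- out[nchar(out$sequence) >= min_len, , drop = FALSE]
  out <- out[order(out$transcript_id), , drop = FALSE]
  if (dedupe) out <- out[!duplicated(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes considered expressed for the 5'UTR analysis
#'
#' A gene is expressed when its mean normalized count meets `min_mean`
#' (default 1) across the supplied samples.
#'
#' @param cm count_matrix with size factors.
#' @param min_mean threshold on the mean normalized count.
#' @return character vector of gene ids.
#' @export
expressed_genes <- function(cm, min_mean = 1) {
  bm <- rowMeans(normalized_counts(cm))
  rownames(cm$counts)[bm >= min_mean]
}

#' Write derived features as BED6 (transcript coordinates)
#'
#' One line per feature interval; `chrom` is the transcript id, `name` is
#' `transcript_id|feature`.
#'
#' @param features output of [feature_table()].
#' @param path output file.
#' @export
write_features_bed <- function(features, path) {
  bed <- data.frame(features$transcript_id, features$start, features$end,
                    paste0(features$transcript_id, "|", features$feature),
                    0L, "+")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a 5'UTR set as FASTA
#'
#' @param utrs output of [extract_utr5_set()].
#' @param path output file.
#' @export
write_utr5_fasta <- function(utrs, path) {
  ss <- Biostrings::DNAStringSet(gsub("U", "T", utrs$sequence, fixed = TRUE))
  names(ss) <- paste(utrs$transcript_id, utrs$gene_id, utrs$source)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
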
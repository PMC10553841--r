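#' Predict the minimum free energy structure of an RNA sequence
#'
#' Two engines are available. The `builtin` engine is a pair-additive
#' dynamic program (Nussinov-style energy minimization: GC = -3, AU = -2,
#' GU = -1, minimum hairpin loop of 3 unpaired nt, no pseudoknots) with a
#' deterministic traceback; its scores are rank-proxies for structural
#' stability in arbitrary units, suitable for comparing groups of
#' sequences. The `external` engine delegates to an installed
#' RNAfold-compatible executable and returns nearest-neighbor model
#' energies in kcal/mol.
#'
#' @param seq nucleotide string over A/C/G/U (T is mapped to U).
#' @param engine `"builtin"` or `"external"`.
#' @param gu_wobble allow G.U wobble pairs in the builtin engine. Note
#'   that wobble pairing breaks the reverse-complement symmetry of the
#'   pair-additive model (a G.U pair maps to an unpairable A.C under
#'   reverse complement); with `gu_wobble = FALSE` the model is exactly
#'   symmetric.
#' @param rnafold path to the RNAfold executable for the external engine.
#' @return a `fold_result` list: `sequence`, `structure` (dot-bracket),
#'   `mfe`, `engine`.
#' @export
fold_mfe <- function(seq, engine = c("builtin", "external"),
                     gu_wobble = TRUE, rnafold = "RNAfold") {
  engine <- match.arg(engine)
  seq <- chartr("acgut", "ACGUT", seq)
  seq <- gsub("T", "U", seq, fixed = TRUE)
  if (nchar(seq) == 0 || grepl("[^ACGU]", seq))
    stop("sequence must be non-empty over the alphabet {A,C,G,U/T}")
  if (engine == "builtin") {
    f <- nussinov_fold(seq, min_loop = 3L, wobble = gu_wobble)
    res <- list(sequence = seq, structure = f$structure, mfe = f$mfe,
                engine = "builtin")
  } else {
    if (Sys.which(rnafold) == "")
      stop("external engine unavailable (RNAfold not found); ",
           "use engine = 'builtin'")
    out <- system2(rnafold, args = "--noPS", input = seq, stdout = TRUE)
    line <- out[length(out)]
    m <- regmatches(line, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
    if (length(m) != 3) stop("could not parse RNAfold output: ", line)
    res <- list(sequence = seq, structure = m[2], mfe = as.numeric(m[3]),
                engine = "external")
  }
  class(res) <- "fold_result"
  res
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, sprintf(" (%g, %s)\n", x$mfe, x$engine),
      sep = "")
  invisible(x)
}

#' Minimum free energy scaled to 100 nt
#'
#' Length-normalized structure score, `mfe / length * 100`, so that UTRs
#' of different lengths are comparable.
#'
#' @param fr a `fold_result`, or a numeric mfe (then `len` is required).
#' @param len sequence length when `fr` is numeric.
#' @return numeric scalar.
#' @export
mfe_per_100nt <- function(fr, len = NULL) {
  if (inherits(fr, "fold_result")) {
    mfe <- fr$mfe; len <- nchar(fr$sequence)
  } else {
    mfe <- fr
    if (is.null(len)) stop("len required for a bare mfe value")
  }
  mfe / len * 100
}

#' Fold a table of 5'UTR sequences
#'
#' Runs [fold_mfe()] on each sequence and returns one row per gene with
#' the raw and per-100-nt scaled MFE. Sequences containing N (or shorter
#' than `min_len`) are skipped with a warning.
#'
#' @param utrs data.frame with `gene_id` and `sequence` columns (as
#'   produced by [extract_utr5_set()]).
#' @param groups optional named character vector or data.frame
#'   (`gene_id`, `group`) assigning group labels.
#' @param engine folding engine, see [fold_mfe()].
#' @param min_len minimum sequence length.
#' @return data.frame: gene_id, utr_length, mfe, mfe_per_100nt, group.
#' @export
utr_structure_table <- function(utrs, groups = NULL,
                                engine = c("builtin", "external"),
                                min_len = 4) {
  engine <- match.arg(engine)
  seqs <- toupper(utrs$sequence)
  bad <- grepl("[^ACGUT]", seqs) | nchar(seqs) < min_len
  if (any(bad))
    warning(sum(bad), " sequences skipped (ambiguous bases or length < ",
            min_len, ")")
  utrs <- utrs[!bad, , drop = FALSE]
  mfe <- vapply(utrs$sequence, function(s) fold_mfe(s, engine)$mfe, numeric(1),
                USE.NAMES = FALSE)
  len <- nchar(utrs$sequence)
  out <- data.frame(gene_id = utrs$gene_id, utr_length = len, mfe = mfe,
                    mfe_per_100nt = mfe / len * 100,
                    group = "all", stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    if (is.data.frame(groups))
      groups <- setNames(groups$group, groups$gene_id)
    hit <- out$gene_id %in% names(groups)
    out$group[hit] <- unname(groups[out$gene_id[hit]])
  }
  out
}

#' Compare per-100-nt MFE between two gene groups
#'
#' Two-sided Mann-Whitney U test on `mfe_per_100nt` between two groups of
#' a [utr_structure_table()]. A higher (less negative) median indicates
#' less structured 5'UTRs, the hallmark of efficiently initiated mRNAs.
#'
#' @param rows output of [utr_structure_table()].
#' @param groupA,groupB group labels present in `rows$group`, or
#'   character vectors of gene ids.
#' @param nested allow one group to be a subset of the other (e.g. a
#'   target set against "all").
#' @return list with medians, n per group, U statistic and p-value.
#' @export
compare_utr_groups <- function(rows, groupA, groupB, nested = FALSE) {
  pick <- function(g) {
    if (length(g) == 1 && g %in% rows$group) rows$mfe_per_100nt[rows$group == g]
    else rows$mfe_per_100nt[rows$gene_id %in% g]
  }
  ids <- function(g) {
    if (length(g) == 1 && g %in% rows$group) rows$gene_id[rows$group == g]
    else intersect(g, rows$gene_id)
  }
  a <- pick(groupA); b <- pick(groupB)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ov <- intersect(ids(groupA), ids(groupB))
  if (length(ov) && !nested)
    stop(length(ov), " genes fall in both groups; set nested = TRUE if ",
         "one group contains the other")
  ts <- group_shift_test(list(A = a, B = b), "mwu")
  list(median_A = median(a), median_B = median(b),
       n = c(A = length(a), B = length(b)),
       statistic = ts$statistic, p_value = ts$p_value)
}
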
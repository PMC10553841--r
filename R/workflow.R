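#' Run configuration helpers
#'
#' A run configuration is a plain named list of inputs, contrast labels
#' and thresholds. `write_run_config()` serializes it (without in-memory
#' objects) next to the outputs and returns its md5 hash, which every
#' output table carries as a comment line, so a finished run documents
#' the settings that produced it.
#'
#' @param cfg named list.
#' @param outdir output directory.
#' @return md5 hash string of the serialized config.
#' @keywords internal
write_run_config <- function(cfg, outdir) {
  cfg$outdir <- NULL  # the hash covers analysis settings, not output paths
  serializable <- cfg[vapply(cfg, function(x)
    is.atomic(x) || is.list(x) && all(vapply(x, is.atomic, logical(1))),
    logical(1))]
  path <- file.path(outdir, "run_config.json")
  jsonlite::write_json(serializable, path, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(path))
}

write_result_tsv <- function(df, path, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(paste0("# config_hash=", hash), con)
  write.table(as.data.frame(df), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Feature-level differential translation-efficiency analysis
#'
#' Orchestrates the full Ribo-seq stage: RPF length filtering, P-site
#' offset calibration and assignment, feature-level counting, metagene
#' QC, RNA-level classification of condition-altered genes (excluded
#' from steady-state TE testing), and the NB interaction TE test run
#' independently for each of the five mRNA features.
#'
#' @param cfg list with elements: `txs` (a `transcript_set`) or
#'   `gtf`/`fasta` paths; `reads` (RPF table) or `reads_path`; `rna`
#'   (gene-level [count_matrix()]); `treated`/`untreated` condition
#'   labels; optional `tis_flank` (13), `min_len`/`max_len` (26/29),
#'   `offset` ("auto" or integer), `min_basemean` (10),
#'   `altered_lfc` (1), `altered_padj` (0.05), `lfc_thresh`/`padj_thresh`
#'   for the summary (1, 0.05), `outdir`.
#' @return list: `results` (per-feature `nb_diff` tables), `metagene`
#'   (per condition), `altered_genes`, `summary` data.frame of
#'   significant-unit counts per feature.
#' @export
run_te_analysis <- function(cfg) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  txs <- stage("annotation", {
    if (!is.null(cfg$txs)) cfg$txs else parse_annotation(cfg$gtf, cfg$fasta)
  })
  features <- stage("annotation", feature_table(txs, cfg$tis_flank %||% 13))
  reads <- cfg$reads %||% read_rpf_table(cfg$reads_path)

  psites <- stage("ribo_profiling", {
    reads <- filter_rpf_lengths(reads, cfg$min_len %||% 26, cfg$max_len %||% 29)
    offset <- cfg$offset %||% "auto"
    offsets <- if (identical(offset, "auto"))
      calibrate_psite_offset(reads, txs) else as.integer(offset)
    assign_psites(reads, offsets, txs)
  })
  ribo_cm <- stage("ribo_profiling", count_psites_by_feature(psites, features))
  # carry condition labels onto the ribo samples
  smap <- cfg$sample_conditions %||% NULL
  ribo_cm$samples$condition <- if (!is.null(smap)) smap[ribo_cm$samples$sample_id]
    else sub("^ribo_(.*)_r[0-9]+$", "\\1", ribo_cm$samples$sample_id)

  metagene <- stage("ribo_profiling", {
    conds <- unique(ribo_cm$samples$condition)
    setNames(lapply(conds, function(cc) {
      ids <- ribo_cm$samples$sample_id[ribo_cm$samples$condition == cc]
      metagene_profile(psites[psites$sample_id %in% ids, , drop = FALSE], txs)
    }), conds)
  })

  diff <- stage("diff_models", {
    rna <- estimate_size_factors(cfg$rna)
    altered <- classify_altered_genes(
      nb_contrast(rna, contrast_spec("rna", cfg$treated, cfg$untreated)),
      cfg$altered_lfc %||% 1, cfg$altered_padj %||% 0.05)
    res <- te_tests_by_feature(
      ribo_cm, rna,
      contrast_spec("te", cfg$treated, cfg$untreated),
      min_basemean = cfg$min_basemean %||% 10,
      exclude_genes = altered)
    list(res = res, altered = altered)
  })

  lfc_thr <- cfg$lfc_thresh %||% 1
  padj_thr <- cfg$padj_thresh %||% 0.05
  summary_df <- do.call(rbind, lapply(names(diff$res), function(f) {
    r <- diff$res[[f]]
    ok <- !is.na(r$padj)
    data.frame(feature = f, tested = sum(ok),
               sig_down = sum(ok & r$log2FC < -lfc_thr & r$padj < padj_thr),
               sig_up = sum(ok & r$log2FC > lfc_thr & r$padj < padj_thr),
               stringsAsFactors = FALSE)
  }))
  summary_df$frac_down <- summary_df$sig_down / pmax(summary_df$tested, 1)

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    hash <- write_run_config(cfg[setdiff(names(cfg), c("txs", "reads", "rna"))],
                             cfg$outdir)
    for (f in names(diff$res))
      write_result_tsv(diff$res[[f]],
                       file.path(cfg$outdir, paste0("te_", f, ".tsv")), hash)
    write_result_tsv(summary_df, file.path(cfg$outdir, "te_summary.tsv"), hash)
    jsonlite::write_json(
      list(config_hash = hash,
           frame_fractions = lapply(metagene, `[[`, "frame_fractions"),
           altered_genes = diff$altered),
      file.path(cfg$outdir, "te_qc.json"), auto_unbox = TRUE, digits = NA)
  }
  list(results = diff$res, metagene = metagene,
       altered_genes = diff$altered, summary = summary_df)
}

#' Differential polysome-association analysis (three formulations)
#'
#' Spike-in normalizes a polysome count matrix and runs: (1) each
#' gradient fraction against total input, (2) the high-to-sub ratio
#' contrast, both with transcriptionally altered genes excluded, and
#' (3) simple differential expression within the high fraction with
#' altered genes retained; plus a gene-set shift summary (e.g. TOP
#' mRNAs) on the high/sub results.
#'
#' @param cfg list with: `counts` (polysome [count_matrix()] incl. total
#'   input and spike totals); `treated`/`untreated`; optional
#'   `gene_sets` (named list of gene-id vectors), `altered_lfc` (2),
#'   `altered_padj` (0.01), `normalization` ("spike"), `lfc_thresh` (1),
#'   `padj_thresh` (0.01), `min_basemean` (50), `outdir`.
#' @return list: `fraction_vs_total` (per fraction), `high_over_sub`,
#'   `high_dge`, `altered_genes`, `gene_set_shifts`.
#' @export
run_polysome_analysis <- function(cfg) {
  cm <- cfg$counts
  contrast <- contrast_spec("polysome", cfg$treated, cfg$untreated)
  normalization <- cfg$normalization %||% "spike"

  total <- fractions_cm(cm, "total")
  total <- if (normalization == "spike") estimate_size_factors(total, "spike_in")
    else estimate_size_factors(total)
  altered <- classify_altered_genes(
    nb_contrast(total, contrast_spec("input", cfg$treated, cfg$untreated)),
    cfg$altered_lfc %||% 2, cfg$altered_padj %||% 0.01)

  fvt <- setNames(lapply(c("sub", "low", "high"), function(f)
    fraction_vs_total_contrast(cm, f, contrast, exclude_genes = altered,
                               normalization = normalization)),
    c("sub", "low", "high"))
  hos <- high_over_sub_contrast(cm, contrast, exclude_genes = altered,
                                normalization = normalization)
  hdge <- high_fraction_dge(cm, contrast, normalization = normalization)

  shifts <- NULL
  if (!is.null(cfg$gene_sets))
    shifts <- lapply(cfg$gene_sets, function(gs) gene_set_shift(hos, gs))

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    hash <- write_run_config(cfg[setdiff(names(cfg), "counts")], cfg$outdir)
    lfc_thr <- cfg$lfc_thresh %||% 1
    padj_thr <- cfg$padj_thresh %||% 0.01
    bm_thr <- cfg$min_basemean %||% 50
    flag <- function(r) {
      r$significant <- !is.na(r$padj) & r$baseMean > bm_thr &
        abs(r$log2FC) > lfc_thr & r$padj < padj_thr
      r
    }
    for (f in names(fvt))
      write_result_tsv(flag(fvt[[f]]),
                       file.path(cfg$outdir, paste0("fraction_", f, "_vs_total.tsv")), hash)
    write_result_tsv(flag(hos), file.path(cfg$outdir, "high_over_sub.tsv"), hash)
    write_result_tsv(flag(hdge), file.path(cfg$outdir, "high_fraction_dge.tsv"), hash)
    if (!is.null(shifts))
      jsonlite::write_json(list(config_hash = hash, gene_set_shifts = shifts),
                           file.path(cfg$outdir, "gene_set_shifts.json"),
                           auto_unbox = TRUE, digits = NA)
  }
  list(fraction_vs_total = fvt, high_over_sub = hos, high_dge = hdge,
       altered_genes = altered, gene_set_shifts = shifts)
}

#' 5'UTR structure analysis
#'
#' Folds a filtered 5'UTR set, scales MFE to 100 nt, and compares gene
#' groups (each non-background group against the background) with
#' two-sided Mann-Whitney U tests.
#'
#' @param cfg list with: `utrs` (data.frame from [extract_utr5_set()])
#'   or `fasta` path; `groups` (data.frame gene_id, group); optional
#'   `engine` ("builtin"), `background_group` ("all"), `outdir`.
#' @return list: `table` ([utr_structure_table()] rows), `comparisons`.
#' @export
run_utr_analysis <- function(cfg) {
  utrs <- cfg$utrs
  if (is.null(utrs)) {
    ss <- Biostrings::readDNAStringSet(cfg$fasta)
    parts <- strsplit(names(ss), "\\s+")
    utrs <- data.frame(
      gene_id = vapply(parts, function(p) p[min(2, length(p))], ""),
      transcript_id = vapply(parts, `[[`, "", 1),
      sequence = as.character(ss), stringsAsFactors = FALSE)
  }
  tab <- utr_structure_table(utrs, groups = cfg$groups,
                             engine = cfg$engine %||% "builtin")
  bg <- cfg$background_group %||% "all"
  others <- setdiff(unique(tab$group), bg)
  if (!length(others)) stop("no non-background group to compare")
  comparisons <- setNames(lapply(others, function(gother) {
    compare_utr_groups(tab, gother, bg)
  }), others)

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    hash <- write_run_config(cfg[setdiff(names(cfg), c("utrs", "groups"))],
                             cfg$outdir)
    write_result_tsv(tab, file.path(cfg$outdir, "utr_structure.tsv"), hash)
    jsonlite::write_json(list(config_hash = hash, comparisons = comparisons),
                         file.path(cfg$outdir, "utr_comparisons.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(table = tab, comparisons = comparisons)
}
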
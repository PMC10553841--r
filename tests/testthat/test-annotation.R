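write_mini_annotation <- function(dir) {
  # chrT: 300 nt; three genes exercising strand, multi-exon and rejection
  set.seed(42)
  chr <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  fa <- file.path(dir, "mini.fa")
  writeLines(c(">chrT something", chr), fa)
  gtf <- file.path(dir, "mini.gtf")
  writeLines(c(
    # + strand single exon [100,200) (GTF 1-based closed: 101-200), CDS [130,190)
    'chrT\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chrT\tx\tCDS\t131\t190\t.\t+\t0\tgene_id "g1"; transcript_id "t1";',
    # - strand two exons [100,150) and [200,250)
    'chrT\tx\texon\t101\t150\t.\t-\t.\tgene_id "g2"; transcript_id "t2";',
    'chrT\tx\texon\t201\t250\t.\t-\t.\tgene_id "g2"; transcript_id "t2";',
    # CDS with no exon record -> rejected
    'chrT\tx\tCDS\t10\t60\t.\t+\t0\tgene_id "g3"; transcript_id "t3";'),
    gtf)
  list(gtf = gtf, fa = fa, chr = chr)
}

test_that("GTF parsing produces correct transcript coordinates on both strands", {
  dir <- withr::local_tempdir()
  mini <- write_mini_annotation(dir)
  expect_warning(txs <- parse_annotation(mini$gtf, mini$fa), "no exons")

  t1 <- txs[["t1"]]
  expect_equal(t1$cds_start_tx, 30L)
  expect_equal(t1$cds_end_tx, 90L)
  expect_equal(nchar(t1$sequence), 100L)
  expect_equal(t1$sequence, substr(mini$chr, 101, 200))

  t2 <- txs[["t2"]]
  expect_equal(nchar(t2$sequence), 100L)
  spliced <- paste0(substr(mini$chr, 101, 150), substr(mini$chr, 201, 250))
  expect_equal(t2$sequence,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(spliced))))
  expect_false("t3" %in% names(txs))
})

test_that("missing contig in the FASTA is a hard error naming it", {
  dir <- withr::local_tempdir()
  mini <- write_mini_annotation(dir)
  writeLines(c(">chrOther", "ACGT"), mini$fa)
  expect_error(suppressWarnings(parse_annotation(mini$gtf, mini$fa)), "chrT")
})

test_that("feature derivation follows the TIS window and partition rules", {
  tx <- random_tx(utr5 = 50, cds = 300)
  tx$sequence <- paste(rep("A", 450), collapse = "")
  fi <- derive_features(tx, tis_flank = 13)
  expect_equal(fi$tis_window, c(37L, 66L))
  expect_equal(diff(fi$tis_window), 29L)
  expect_equal(fi$utr5, c(0L, 50L))
  expect_equal(fi$cds, c(50L, 350L))
  expect_equal(fi$utr3, c(350L, 450L))

  # clipped at the 5' end
  tx2 <- random_tx(utr5 = 5, cds = 60)
  fi2 <- derive_features(tx2, tis_flank = 13)
  expect_equal(fi2$tis_window, c(0L, 21L))

  # first coding exon: transcript spans [0,150), [150,450), cds [50,350)
  tx3 <- tiny_tx_plus()
  tx3$exons <- cbind(start = c(0L, 250L), end = c(150L, 550L))
  tx3$sequence <- paste(rep("A", 450), collapse = "")
  tx3$cds_start_tx <- 50L; tx3$cds_end_tx <- 350L
  fi3 <- derive_features(tx3)
  expect_equal(fi3$first_cds_exon, c(50L, 150L))
})

test_that("feature partition and TIS containment hold on random transcripts", {
  set.seed(101)
  for (i in 1:200) {
    tx <- random_tx()
    fi <- derive_features(tx)
    L <- nchar(tx$sequence)
    expect_identical(diff(fi$utr5) + diff(fi$cds) + diff(fi$utr3), L)
    expect_true(fi$tis_window[1] >= 0 && fi$tis_window[2] <= L)
    expect_true(fi$first_cds_exon[1] >= fi$cds[1] &&
                  fi$first_cds_exon[2] <= fi$cds[2])
  }
})

test_that("genome/transcript coordinate projection round-trips on both strands", {
  set.seed(7)
  for (i in 1:50) {
    tx <- random_tx()
    pos <- seq(0L, nchar(tx$sequence) - 1L)
    g <- tx_to_genome(tx, pos)
    expect_false(anyNA(g))
    expect_identical(genome_to_tx(tx, g), pos)
  }
})

test_that("non-coding transcripts yield no features", {
  tx <- random_tx()
  tx$cds_start_tx <- NA_integer_
  expect_message(fi <- derive_features(tx), "non-coding")
  expect_null(fi)
})

test_that("5'UTR overrides replace sequence and provenance for listed genes", {
  tx <- random_tx(utr5 = 200, cds = 300)
  txs <- structure(list(txR = tx), class = "transcript_set")
  ov <- data.frame(gene_id = "gR",
                   utr5_sequence = paste(rep("AC", 40), collapse = ""),
                   stringsAsFactors = FALSE)
  out <- apply_utr_overrides(txs, ov)
  expect_equal(out$txR$cds_start_tx, 80L)
  expect_equal(out$txR$utr5_source, "override")
  utr <- extract_utr5_set(out)
  expect_equal(nchar(utr$sequence), 80L)
  expect_equal(utr$source, "override")
  # CDS sequence untouched
  expect_equal(substr(out$txR$sequence, 81, nchar(out$txR$sequence)),
               substr(tx$sequence, 201, nchar(tx$sequence)))

  # identity on empty table; warnings on bad rows
  expect_identical(apply_utr_overrides(txs, ov[0, ]), txs)
  expect_warning(apply_utr_overrides(txs, data.frame(
    gene_id = "gR", utr5_sequence = "ACGNN")), "skipped")
  expect_warning(apply_utr_overrides(txs, data.frame(
    gene_id = "nope", utr5_sequence = "ACGU")), "unknown gene")
})

test_that("5'UTR set extraction filters short and duplicate sequences", {
  mk <- function(id, gid, utr) {
    tx <- random_tx(utr5 = nchar(utr), cds = 60)
    tx$transcript_id <- id; tx$gene_id <- gid
    tx$sequence <- paste0(utr, substr(tx$sequence, nchar(utr) + 1,
                                      nchar(tx$sequence)))
    tx
  }
  set.seed(1)
  txs <- structure(list(
    a = mk("a", "g1", "ATGC"), b = mk("b", "g2", "ATG"),
    c = mk("c", "g3", "ATGC"), d = mk("d", "g4", "GGGC")),
    class = "transcript_set")
  out <- extract_utr5_set(txs)
  expect_setequal(out$sequence, c("ATGC", "GGGC"))
  out2 <- extract_utr5_set(txs, dedupe = FALSE)
  expect_equal(nrow(out2), 3L)
  expect_equal(nrow(extract_utr5_set(txs, expressed_genes = character(0))), 0L)
  expect_setequal(extract_utr5_set(txs, expressed_genes = c("g1", "g2"))$sequence,
                  "ATGC")
})

test_that("feature BED and UTR FASTA exports round-trip", {
  set.seed(3)
  txs <- structure(list(txR = random_tx()), class = "transcript_set")
  ft <- feature_table(txs)
  expect_equal(nrow(ft), 5L)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_features_bed(ft, bed)
  back <- read.delim(bed, header = FALSE)
  expect_equal(nrow(back), 5L)
  expect_true(all(back$V3 > back$V2 | back$V3 == back$V2))

  fa <- withr::local_tempfile(fileext = ".fa")
  write_utr5_fasta(extract_utr5_set(txs), fa)
  ss <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(ss[[1]]),
               substr(txs$txR$sequence, 1, txs$txR$cds_start_tx))
})
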
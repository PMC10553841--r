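mk_reads <- function(tx, pos, len = 28L, sample_id = "s1", offset = 12L) {
  data.frame(transcript_id = tx$transcript_id, five_prime_pos = pos - offset,
             length = len, sample_id = sample_id, stringsAsFactors = FALSE)
}

test_that("RPF length filter keeps the dominant 26-29 nt class", {
  reads <- data.frame(transcript_id = "t", five_prime_pos = 0,
                      length = c(25, 26, 28, 29, 30), sample_id = "s")
  suppressMessages(kept <- filter_rpf_lengths(reads))
  expect_setequal(kept$length, c(26, 28, 29))
  suppressMessages(expect_equal(nrow(filter_rpf_lengths(reads[0, ])), 0L))
  suppressMessages(expect_setequal(
    filter_rpf_lengths(reads, 28, 28)$length, 28))
  expect_error(filter_rpf_lengths(reads, 29, 26), "lo")
})

test_that("P-site offset calibration recovers planted offsets per length", {
  set.seed(5)
  txs <- structure(setNames(lapply(1:30, function(i) {
    tx <- random_tx(utr5 = 40, cds = 300); tx$transcript_id <- paste0("t", i)
    tx
  }), paste0("t", 1:30)), class = "transcript_set")
  plant <- function(offset) {
    do.call(rbind, lapply(txs, function(tx) {
      codons <- seq(tx$cds_start_tx, tx$cds_end_tx - 3L, by = 3L)
      # enough reads must overlap the start codon for calibration
      pos <- c(rep(codons[1], 20), sample(codons, 40, replace = TRUE))
      do.call(rbind, lapply(c(26L, 27L, 28L, 29L), function(len)
        mk_reads(tx, pos, len = len, offset = offset)))
    }))
  }
  off12 <- calibrate_psite_offset(plant(12L), txs)
  expect_true(all(off12 == 12L))
  off13 <- calibrate_psite_offset(plant(13L), txs)
  expect_true(all(off13 == 13L))
  # too few start-proximal reads: default with warning
  few <- plant(12L)[1:10, ]
  expect_warning(offd <- calibrate_psite_offset(few, txs), "default offset")
  expect_true(all(offd == 12L))
})

test_that("P-site assignment adds the offset and drops off-transcript sites", {
  tx <- random_tx(utr5 = 40, cds = 300)
  txs <- structure(list(txR = tx), class = "transcript_set")
  reads <- data.frame(transcript_id = "txR",
                      five_prime_pos = c(38L, nchar(tx$sequence) - 5L, 10L, 10L, 10L),
                      length = 28L,
                      sample_id = c("s1", "s1", "s1", "s1", "s2"))
  suppressMessages(ps <- assign_psites(reads, c(`28` = 12L), txs))
  expect_equal(ps$pos[1], 50L)
  expect_equal(nrow(ps), 4L)  # the off-end read dropped
  expect_equal(sum(ps$sample_id == "s2"), 1L)
  expect_error(assign_psites(data.frame(transcript_id = "txR",
                                        five_prime_pos = 1L, length = 31L,
                                        sample_id = "s"),
                             c(`28` = 12L), txs), "31")
})

test_that("feature counting places P-sites per the interval definitions", {
  features <- data.frame(
    transcript_id = "tx", gene_id = "g",
    feature = c("utr5", "tis", "first_cds_exon", "cds", "utr3"),
    start = c(0L, 37L, 50L, 50L, 350L),
    end = c(50L, 66L, 150L, 350L, 450L), stringsAsFactors = FALSE)
  ps <- data.frame(transcript_id = "tx", pos = c(10L, 40L, 60L, 200L, 420L),
                   sample_id = "s1", frame = 0)
  cm <- count_psites_by_feature(ps, features)
  got <- cm$counts[, "s1"]
  expect_equal(unname(got[paste0("g|", c("utr5", "tis", "first_cds_exon",
                                         "cds", "utr3"))]),
               c(2, 2, 1, 2, 1))

  # boundary: P-site exactly at cds_start counts in tis/first exon/cds only
  ps2 <- data.frame(transcript_id = "tx", pos = 50L, sample_id = "s1", frame = 0)
  got2 <- count_psites_by_feature(ps2, features)$counts[, "s1"]
  expect_equal(unname(got2[c("g|utr5", "g|tis", "g|first_cds_exon", "g|cds")]),
               c(0, 1, 1, 1))

  # all-zero rows are retained
  ps3 <- ps[0, ]
  cm3 <- count_psites_by_feature(ps3, features, sample_ids = "s1")
  expect_equal(nrow(cm3$counts), 5L)
  expect_true(all(cm3$counts == 0))

  # conservation: CDS feature counts equal P-sites inside the CDS interval
  set.seed(9)
  psr <- data.frame(transcript_id = "tx",
                    pos = sample(0:449, 500, replace = TRUE),
                    sample_id = "s1", frame = 0)
  cmr <- count_psites_by_feature(psr, features)
  expect_equal(unname(cmr$counts["g|cds", "s1"]),
               sum(psr$pos >= 50 & psr$pos < 350))
})

test_that("offset-shift equivariance: shifting reads and offsets cancels", {
  set.seed(11)
  tx <- random_tx(utr5 = 40, cds = 600)
  txs <- structure(list(txR = tx), class = "transcript_set")
  reads <- data.frame(transcript_id = "txR",
                      five_prime_pos = sample(20:500, 1000, replace = TRUE),
                      length = sample(26:29, 1000, replace = TRUE),
                      sample_id = "s1")
  offsets <- c(`26` = 12L, `27` = 12L, `28` = 12L, `29` = 13L)
  suppressMessages(a <- assign_psites(reads, offsets, txs))
  shifted <- reads
  shifted$five_prime_pos <- shifted$five_prime_pos + 3L
  suppressMessages(b <- assign_psites(shifted, offsets - 3L, txs))
  expect_identical(a, b)
})

test_that("metagene profiles recover planted frame fractions", {
  set.seed(13)
  tx <- random_tx(utr5 = 60, cds = 900)
  txs <- structure(list(txR = tx), class = "transcript_set")
  s <- tx$cds_start_tx
  codons <- seq(s, tx$cds_end_tx - 3L, 3L)
  # all frame 0
  ps0 <- data.frame(transcript_id = "txR",
                    pos = sample(codons, 2000, replace = TRUE),
                    sample_id = "s1")
  ps0$frame <- (ps0$pos - s) %% 3
  mg0 <- metagene_profile(ps0, txs)
  expect_equal(unname(mg0$frame_fractions), c(1, 0, 0))

  # planted mixture
  mix <- sample(0:2, 50000, replace = TRUE, prob = c(0.85, 0.10, 0.05))
  psm <- data.frame(transcript_id = "txR",
                    pos = sample(codons, 50000, replace = TRUE) + mix,
                    sample_id = "s1")
  psm$frame <- (psm$pos - s) %% 3
  mgm <- metagene_profile(psm, txs)
  expect_true(all(abs(mgm$frame_fractions - c(0.85, 0.10, 0.05)) < 0.02))
  expect_equal(sum(mgm$frame_fractions), 1, tolerance = 1e-9)

  # uniform positions: roughly equal frames
  psu <- data.frame(transcript_id = "txR",
                    pos = sample(seq(s, tx$cds_end_tx - 1L), 50000, replace = TRUE),
                    sample_id = "s1")
  psu$frame <- (psu$pos - s) %% 3
  mgu <- metagene_profile(psu, txs)
  expect_true(all(abs(mgu$frame_fractions - 1 / 3) < 0.02))

  # coverage sums to the number of in-window P-sites
  expect_equal(sum(mgm$coverage), mgm$n_psites)
})
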
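test_that("identity overlap merges to read 1", {
  a <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  m <- merge_read_pair(a, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(a))), min_overlap = 20)
  expect_true(m$ok)
  expect_identical(m$merged, a)
  expect_equal(m$overlap, 80L)
})

test_that("a 550 nt amplicon read as 300 bp pairs merges with 50 nt overlap", {
  amp <- withr::with_seed(1, paste(sample(c("A", "C", "G", "T"), 550, TRUE),
                                   collapse = ""))
  r1 <- substr(amp, 1, 300)
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(amp, 251, 550))))
  m <- merge_read_pair(r1, r2)
  expect_true(m$ok)
  expect_equal(nchar(m$merged), 550L)
  expect_equal(m$overlap, 50L)
  expect_identical(m$merged, amp)
})

test_that("pairs without a sufficient overlap fail to merge", {
  r1 <- strrep("ACGT", 25)
  r2 <- strrep("GGTTCC", 17)
  m <- merge_read_pair(r1, r2, min_overlap = 20, max_mismatch_rate = 0.02)
  expect_false(m$ok)
  expect_true(is.na(m$merged))
})

test_that("overlap disagreements resolve by Phred quality, ties to read 1", {
  a <- withr::with_seed(5, paste(sample(c("A", "C", "G", "T"), 40, TRUE),
                                 collapse = ""))
  b_seq <- a
  orig <- substr(a, 21, 21)
  alt <- setdiff(c("A", "C", "G", "T"), orig)[1]
  substr(b_seq, 21, 21) <- alt                           # mismatch at pos 21
  b <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b_seq)))
  hi <- strrep("I", 40)  # Q40
  lo <- strrep("#", 40)  # Q2
  m_tie <- merge_read_pairs(a, hi, b, hi, min_overlap = 10)
  expect_equal(substr(m_tie$merged, 21, 21), orig)       # read 1 wins ties
  m_q <- merge_read_pairs(a, lo, b, hi, min_overlap = 10)
  expect_equal(substr(m_q$merged, 21, 21), alt)          # higher quality wins
})

test_that("length filter keeps the inclusive window", {
  lens <- c(500, 550, 600, 850, 900)
  seqs <- vapply(lens, function(l) strrep("A", l), character(1))
  kept <- length_filter(seqs, 550, 850)
  expect_equal(nchar(kept), c(550, 600, 850))
  expect_length(length_filter(character(0), 550, 850), 0)
})

test_that("primer excision tolerates limited mismatches and anchors frame", {
  p <- default_primers()
  cds <- "ATGGCCCAGGTT"
  amp <- paste0(p$primer5, cds, p$primer3)
  expect_identical(extract_cds(amp), cds)
  # one substitution inside primer5 still extracts
  p5mut <- paste0("T", substring(p$primer5, 2))
  expect_identical(extract_cds(paste0(p5mut, cds, p$primer3)), cds)
  # missing 3' primer -> unparseable
  expect_true(is.na(extract_cds(paste0(p$primer5, cds,
                                       strrep("A", nchar(p$primer3))))))
})

test_that("annotation recovers simulated regions exactly on clean input", {
  lib <- small_library()
  ann <- annotate_vhh(lib$clones$nt_cds)
  expect_true(all(ann$complete))
  expect_identical(ann$cdr1_aa, lib$clones$cdr1_aa)
  expect_identical(ann$cdr2_aa, lib$clones$cdr2_aa)
  expect_identical(ann$cdr3_aa, lib$clones$cdr3_aa)
  expect_true(all(ann$anchor_fr1 & ann$anchor_fr2 & ann$anchor_fr3 &
                    ann$anchor_fr4))
})

test_that("region boundaries tile the sequence for complete records", {
  lib <- generate_library(small_config(n_clones = 400, seed = 12))
  ann <- annotate_vhh(lib$clones$nt_cds)
  ann <- ann[ann$complete, ]
  expect_gt(nrow(ann), 0)
  expect_true(all(ann$fr1_start == 0))
  expect_true(all(ann$fr1_end == ann$cdr1_start))
  expect_true(all(ann$cdr1_end == ann$fr2_start))
  expect_true(all(ann$fr2_end == ann$cdr2_start))
  expect_true(all(ann$cdr2_end == ann$fr3_start))
  expect_true(all(ann$fr3_end == ann$cdr3_start))
  expect_true(all(ann$cdr3_end == ann$fr4_start))
  expect_true(all(ann$fr4_end <= nchar(ann$aa)))
  expect_true(all(ann$cdr3_end - ann$cdr3_start >= 1 &
                    ann$cdr3_end - ann$cdr3_start <= 36))
})

test_that("internal stop codons and broken anchors mark records partial", {
  lib <- small_library()
  nt <- lib$clones$nt_cds[1]
  # replace the first CDR3 codon with a stop
  ann0 <- annotate_vhh(nt)
  stop_pos <- 3 * ann0$cdr3_start + 1
  nt_stop <- paste0(substr(nt, 1, stop_pos - 1), "TAA",
                    substr(nt, stop_pos + 3, nchar(nt)))
  expect_false(annotate_vhh(nt_stop)$complete)
  # mutate the conserved FR1 cysteine codon (TGT/TGC -> GGT)
  cys_pos <- 3 * (ann0$fr1_end - 1) + 1
  nt_cys <- paste0(substr(nt, 1, cys_pos - 1), "GGT",
                   substr(nt, cys_pos + 3, nchar(nt)))
  ann_cys <- annotate_vhh(nt_cys)
  expect_false(ann_cys$anchor_fr1)
  expect_false(ann_cys$complete)
  # ambiguous base inside a CDR -> partial
  nt_n <- paste0(substr(nt, 1, stop_pos - 1), "AAN",
                 substr(nt, stop_pos + 3, nchar(nt)))
  expect_false(annotate_vhh(nt_n)$complete)
})

test_that("drop_partials keeps exactly the complete records", {
  lib <- small_library()
  ann <- annotate_vhh(lib$clones$nt_cds[1:3])
  ann$complete <- c(TRUE, FALSE, TRUE)
  expect_equal(nrow(suppressMessages(drop_partials(ann))), 2)
  expect_equal(nrow(suppressMessages(drop_partials(ann[0, ]))), 0)
})

test_that("higher sequencing error never yields more complete records", {
  lib <- small_library()
  frac_complete <- vapply(c(0, 0.005, 0.02), function(e) {
    cfg <- small_config(reads_per_sample = 150, seq_error_rate = e)
    em <- withr::with_seed(33, emit_reads(lib$clones$initial_freq, lib, cfg))
    m <- merge_read_pairs(em$reads$r1, em$reads$q1, em$reads$r2,
                          em$reads$q2)
    cds <- extract_cds(m$merged[m$ok])
    mean(annotate_vhh(cds[!is.na(cds)])$complete)
  }, numeric(1))
  expect_true(all(diff(frac_complete) <= 0.02))  # sampling slack
  expect_equal(frac_complete[1], 1)
})
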
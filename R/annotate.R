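#' Excise the VHH coding sequence from an amplicon
#'
#' Locates the 5' and 3' flanking primers near the respective amplicon ends
#' (each allowing up to `max_primer_mismatches` substitutions and a start
#' shift of up to `max_shift` nt) and returns the enclosed sequence. The
#' reading frame downstream is anchored at the first base after the 5'
#' primer.
#'
#' @param amplicons Character vector of merged amplicon sequences.
#' @param primer5,primer3 Flanking primer sequences (see
#'   [default_primers()]).
#' @param max_primer_mismatches Substitutions tolerated within each primer.
#' @param max_shift Positional slack for each primer start, in nt.
#' @return Character vector of coding sequences; `NA` where either primer
#'   was not found (record unparseable).
#' @export
#' @examples
#' p <- default_primers()
#' extract_cds(paste0(p$primer5, "ATGGCC", p$primer3),
#'             p$primer5, p$primer3)
extract_cds <- function(amplicons, primer5 = default_primers()$primer5,
                        primer3 = default_primers()$primer3,
                        max_primer_mismatches = 2, max_shift = 3) {
  n <- length(amplicons)
  if (n == 0) return(character(0))
  len <- nchar(amplicons)
  n5 <- nchar(primer5)
  n3 <- nchar(primer3)

  hit5 <- scan_motif_cpp(amplicons, primer5, rep(0L, n),
                         rep(as.integer(max_shift), n))
  hit3 <- scan_motif_cpp(amplicons, primer3,
                         pmax(len - n3 - as.integer(max_shift), 0L),
                         len - n3)
  ok <- hit5[, 1] >= 0 & hit3[, 1] >= 0 &
    hit5[, 2] <= max_primer_mismatches &
    hit3[, 2] <= max_primer_mismatches
  start <- hit5[, 1] + n5 + 1L   # 1-based first CDS base
  end <- hit3[, 1]               # 0-based primer3 start == 1-based CDS end
  ok <- ok & end >= start
  out <- rep(NA_character_, n)
  out[ok] <- substring(amplicons[ok], start[ok], end[ok])
  out
}

#' Annotate VHH coding sequences against the scaffold consensus
#'
#' Translates each coding sequence in the anchored frame and places the
#' scaffold frameworks on the amino-acid sequence: FR1 is pinned at the
#' start, and FR2/FR3/FR4 are each located by a banded ungapped scan within
#' the window of admissible CDR lengths (the substitution-only equivalent of
#' a semi-global alignment in which the CDR segments are free-gap regions).
#' FR/CDR boundaries are transferred from the scaffold placement; the four
#' hallmark anchors are then verified: conserved Cys terminating FR1,
#' conserved Trp opening FR2, conserved Cys terminating FR3, and the
#' `[WF]-G-x-G` J-motif opening FR4.
#'
#' A record is `complete` only if all four anchors match, every framework
#' placement stays under `max_fr_mismatch_rate`, there is no internal stop
#' codon, no ambiguous residue (from an N base) falls inside a CDR, and the
#' CDR3 length lies in 1-36 aa. All reported boundaries are 0-based
#' half-open intervals on the amino-acid sequence.
#'
#' @param nt_cds Character vector of coding sequences (frame-anchored at
#'   base 1).
#' @param scaffold A [vhh_scaffold()].
#' @param max_fr_mismatch_rate Maximum per-framework mismatch rate for a
#'   placement to count as matched.
#' @param cdr1_window,cdr2_window,cdr3_window Admissible CDR length ranges
#'   (aa) used as scan bands; the CDR3 completeness check itself is fixed at
#'   1-36.
#' @return Data frame with one row per input: `nt_cds`, `aa`, region
#'   boundaries (`fr1_start`, `fr1_end`, `cdr1_start`, ..., `fr4_end`),
#'   `cdr1_aa`, `cdr2_aa`, `cdr3_aa`, the four `anchor_*` flags, and
#'   `complete`.
#' @export
#' @examples
#' lib <- generate_library(simulation_config(n_clones = 3,
#'                                           n_binders_per_subtype = 0,
#'                                           seed = 1))
#' ann <- annotate_vhh(lib$clones$nt_cds)
#' ann$complete
annotate_vhh <- function(nt_cds, scaffold = vhh_scaffold(),
                         max_fr_mismatch_rate = 0.2,
                         cdr1_window = c(1L, 20L),
                         cdr2_window = c(1L, 20L),
                         cdr3_window = c(0L, 45L)) {
  n <- length(nt_cds)
  out <- data.frame(
    nt_cds = nt_cds, aa = NA_character_,
    fr1_start = 0L, fr1_end = NA_integer_,
    cdr1_start = NA_integer_, cdr1_end = NA_integer_,
    fr2_start = NA_integer_, fr2_end = NA_integer_,
    cdr2_start = NA_integer_, cdr2_end = NA_integer_,
    fr3_start = NA_integer_, fr3_end = NA_integer_,
    cdr3_start = NA_integer_, cdr3_end = NA_integer_,
    fr4_start = NA_integer_, fr4_end = NA_integer_,
    cdr1_aa = NA_character_, cdr2_aa = NA_character_,
    cdr3_aa = NA_character_,
    anchor_fr1 = FALSE, anchor_fr2 = FALSE, anchor_fr3 = FALSE,
    anchor_fr4 = FALSE, complete = FALSE, stringsAsFactors = FALSE)
  if (n == 0) return(out)

  translatable <- !is.na(nt_cds) & nchar(nt_cds) >= 3
  aa <- rep(NA_character_, n)
  aa[translatable] <- translate_frame(nt_cds[translatable])
  out$aa <- aa
  alen <- ifelse(is.na(aa), 0L, nchar(aa))

  l1 <- nchar(scaffold$fr1); l2 <- nchar(scaffold$fr2)
  l3 <- nchar(scaffold$fr3); l4 <- nchar(scaffold$fr4)
  aa_scan <- ifelse(is.na(aa), "", aa)

  # FR1 pinned at position 0
  h1 <- scan_motif_cpp(aa_scan, scaffold$fr1, rep(0L, n), rep(0L, n))
  fr1_ok <- h1[, 1] == 0 & h1[, 2] <= max_fr_mismatch_rate * l1
  out$anchor_fr1 <- fr1_ok & substring(aa_scan, l1, l1) == "C"
  out$fr1_end <- ifelse(alen >= l1, l1, NA_integer_)

  # FR2 within the CDR1 band
  h2 <- scan_motif_cpp(aa_scan, scaffold$fr2,
                       rep(l1 + cdr1_window[1], n),
                       rep(l1 + cdr1_window[2], n))
  fr2_found <- h2[, 1] >= 0
  fr2_ok <- fr2_found & h2[, 2] <= max_fr_mismatch_rate * l2
  fr2_start <- ifelse(fr2_found, h2[, 1], NA_integer_)
  out$fr2_start <- fr2_start
  out$fr2_end <- fr2_start + l2
  out$cdr1_start <- ifelse(fr2_found, l1, NA_integer_)
  out$cdr1_end <- fr2_start
  out$anchor_fr2 <- fr2_ok &
    substring(aa_scan, fr2_start + 1L, fr2_start + 1L) == "W"

  # FR3 within the CDR2 band (window collapses to empty where FR2 missing)
  lo3 <- ifelse(fr2_found, fr2_start + l2 + cdr2_window[1], 1L)
  hi3 <- ifelse(fr2_found, fr2_start + l2 + cdr2_window[2], 0L)
  h3 <- scan_motif_cpp(aa_scan, scaffold$fr3, as.integer(lo3),
                       as.integer(hi3))
  fr3_found <- h3[, 1] >= 0
  fr3_ok <- fr3_found & h3[, 2] <= max_fr_mismatch_rate * l3
  fr3_start <- ifelse(fr3_found, h3[, 1], NA_integer_)
  out$fr3_start <- fr3_start
  out$fr3_end <- fr3_start + l3
  out$cdr2_start <- ifelse(fr3_found, fr2_start + l2, NA_integer_)
  out$cdr2_end <- fr3_start
  out$anchor_fr3 <- fr3_ok &
    substring(aa_scan, fr3_start + l3, fr3_start + l3) == "C"

  # FR4 within the CDR3 band
  lo4 <- ifelse(fr3_found, fr3_start + l3 + cdr3_window[1], 1L)
  hi4 <- ifelse(fr3_found, fr3_start + l3 + cdr3_window[2], 0L)
  h4 <- scan_motif_cpp(aa_scan, scaffold$fr4, as.integer(lo4),
                       as.integer(hi4))
  fr4_found <- h4[, 1] >= 0
  fr4_ok <- fr4_found & h4[, 2] <= max_fr_mismatch_rate * l4
  fr4_start <- ifelse(fr4_found, h4[, 1], NA_integer_)
  out$fr4_start <- fr4_start
  out$fr4_end <- fr4_start + l4
  out$cdr3_start <- ifelse(fr4_found, fr3_start + l3, NA_integer_)
  out$cdr3_end <- fr4_start
  out$anchor_fr4 <- fr4_ok &
    grepl("^[WF]G.G", substring(aa_scan, fr4_start + 1L, fr4_start + 4L))

  cdr_sub <- function(s0, s1) {
    res <- rep(NA_character_, n)
    i <- !is.na(s0) & !is.na(s1)
    res[i] <- substring(aa_scan[i], s0[i] + 1L, s1[i])
    res
  }
  out$cdr1_aa <- cdr_sub(out$cdr1_start, out$cdr1_end)
  out$cdr2_aa <- cdr_sub(out$cdr2_start, out$cdr2_end)
  out$cdr3_aa <- cdr_sub(out$cdr3_start, out$cdr3_end)

  cdr3_len <- out$cdr3_end - out$cdr3_start
  body <- cdr_sub(rep(0L, n), out$fr4_end)
  no_stop <- !is.na(body) & !grepl("*", body, fixed = TRUE)
  no_ambig <- !grepl("X", paste0(out$cdr1_aa, out$cdr2_aa, out$cdr3_aa),
                     fixed = TRUE)
  out$complete <- out$anchor_fr1 & out$anchor_fr2 & out$anchor_fr3 &
    out$anchor_fr4 & no_stop & no_ambig &
    !is.na(cdr3_len) & cdr3_len >= 1 & cdr3_len <= 36 &
    (out$cdr1_end - out$cdr1_start) >= 1 &
    (out$cdr2_end - out$cdr2_start) >= 1
  out
}

# translate in frame 1, trailing partial codon truncated; fuzzy codons -> X
translate_frame <- function(nt) {
  keep <- 3L * (nchar(nt) %/% 3L)
  trimmed <- substring(nt, 1L, keep)
  as.character(Biostrings::translate(Biostrings::DNAStringSet(trimmed),
                                     if.fuzzy.codon = "X"))
}

#' Keep only completely assembled VHH records
#'
#' @param records Data frame from [annotate_vhh()].
#' @param quiet Suppress the retained/dropped message.
#' @return The complete records.
#' @export
drop_partials <- function(records, quiet = FALSE) {
  keep <- !is.na(records$complete) & records$complete
  if (!quiet) {
    message(sprintf("drop_partials: retained %d / %d records",
                    sum(keep), nrow(records)))
  }
  records[keep, , drop = FALSE]
}
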
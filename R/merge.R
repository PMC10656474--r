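#' Merge paired-end reads by overlap consensus
#'
#' Reverse-complements read 2, scans candidate overlaps of at least
#' `min_overlap` bases, and keeps the offset minimizing the mismatch rate
#' (ties going to the larger overlap). A pair merges only if the best rate is
#' at most `max_mismatch_rate`; within the overlap, disagreeing bases are
#' resolved toward the higher Phred quality (ties toward read 1). Failed
#' pairs are kept in the output with `ok = FALSE` so the caller can count
#' them.
#'
#' @param r1,r2 Character vectors of read sequences (mate 1, mate 2).
#' @param q1,q2 Matching Phred-33 quality strings.
#' @param min_overlap Minimum acceptable overlap length in nt.
#' @param max_mismatch_rate Maximum mismatch rate within the overlap.
#' @param id Optional read identifiers carried through.
#' @return Data frame with `id`, `merged`, `quality`, `overlap`,
#'   `mismatches`, `mean_quality`, `ok`.
#' @export
#' @examples
#' a <- "ACGTACGTACGTACGTACGTACGT"
#' merge_read_pairs(a, strrep("I", 24),
#'                  as.character(Biostrings::reverseComplement(
#'                    Biostrings::DNAString(a))),
#'                  strrep("I", 24), min_overlap = 10)
merge_read_pairs <- function(r1, q1, r2, q2, min_overlap = 20,
                             max_mismatch_rate = 0.05, id = NULL) {
  assert_that(length(r1) == length(r2) && length(r1) == length(q1) &&
                length(r1) == length(q2),
              "r1, q1, r2, q2 must have equal length")
  if (length(r1) == 0) {
    return(data.frame(id = character(0), merged = character(0),
                      quality = character(0), overlap = integer(0),
                      mismatches = integer(0), mean_quality = numeric(0),
                      ok = logical(0), stringsAsFactors = FALSE))
  }
  res <- merge_pairs_cpp(r1, q1, revcomp(r2), reverse_chars(q2),
                         as.integer(min_overlap), max_mismatch_rate)
  data.frame(id = id %||% paste0("pair", seq_along(r1)),
             merged = res$merged, quality = res$quality,
             overlap = res$overlap, mismatches = res$mismatches,
             mean_quality = res$mean_quality, ok = res$ok,
             stringsAsFactors = FALSE)
}

#' Merge a single read pair
#'
#' Scalar convenience wrapper around [merge_read_pairs()].
#'
#' @inheritParams merge_read_pairs
#' @param read1,read2 Read sequences.
#' @param qual1,qual2 Phred-33 quality strings; default assumes Q40.
#' @return A list (`merged`, `quality`, `overlap`, `mismatches`,
#'   `mean_quality`, `ok`); `ok = FALSE` marks a merge failure.
#' @export
merge_read_pair <- function(read1, read2,
                            qual1 = strrep("I", nchar(read1)),
                            qual2 = strrep("I", nchar(read2)),
                            min_overlap = 20, max_mismatch_rate = 0.05) {
  as.list(merge_read_pairs(read1, qual1, read2, qual2,
                           min_overlap = min_overlap,
                           max_mismatch_rate = max_mismatch_rate)[1, -1])
}

#' Retain amplicons within a length window
#'
#' Mirrors the gel size selection applied to the sequencing library; the
#' default window keeps the 550-850 bp band. Bounds are inclusive.
#'
#' @param amplicons Data frame from [merge_read_pairs()] (filtered on the
#'   `merged` column) or a character vector of sequences.
#' @param min_len,max_len Inclusive length bounds in nt.
#' @return Input with out-of-window (or unmerged) records removed.
#' @export
#' @examples
#' length_filter(c(strrep("A", 500), strrep("A", 600)), 550, 850)
length_filter <- function(amplicons, min_len = 550, max_len = 850) {
  assert_that(min_len <= max_len, "min_len must be <= max_len")
  if (is.character(amplicons)) {
    len <- nchar(amplicons)
    return(amplicons[!is.na(amplicons) & len >= min_len & len <= max_len])
  }
  len <- nchar(amplicons$merged)
  keep <- amplicons$ok & !is.na(len) & len >= min_len & len <= max_len
  amplicons[keep, , drop = FALSE]
}

#' Drop merged amplicons with low mean base quality
#'
#' @param amplicons Data frame from [merge_read_pairs()].
#' @param min_mean_q Minimum mean Phred quality over the merged amplicon.
#' @return Filtered data frame.
#' @export
quality_filter <- function(amplicons, min_mean_q = 20) {
  keep <- amplicons$ok & !is.na(amplicons$mean_quality) &
    amplicons$mean_quality >= min_mean_q
  amplicons[keep, , drop = FALSE]
}
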
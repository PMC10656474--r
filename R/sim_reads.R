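#' Per-cycle substitution-error profile
#'
#' Error probability per sequencing cycle: a linear Phred decline from Q38
#' (first cycle) to Q22 (last cycle), rescaled so the mean per-base error
#' equals `mean_rate`. The matching Phred values are what the emitted quality
#' strings encode, so quality-aware merging sees the true error model.
#'
#' @param read_length Read length in cycles.
#' @param mean_rate Mean per-base substitution probability.
#' @return List with `rate` (per-cycle probabilities) and `phred`
#'   (integer per-cycle quality scores).
#' @export
error_profile <- function(read_length, mean_rate) {
  if (mean_rate <= 0) {
    return(list(rate = rep(0, read_length),
                phred = rep(40L, read_length)))
  }
  shape <- 10^(-seq(38, 22, length.out = read_length) / 10)
  rate <- shape * (mean_rate / mean(shape))
  rate <- pmin(rate, 0.75)
  list(rate = rate,
       phred = pmin(pmax(as.integer(round(-10 * log10(rate))), 2L), 41L))
}

#' Emit paired sequencing reads for one sample
#'
#' Draws `reads_per_sample` read pairs with clone probabilities proportional
#' to `weights`, builds each amplicon as `primer5 + nt_cds + primer3`, takes
#' read 1 as the first `read_length` bases and read 2 as the reverse
#' complement of the last `read_length` bases, and applies independent
#' per-base substitutions following [error_profile()]. Uses the current RNG
#' state (the simulation driver supplies a per-sample substream).
#'
#' @param weights Nonnegative per-clone sampling weights (counts or
#'   frequencies).
#' @param library A [generate_library()] result.
#' @param config A [simulation_config()].
#' @param sample_id Prefix for read identifiers.
#' @return List with `counts` (realized per-clone read counts, summing to
#'   `reads_per_sample`) and `reads` (list `id`, `r1`, `q1`, `r2`, `q2`).
#' @export
emit_reads <- function(weights, library, config, sample_id = "sample") {
  n <- config$n_clones
  assert_that(length(weights) == n, "weights must have one entry per clone")
  assert_that(all(weights >= 0), "weights must be nonnegative")
  L <- config$read_length
  p5 <- config$primers$primer5
  p3 <- config$primers$primer3
  min_amp <- nchar(p5) + nchar(p3) + 3 * min_cds_aa(config)
  if (min_amp < L) {
    stop("amplicons can be shorter than read_length; reads would run off ",
         "the template (configuration error)", call. = FALSE)
  }

  nreads <- config$reads_per_sample
  if (nreads == 0 || sum(weights) == 0) {
    empty <- list(id = character(0), r1 = character(0), q1 = character(0),
                  r2 = character(0), q2 = character(0))
    return(list(counts = integer(n), reads = empty))
  }
  counts <- as.integer(rmultinom(1, nreads, weights / sum(weights)))
  nz <- which(counts > 0)
  amp <- paste0(p5, library$clones$nt_cds[nz], p3)
  alen <- nchar(amp)
  assert_that(all(alen >= L), "amplicon shorter than read length")

  idx <- rep(seq_along(nz), counts[nz])
  idx <- idx[sample.int(length(idx))]  # shuffle read order
  r1 <- substring(amp[idx], 1L, L)
  r2 <- revcomp(substring(amp[idx], alen[idx] - L + 1L, alen[idx]))

  prof <- error_profile(L, config$seq_error_rate)
  r1 <- apply_substitutions(r1, prof$rate)
  r2 <- apply_substitutions(r2, prof$rate)
  qual <- phred_to_char(prof$phred)

  reads <- list(
    id = sprintf("%s:%06d %s", sample_id, seq_along(idx),
                 library$clones$clone_id[nz][idx]),
    r1 = r1, q1 = rep(qual, length(idx)),
    r2 = r2, q2 = rep(qual, length(idx)))
  list(counts = counts, reads = reads)
}

min_cds_aa <- function(config) {
  sum(config$scaffold$fr_lengths) + config$cdr1_length_range[1] +
    config$cdr2_length_range[1] +
    min(as.integer(names(config$cdr3_length_law)[config$cdr3_length_law > 0]))
}

# independent per-base substitutions with position-dependent rates
apply_substitutions <- function(reads, rate) {
  if (length(reads) == 0 || all(rate == 0)) return(reads)
  L <- length(rate)
  n <- length(reads)
  bases <- c("A", "C", "G", "T")
  for (j in seq_len(L)) {
    if (rate[j] == 0) next
    hit <- which(runif(n) < rate[j])
    for (i in hit) {
      orig <- substr(reads[i], j, j)
      sub <- sample(setdiff(bases, orig), 1)
      substr(reads[i], j, j) <- sub
    }
  }
  reads
}
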
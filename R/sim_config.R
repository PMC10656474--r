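#' Default CDR3 amino-acid length distribution
#'
#' Discrete distribution on 1..36 aa calibrated so the median length is 18:
#' a shifted binomial core (mode near 17-18) mixed with a small uniform
#' component that reproduces the long observed tails out to the extremes of
#' the 1-36 range.
#'
#' @param mix Weight of the uniform tail component.
#' @return Named numeric vector of probabilities over lengths `1:36`.
#' @export
#' @examples
#' pmf <- default_cdr3_pmf()
#' sum(pmf)  # 1
default_cdr3_pmf <- function(mix = 0.02) {
  core <- stats::dbinom(0:35, size = 35, prob = 17 / 35)
  pmf <- (1 - mix) * core + mix / 36
  names(pmf) <- 1:36
  pmf / sum(pmf)
}

#' Simulation configuration for synthetic biopanning
#'
#' Collects every parameter of the synthetic biopanning generator: library
#' composition, planted binder structure, per-round selection and
#' amplification, and the sequencing readout. Defaults emulate the study
#' conditions of an in vivo VHH biopanning campaign (CDR3 lengths median 18,
#' range 1-36; five sorted cell subtypes per round seeded from the bulk CD45
#' pool; four selection rounds; ~600 bp amplicons read as 300 bp pairs;
#' ~450,000 reads per sample), scaled down by `scale_factor` to desk size.
#'
#' @param n_clones Number of distinct clones in the naive library.
#' @param abundance_law Lognormal parameters (`meanlog`, `sdlog`) for initial
#'   clone frequencies (normalized to sum to 1).
#' @param cdr3_length_law Probability vector over CDR3 lengths `1:36`
#'   (see [default_cdr3_pmf()]).
#' @param cdr1_length_range,cdr2_length_range Inclusive integer ranges for
#'   CDR1/CDR2 amino-acid lengths (uniform).
#' @param n_binders_per_subtype Number of clones planted as binders for each
#'   of the five sorted subtypes.
#' @param affinity_law Lognormal parameters for the binder affinity
#'   multiplier kappa (capture weight relative to background).
#' @param background_affinity Baseline capture weight of non-binders.
#' @param shared_binders If `TRUE`, binder sets may overlap across subtypes;
#'   default `FALSE` keeps them disjoint for clean recovery bookkeeping.
#' @param amplification_noise_sd Per-clone log-scale SD of the multiplicative
#'   lognormal amplification perturbation applied after each capture.
#' @param capture_size Phage captured per subtype per round; `NULL` draws a
#'   value uniformly in `[4e6, 6e7] * scale_factor` per round x subtype.
#' @param scale_factor Desk-scale shrink factor applied to capture sizes and
#'   (when `reads_per_sample` is `NULL`) to the 450,000-read sequencing depth.
#' @param reads_per_sample Read pairs sequenced per sample; `NULL` means
#'   `round(450000 * scale_factor)`.
#' @param read_length Read length of each mate (PE300 default).
#' @param seq_error_rate Mean per-base substitution probability. Errors follow
#'   a per-cycle Phred profile declining linearly from Q38 to Q22 across the
#'   read, rescaled so the mean equals this value; quality strings encode the
#'   per-cycle error probabilities.
#' @param n_rounds Number of biopanning rounds after BP0.
#' @param n_replicates Sequencing replicates per round x subtype.
#' @param primers Amplicon flanks (see [default_primers()]).
#' @param scaffold VHH framework consensus (see [vhh_scaffold()]).
#' @param subtypes Cell-subtype roster; first entry is the bulk pool that
#'   seeds the next round.
#' @param seed Integer seed (required); all randomness derives from it.
#' @return A list of class `simulation_config`.
#' @export
#' @examples
#' cfg <- simulation_config(n_clones = 100, seed = 1)
#' cfg$reads_per_sample
simulation_config <- function(n_clones = 5000,
                              abundance_law = c(meanlog = 0, sdlog = 1),
                              cdr3_length_law = default_cdr3_pmf(),
                              cdr1_length_range = c(6L, 10L),
                              cdr2_length_range = c(5L, 9L),
                              n_binders_per_subtype = 20,
                              affinity_law = c(meanlog = log(8), sdlog = 0.3),
                              background_affinity = 1,
                              shared_binders = FALSE,
                              amplification_noise_sd = 0.15,
                              capture_size = NULL,
                              scale_factor = 0.01,
                              reads_per_sample = NULL,
                              read_length = 300L,
                              seq_error_rate = 1e-3,
                              n_rounds = 4L,
                              n_replicates = 3L,
                              primers = default_primers(),
                              scaffold = vhh_scaffold(),
                              subtypes = subtype_roster(),
                              seed) {
  if (missing(seed) || is.null(seed)) {
    stop("simulation_config() requires an explicit integer `seed`",
         call. = FALSE)
  }
  if (is.null(reads_per_sample)) {
    reads_per_sample <- as.integer(round(450000 * scale_factor))
  }
  cfg <- structure(
    list(n_clones = as.integer(n_clones),
         abundance_law = abundance_law,
         cdr3_length_law = cdr3_length_law,
         cdr1_length_range = as.integer(cdr1_length_range),
         cdr2_length_range = as.integer(cdr2_length_range),
         n_binders_per_subtype = as.integer(n_binders_per_subtype),
         affinity_law = affinity_law,
         background_affinity = background_affinity,
         shared_binders = isTRUE(shared_binders),
         amplification_noise_sd = amplification_noise_sd,
         capture_size = capture_size,
         scale_factor = scale_factor,
         reads_per_sample = as.integer(reads_per_sample),
         read_length = as.integer(read_length),
         seq_error_rate = seq_error_rate,
         n_rounds = as.integer(n_rounds),
         n_replicates = as.integer(n_replicates),
         primers = primers,
         scaffold = scaffold,
         subtypes = subtypes,
         seed = as.integer(seed)),
    class = "simulation_config")
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  assert_that(cfg$n_clones >= 1, "n_clones must be >= 1")
  pmf <- cfg$cdr3_length_law
  assert_that(!is.null(names(pmf)) &&
                all(as.integer(names(pmf)) %in% 1:36),
              "cdr3_length_law support must lie in 1..36 (named vector)")
  assert_that(all(pmf >= 0) && abs(sum(pmf) - 1) < 1e-9,
              "cdr3_length_law probabilities must be nonnegative and sum to 1")
  n_sel <- length(cfg$subtypes) - 1L
  if (!cfg$shared_binders &&
      cfg$n_binders_per_subtype * n_sel > cfg$n_clones) {
    stop("n_binders_per_subtype x ", n_sel,
         " subtypes exceeds n_clones; cannot plant disjoint binder sets",
         call. = FALSE)
  }
  assert_that(cfg$background_affinity > 0, "background_affinity must be > 0")
  assert_that(cfg$amplification_noise_sd >= 0,
              "amplification_noise_sd must be >= 0")
  assert_that(cfg$seq_error_rate >= 0 && cfg$seq_error_rate < 0.1,
              "seq_error_rate must be in [0, 0.1)")
  assert_that(cfg$read_length >= 50, "read_length must be >= 50")
  assert_that(cfg$n_rounds >= 1 && cfg$n_replicates >= 1,
              "n_rounds and n_replicates must be >= 1")
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Biopanning simulation config\n")
  cat(sprintf("  library: %d clones, %d binders/subtype (%s)\n",
              x$n_clones, x$n_binders_per_subtype,
              if (x$shared_binders) "shared" else "disjoint"))
  cat(sprintf("  rounds: BP0 + %d, subtypes: %s, replicates: %d\n",
              x$n_rounds, paste(x$subtypes, collapse = ", "),
              x$n_replicates))
  cat(sprintf("  sequencing: %d x %d bp pairs/sample, error %.2g\n",
              x$reads_per_sample, x$read_length, x$seq_error_rate))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
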
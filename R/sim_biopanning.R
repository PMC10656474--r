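#' Simulate one round of phage capture and amplification
#'
#' Capture is a multinomial draw of `capture_size` phage with per-clone
#' probabilities proportional to `freqs * affinity`; amplification perturbs
#' the captured counts clone-wise by `exp(Normal(0, amplification_noise_sd))`
#' and renormalizes. Uses the current RNG state; [simulate_biopanning()]
#' wraps each call in a deterministic substream derived from
#' `(seed, round, subtype)`.
#'
#' @param freqs Clone frequency vector summing to 1.
#' @param affinity Positive capture-weight vector (same length as `freqs`);
#'   background clones have weight `background_affinity`, planted binders
#'   carry their kappa multiplier.
#' @param config A [simulation_config()].
#' @param capture_size Number of phage captured; `NULL` draws uniformly in
#'   `[4e6, 6e7] * scale_factor`.
#' @return List with `captured` (integer counts), `amplified_freq`
#'   (post-amplification frequencies), `expected_freq` (exact post-selection
#'   probabilities `freqs * affinity / sum`), and `capture_size`.
#' @export
#' @examples
#' f <- rep(0.25, 4)
#' r <- simulate_round(f, c(1, 1, 1, 8), simulation_config(seed = 1),
#'                     capture_size = 1e5)
#' r$expected_freq
simulate_round <- function(freqs, affinity, config, capture_size = NULL) {
  assert_that(abs(sum(freqs) - 1) < 1e-6, "freqs must sum to 1")
  assert_that(length(affinity) == length(freqs),
              "affinity and freqs must have equal length")
  assert_that(all(affinity > 0), "affinities must be positive")
  if (is.null(capture_size)) capture_size <- draw_capture_size(config)
  w <- freqs * affinity
  p <- w / sum(w)
  captured <- as.integer(rmultinom(1, capture_size, p))
  if (config$amplification_noise_sd > 0) {
    amp <- captured * exp(rnorm(length(captured), 0,
                                config$amplification_noise_sd))
  } else {
    amp <- as.numeric(captured)
  }
  amplified <- if (sum(amp) > 0) amp / sum(amp) else p
  list(captured = captured, amplified_freq = amplified,
       expected_freq = p, capture_size = as.integer(capture_size))
}

draw_capture_size <- function(config) {
  if (!is.null(config$capture_size)) return(as.integer(config$capture_size))
  max(1L, as.integer(round(runif(1, 4e6, 6e7) * config$scale_factor)))
}

#' Simulate a full multi-round biopanning campaign
#'
#' Runs BP0 (bulk-pool capture of the injected library) followed by
#' `n_rounds` rounds in which every subtype pool is captured from the
#' current bulk pool; the input pool for round `r + 1` is the amplified bulk
#' (CD45) pool of round `r`, so the sorted subtype streams are measurements
#' of the lineage, not lineages themselves. Each round x subtype x replicate
#' sample is then sequenced as a multinomial draw of `reads_per_sample` read
#' pairs; replicates are independent sequencing draws from the same captured
#' pool. All draws run in substreams derived from `(seed, round, subtype,
#' replicate)`, so outputs are byte-identical for a fixed seed.
#'
#' @param config A [simulation_config()].
#' @param library Optional pre-built [generate_library()] result (must match
#'   the config); `NULL` generates one.
#' @param emit `"counts"` records only per-clone read counts (fast);
#'   `"reads"` additionally synthesizes paired reads in memory;
#'   `"files"` writes paired FASTQ (plus truth/library files) to `out_dir`.
#' @param out_dir Output directory for `emit = "files"`.
#' @return An object of class `biopanning_sim`: the `library`, `pools`
#'   (clones x rounds matrix of input-pool frequencies), `post_selection`
#'   (per round, clones x subtypes matrix of exact post-selection
#'   frequencies), `truth` (data frame: `clone_id`, `round`, `subtype`,
#'   `replicate`, `true_freq`, `reads`; rows with `reads > 0`), `samples`
#'   (per-sample bookkeeping), and `reads` (per-sample read sets, unless
#'   `emit = "counts"`).
#' @export
#' @examples
#' cfg <- simulation_config(n_clones = 200, n_binders_per_subtype = 2,
#'                          reads_per_sample = 200, n_replicates = 1,
#'                          capture_size = 1e4, seed = 7)
#' sim <- simulate_biopanning(cfg, emit = "counts")
#' head(sim$truth)
simulate_biopanning <- function(config, library = NULL,
                                emit = c("counts", "reads", "files"),
                                out_dir = NULL) {
  emit <- match.arg(emit)
  if (emit == "files") {
    assert_that(!is.null(out_dir), "emit = \"files\" requires out_dir")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  lib <- library %||% generate_library(config)
  n <- config$n_clones
  subtypes <- config$subtypes
  bulk <- subtypes[1]
  rounds <- 0:config$n_rounds

  pools <- matrix(NA_real_, n, length(rounds),
                  dimnames = list(lib$clones$clone_id,
                                  paste0("BP", rounds)))
  pools[, 1] <- lib$clones$initial_freq
  post <- vector("list", length(rounds))
  names(post) <- paste0("BP", rounds)

  cur <- lib$clones$initial_freq
  for (r in rounds) {
    active <- if (r == 0) bulk else subtypes
    mat <- matrix(NA_real_, n, length(active),
                  dimnames = list(lib$clones$clone_id, active))
    amp <- vector("list", length(active))
    names(amp) <- active
    for (s in active) {
      res <- withr::with_seed(
        derive_seed(config$seed, "round", r, s),
        simulate_round(cur, lib$affinity[, s], config))
      mat[, s] <- res$expected_freq
      amp[[s]] <- res$amplified_freq
    }
    post[[paste0("BP", r)]] <- mat
    cur <- amp[[bulk]]
    if (r < config$n_rounds) pools[, r + 2] <- cur
    attr(post, paste0("amp_BP", r)) <- amp
  }

  truth <- list()
  samples <- list()
  read_sets <- list()
  for (r in rounds) {
    active <- if (r == 0) bulk else subtypes
    amp <- attr(post, paste0("amp_BP", r))
    for (s in active) {
      for (rep_i in seq_len(config$n_replicates)) {
        sid <- sprintf("BP%d_%s_rep%d", r, s, rep_i)
        sub_seed <- derive_seed(config$seed, "reads", r, s, rep_i)
        if (emit == "counts") {
          counts <- withr::with_seed(
            sub_seed,
            as.integer(rmultinom(1, config$reads_per_sample, amp[[s]])))
          reads <- NULL
        } else {
          em <- withr::with_seed(
            sub_seed, emit_reads(amp[[s]], lib, config, sample_id = sid))
          counts <- em$counts
          reads <- em$reads
        }
        nz <- which(counts > 0)
        truth[[sid]] <- data.frame(
          clone_id = lib$clones$clone_id[nz],
          round = paste0("BP", r), subtype = s, replicate = rep_i,
          true_freq = post[[paste0("BP", r)]][nz, s],
          reads = counts[nz], stringsAsFactors = FALSE)
        samples[[sid]] <- data.frame(
          sample_id = sid, round = paste0("BP", r), subtype = s,
          replicate = rep_i, reads = sum(counts),
          stringsAsFactors = FALSE)
        if (emit == "files" && !is.null(reads)) {
          write_fastq_pair(reads,
                           file.path(out_dir, paste0(sid, "_R1.fastq")),
                           file.path(out_dir, paste0(sid, "_R2.fastq")))
          read_sets[[sid]] <- list(
            r1 = file.path(out_dir, paste0(sid, "_R1.fastq")),
            r2 = file.path(out_dir, paste0(sid, "_R2.fastq")))
        } else if (emit == "reads") {
          read_sets[[sid]] <- reads
        }
      }
    }
  }

  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  samples <- do.call(rbind, samples)
  rownames(samples) <- NULL

  out <- structure(
    list(library = lib, config = config, pools = pools,
         post_selection = post, truth = truth, samples = samples,
         reads = if (emit == "counts") NULL else read_sets),
    class = "biopanning_sim")
  if (emit == "files") {
    write_truth_table(truth, file.path(out_dir, "truth.tsv"))
    write_fasta(setNames(lib$clones$nt_cds, lib$clones$clone_id),
                file.path(out_dir, "library.fasta"))
  }
  out
}

#' @export
print.biopanning_sim <- function(x, ...) {
  cat(sprintf("Biopanning simulation: %d clones, BP0-BP%d, %d samples\n",
              x$config$n_clones, x$config$n_rounds, nrow(x$samples)))
  invisible(x)
}

#' Write a simulation truth table as TSV
#'
#' @param truth Truth data frame from [simulate_biopanning()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
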
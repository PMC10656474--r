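# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small error-free library + matching reads for round-trip checks
small_config <- function(n_clones = 60, seed = 42, reads_per_sample = 0,
                         seq_error_rate = 0, ...) {
  simulation_config(n_clones = n_clones, n_binders_per_subtype = 0,
                    reads_per_sample = reads_per_sample,
                    seq_error_rate = seq_error_rate,
                    n_replicates = 1, capture_size = 5000, seed = seed, ...)
}

small_library <- function() {
  memo("small_library", function() generate_library(small_config()))
}

# build exact read pairs (no errors) straight from clone amplicons
exact_pairs <- function(lib, read_length = 300) {
  cfg <- lib$config
  amp <- paste0(cfg$primers$primer5, lib$clones$nt_cds, cfg$primers$primer3)
  alen <- nchar(amp)
  q <- strrep(rawToChar(as.raw(40 + 33)), read_length)
  list(r1 = substring(amp, 1, read_length),
       q1 = rep(q, length(amp)),
       r2 = as.character(Biostrings::reverseComplement(
         Biostrings::DNAStringSet(substring(amp, alen - read_length + 1,
                                            alen)))),
       q2 = rep(q, length(amp)),
       amplicon = amp)
}

# clonotype tables with random counts, for property checks
random_tables <- function(n_tables = 10, seed = 7) {
  withr::with_seed(seed, lapply(seq_len(n_tables), function(i) {
    k <- sample(3:25, 1)
    counts <- pmax(1, stats::rpois(k, lambda = sample(c(1, 3, 10), 1)))
    clonotype_table(sprintf("key%02d", seq_len(k)), counts)
  }))
}

# toy 4-round series from explicit count vectors (named by key)
toy_series <- function(..., key_level = "full_aa") {
  counts <- list(...)
  tabs <- lapply(counts, function(x) {
    clonotype_table(names(x), as.numeric(x), key_level = key_level)
  })
  names(tabs) <- paste0("BP", seq_along(tabs))
  biopanning_series(tabs)
}
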
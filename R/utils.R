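#' Derive a reproducible substream seed
#'
#' Folds a base seed and an arbitrary sequence of labels (round, subtype,
#' replicate, stage name, ...) into a deterministic 31-bit seed, so that every
#' sample in a simulation draws from its own independent, reproducible
#' substream.
#'
#' @param seed Integer base seed.
#' @param ... Labels (character or integer scalars) identifying the substream.
#' @return An integer in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "BP1", "CD11c", 2)
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (part in list(...)) {
    for (ch in utf8ToInt(paste0("|", as.character(part)))) {
      h <- (h * 131 + ch) %% m
    }
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# reverse complement on plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

reverse_chars <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

phred_to_char <- function(q) {
  q <- pmin(pmax(as.integer(round(q)), 0L), 93L)
  intToUtf8(q + 33L, multiple = FALSE)
}

char_to_phred <- function(s) utf8ToInt(s) - 33L
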
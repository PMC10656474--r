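#' Ordered collection of clonotype tables across biopanning rounds
#'
#' @param tables Named list of `clonotype_table`s; names are round labels
#'   (`"BP0"`, `"BP1"`, ...). Tables must share `key_level`.
#' @param metadata Stratum metadata (model, tissue, subtype, ...).
#' @return Object of class `biopanning_series`.
#' @export
#' @examples
#' s <- biopanning_series(list(BP1 = build_clonotypes(c("A", "B")),
#'                             BP2 = build_clonotypes(c("A", "A"))))
#' round_labels(s)
biopanning_series <- function(tables, metadata = list()) {
  assert_that(length(tables) >= 1, "need at least one table")
  assert_that(!is.null(names(tables)) && all(grepl("^BP\\d+$", names(tables))),
              "tables must be named BP0, BP1, ...")
  lvls <- unique(vapply(tables, `[[`, character(1), "key_level"))
  assert_that(length(lvls) == 1, "all tables must share key_level")
  ord <- order(as.integer(sub("^BP", "", names(tables))))
  assert_that(!anyDuplicated(names(tables)), "duplicate round labels")
  structure(list(tables = tables[ord], key_level = lvls,
                 metadata = metadata),
            class = "biopanning_series")
}

#' @export
print.biopanning_series <- function(x, ...) {
  cat(sprintf("Biopanning series (%s): rounds %s\n", x$key_level,
              paste(names(x$tables), collapse = ", ")))
  invisible(x)
}

#' Round labels of a series
#' @param series A `biopanning_series`.
#' @return Character vector of round labels in order.
#' @export
round_labels <- function(series) names(series$tables)

series_counts <- function(series, keys) {
  m <- vapply(series$tables, function(t) {
    idx <- match(keys, t$data$key)
    ifelse(is.na(idx), 0, t$data$count[idx])
  }, numeric(length(keys)))
  if (length(keys) == 1) m <- matrix(m, nrow = 1,
                                     dimnames = list(keys, names(series$tables)))
  else rownames(m) <- keys
  m
}

#' Proportion trajectories of clones across rounds
#'
#' Returns each key's per-round repertoire proportion, with 0 where the key
#' is absent from a round.
#'
#' @param series A `biopanning_series`.
#' @param keys Clonotype keys to track.
#' @return Data frame: `key` plus one proportion column per round.
#' @export
track_clones <- function(series, keys) {
  assert_that(length(keys) >= 1, "keys must be nonempty")
  m <- vapply(series$tables, function(t) {
    idx <- match(keys, t$data$key)
    ifelse(is.na(idx), 0, t$data$proportion[idx])
  }, numeric(length(keys)))
  if (length(keys) == 1) {
    m <- matrix(m, nrow = 1, dimnames = list(NULL, names(series$tables)))
  }
  if (any(rowSums(m) == 0)) {
    warning(sum(rowSums(m) == 0), " key(s) absent from every round")
  }
  data.frame(key = keys, m, row.names = NULL, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Trajectories of the most abundant clones of one round
#'
#' Ranks clones by count in `anchor_round` (ties lexicographic) and tracks
#' the top `k` across all rounds — forward from the naive pool or backward
#' from the final round.
#'
#' @param series A `biopanning_series`.
#' @param k Number of top clones.
#' @param anchor_round Round label to rank in (default last round).
#' @return Data frame as [track_clones()], rows in rank order.
#' @export
top_clone_fate <- function(series, k, anchor_round = NULL) {
  assert_that(k >= 1, "k must be >= 1")
  anchor_round <- anchor_round %||% tail(round_labels(series), 1)
  assert_that(anchor_round %in% round_labels(series),
              paste0("no table for round ", anchor_round))
  tab <- series$tables[[anchor_round]]
  if (k > tab$s_obs) {
    warning("k = ", k, " exceeds the ", tab$s_obs, " clones in ",
            anchor_round, "; returning all")
    k <- tab$s_obs
  }
  track_clones(series, tab$data$key[seq_len(k)])
}

#' Late-over-early enrichment filter
#'
#' Operationalizes selection for clones enriched in the last two rounds over
#' the first two: with a pseudocount added to every clone's count in every
#' round (making the ratio well-defined and depth-invariant), the enrichment
#' ratio is `(p3 + p4) / (p1 + p2)`. A clone passes when the ratio exceeds 1
#' and its raw read count summed over BP3 and BP4 reaches `min_late_count`.
#'
#' @param series A `biopanning_series` containing rounds BP1-BP4.
#' @param pseudocount Count added to every clone in every round (default
#'   0.5).
#' @param min_late_count Minimum raw BP3+BP4 count to pass (default 2).
#' @return Data frame sorted by `log2_enrichment` descending: `key`,
#'   per-round proportions `p_BP1` ... `p_BP4`, `early_mass`, `late_mass`,
#'   `late_count`, `enrichment_ratio`, `log2_enrichment`, `passes_filter`.
#' @export
enrichment_filter <- function(series, pseudocount = 0.5,
                              min_late_count = 2) {
  needed <- paste0("BP", 1:4)
  missing_r <- setdiff(needed, round_labels(series))
  if (length(missing_r)) {
    stop("series is missing round(s): ", paste(missing_r, collapse = ", "),
         call. = FALSE)
  }
  keys <- sort(unique(unlist(lapply(series$tables[needed],
                                    function(t) t$data$key))))
  sub <- biopanning_series(series$tables[needed], series$metadata)
  x <- series_counts(sub, keys)
  ns <- vapply(sub$tables, `[[`, numeric(1), "n")
  K <- length(keys)
  p <- sweep(x + pseudocount, 2, ns + pseudocount * K, "/")
  early <- p[, "BP1"] + p[, "BP2"]
  late <- p[, "BP3"] + p[, "BP4"]
  late_count <- x[, "BP3"] + x[, "BP4"]
  ratio <- late / early
  out <- data.frame(key = keys,
                    p_BP1 = p[, "BP1"], p_BP2 = p[, "BP2"],
                    p_BP3 = p[, "BP3"], p_BP4 = p[, "BP4"],
                    early_mass = early, late_mass = late,
                    late_count = late_count,
                    enrichment_ratio = ratio,
                    log2_enrichment = log2(ratio),
                    passes_filter = ratio > 1 & late_count >= min_late_count,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$log2_enrichment, out$key, method = "radix"), ,
      drop = FALSE]
}
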
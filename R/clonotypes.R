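#' Build a clonotype table from annotated VHH records
#'
#' Groups complete records by the chosen clonotype key and tabulates counts,
#' proportions, observed richness and the singleton/doubleton counts used by
#' richness extrapolation. Keys are ordered by count descending, ties broken
#' lexicographically, so tables are deterministic.
#'
#' @param records Data frame of complete [annotate_vhh()] records, or a
#'   character vector of keys. Records may carry a `count` column (default
#'   one read per row).
#' @param key_level One of `"full_aa"` (full amino-acid sequence, the
#'   default), `"cdr3_aa"`, or `"cdr3_nt"` (nucleotide CDR3).
#' @param metadata Named list of sample metadata (`tumor_model`, `tissue`,
#'   `subtype`, `round`, `replicate`, ...), carried on the table.
#' @return Object of class `clonotype_table`: list with `data` (data frame
#'   `key`, `count`, `proportion`), `n` (total reads), `s_obs`, `f1`, `f2`,
#'   `key_level`, `metadata`.
#' @export
#' @examples
#' tab <- build_clonotypes(c("A", "A", "B"))
#' tab$data
build_clonotypes <- function(records, key_level = c("full_aa", "cdr3_aa",
                                                    "cdr3_nt"),
                             metadata = list()) {
  key_level <- match.arg(key_level)
  if (is.character(records)) {
    keys <- records
    counts <- rep(1L, length(keys))
  } else {
    if (nrow(records) > 0 && !all(records$complete)) {
      stop("records must be complete; apply drop_partials() first",
           call. = FALSE)
    }
    keys <- switch(key_level,
                   full_aa = records$aa,
                   cdr3_aa = records$cdr3_aa,
                   cdr3_nt = cdr3_nt_keys(records))
    counts <- if ("count" %in% names(records)) records$count
              else rep(1L, nrow(records))
  }
  if (length(keys) == 0) {
    return(clonotype_table(character(0), numeric(0), key_level = key_level,
                           metadata = metadata))
  }
  agg <- tapply(counts, keys, sum)
  clonotype_table(names(agg), as.numeric(agg), key_level = key_level,
                  metadata = metadata)
}

cdr3_nt_keys <- function(records) {
  substring(records$nt_cds, 3L * records$cdr3_start + 1L,
            3L * records$cdr3_end)
}

#' Construct a clonotype table from keys and counts
#'
#' Lower-level constructor used by [build_clonotypes()] and the table
#' algebra; validates invariants and establishes the deterministic ordering.
#'
#' @param keys Character vector of distinct clonotype keys.
#' @param counts Positive counts, one per key.
#' @inheritParams build_clonotypes
#' @return A `clonotype_table`.
#' @export
clonotype_table <- function(keys, counts, key_level = "full_aa",
                            metadata = list()) {
  assert_that(length(keys) == length(counts), "keys/counts length mismatch")
  assert_that(!anyDuplicated(keys), "keys must be distinct")
  assert_that(all(counts > 0), "counts must be positive")
  ord <- order(-counts, keys, method = "radix")
  keys <- keys[ord]
  counts <- counts[ord]
  n <- sum(counts)
  structure(
    list(data = data.frame(key = keys, count = counts,
                           proportion = counts / n,
                           stringsAsFactors = FALSE),
         n = n, s_obs = length(keys),
         f1 = sum(counts == 1), f2 = sum(counts == 2),
         key_level = key_level, metadata = metadata),
    class = "clonotype_table")
}

#' @export
print.clonotype_table <- function(x, ...) {
  md <- x$metadata
  tag <- if (length(md)) paste(unlist(md), collapse = " / ") else "unlabelled"
  cat(sprintf("Clonotype table (%s, key = %s): %d clonotypes, %g reads\n",
              tag, x$key_level, x$s_obs, x$n))
  cat(sprintf("  singletons f1 = %d, doubletons f2 = %d\n", x$f1, x$f2))
  print(head(x$data, 5))
  invisible(x)
}

#' Sum replicate clonotype tables into one stratum table
#'
#' Counts are summed per key across replicates (replicate files are
#' collapsed, not averaged) and proportions recomputed.
#'
#' @param tables List of `clonotype_table`s sharing `key_level`.
#' @return A merged `clonotype_table`; metadata keeps the shared fields and
#'   drops `replicate`.
#' @export
merge_replicates <- function(tables) {
  if (inherits(tables, "clonotype_table")) return(tables)
  assert_that(length(tables) >= 1, "need at least one table")
  lvls <- unique(vapply(tables, `[[`, character(1), "key_level"))
  if (length(lvls) != 1) {
    stop("cannot merge tables with different key levels: ",
         paste(lvls, collapse = ", "), call. = FALSE)
  }
  if (length(tables) == 1) return(tables[[1]])
  all_keys <- unlist(lapply(tables, function(t) t$data$key))
  all_counts <- unlist(lapply(tables, function(t) t$data$count))
  agg <- tapply(all_counts, all_keys, sum)
  md <- tables[[1]]$metadata
  md$replicate <- NULL
  clonotype_table(names(agg), as.numeric(agg), key_level = lvls,
                  metadata = md)
}

#' Percentage of unique clonotypes per read
#'
#' `100 * S_obs / n`: the headline "percent unique VHHs" statistic, which
#' collapses as selection concentrates the repertoire.
#'
#' @param table A `clonotype_table`.
#' @return Percentage in (0, 100].
#' @export
#' @examples
#' percent_unique(build_clonotypes(c("A", "A", "B")))
percent_unique <- function(table) {
  assert_that(table$n > 0, "percent_unique is undefined for an empty table")
  100 * table$s_obs / table$n
}

#' Repertoire share by abundance rank
#'
#' Sorts clones by count (descending, ties lexicographic) and reports the
#' summed proportion falling into each rank bin — the "top clone proportion"
#' summary.
#'
#' @param table A `clonotype_table`.
#' @param rank_bins List of inclusive rank ranges `c(lo, hi)` (use `Inf` for
#'   an open top); default `1-10, 11-100, 101-1000, 1001-10000, 10001+`.
#' @return Named numeric vector of occupied proportions.
#' @export
#' @examples
#' clonality_by_rank(clonotype_table(c("a", "b", "c"), c(60, 30, 10)),
#'                   list(c(1, 2), c(3, 10)))
clonality_by_rank <- function(table,
                              rank_bins = list(c(1, 10), c(11, 100),
                                               c(101, 1000), c(1001, 10000),
                                               c(10001, Inf))) {
  check_bins(rank_bins)
  p <- table$data$proportion   # already rank-ordered deterministically
  ranks <- seq_along(p)
  out <- vapply(rank_bins, function(b) sum(p[ranks >= b[1] & ranks <= b[2]]),
                numeric(1))
  names(out) <- vapply(rank_bins, bin_label, character(1))
  out
}

#' Repertoire share by clone count
#'
#' Summed proportion of clones whose raw read count falls in each count bin
#' — the "rare clonal proportion" summary.
#'
#' @param table A `clonotype_table`.
#' @param count_bins List of inclusive count ranges; default
#'   `1, 2-3, 4-10, 11-30, 31-100, 101+`.
#' @return Named numeric vector of occupied proportions.
#' @export
clonality_by_count <- function(table,
                               count_bins = list(c(1, 1), c(2, 3), c(4, 10),
                                                 c(11, 30), c(31, 100),
                                                 c(101, Inf))) {
  check_bins(count_bins)
  x <- table$data$count
  p <- table$data$proportion
  out <- vapply(count_bins, function(b) sum(p[x >= b[1] & x <= b[2]]),
                numeric(1))
  names(out) <- vapply(count_bins, bin_label, character(1))
  out
}

check_bins <- function(bins) {
  assert_that(length(bins) >= 1, "need at least one bin")
  for (b in bins) assert_that(length(b) == 2 && b[1] <= b[2],
                              "each bin must be c(lo, hi) with lo <= hi")
  m <- do.call(rbind, bins)
  ord <- order(m[, 1])
  m <- m[ord, , drop = FALSE]
  if (nrow(m) > 1 && any(m[-1, 1] <= m[-nrow(m), 2])) {
    stop("bins overlap", call. = FALSE)
  }
  invisible(TRUE)
}

bin_label <- function(b) {
  if (b[1] == b[2]) as.character(b[1])
  else if (is.infinite(b[2])) paste0(b[1], "+")
  else paste0(b[1], "-", b[2])
}

#' Absorb likely sequencing-error variants into abundant parents
#'
#' Single-linkage error correction in the style of repertoire aligners'
#' clonotype assembly: a minor key is absorbed into the most abundant key of
#' identical length within `max_mismatch` substitutions whose count is at
#' least `min_ratio` times larger. Counts are reassigned to the parent and
#' the table rebuilt.
#'
#' @param table A `clonotype_table`.
#' @param max_mismatch Maximum Hamming distance to a parent (default 1).
#' @param min_ratio Minimum parent/child count ratio (default 20).
#' @return A denoised `clonotype_table`.
#' @export
denoise_clonotypes <- function(table, max_mismatch = 1, min_ratio = 20) {
  d <- table$data
  if (nrow(d) < 2) return(table)
  parent <- collapse_parents_cpp(d$key, d$count,
                                 as.integer(max_mismatch), min_ratio)
  if (all(parent == 0)) return(table)
  target <- ifelse(parent == 0, seq_len(nrow(d)), parent)
  agg <- tapply(d$count, d$key[target], sum)
  clonotype_table(names(agg), as.numeric(agg), key_level = table$key_level,
                  metadata = table$metadata)
}
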
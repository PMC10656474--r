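#' Cell-subtype selectivity of late-round clones
#'
#' For each clone, computes its pseudocounted mean proportion over BP3 and
#' BP4 within each sorted-subtype stream, then normalizes across subtypes so
#' each row sums to 1. The resulting share matrix is the direct input to a
#' relative-enrichment heatmap; the subtype with the largest share is the
#' assigned specificity, with ties flagged ambiguous (and broken toward the
#' input subtype order). A z-score row normalization is available behind
#' `mode = "zscore"` for display purposes; shares remain the default.
#'
#' @param series_list Named list (one `biopanning_series` per sorted
#'   subtype) sharing `key_level` and containing BP3 and BP4.
#' @param keys Clone keys to score; `NULL` scores the union of clones
#'   passing [enrichment_filter()] in any subtype stream.
#' @param pseudocount Count added to every clone in every round.
#' @param mode `"share"` (rows sum to 1) or `"zscore"`.
#' @return Data frame of class `selectivity_matrix`: `key`, one share
#'   column per subtype, `assigned_subtype`, `selectivity_score`,
#'   `ambiguous`.
#' @export
selectivity_matrix <- function(series_list, keys = NULL, pseudocount = 0.5,
                               mode = c("share", "zscore")) {
  mode <- match.arg(mode)
  assert_that(length(series_list) >= 2 && !is.null(names(series_list)),
              "series_list must be a named list of subtype series")
  lvls <- unique(vapply(series_list, `[[`, character(1), "key_level"))
  assert_that(length(lvls) == 1, "subtype series must share key_level")
  subtypes <- names(series_list)
  late <- c("BP3", "BP4")
  for (s in subtypes) {
    assert_that(all(late %in% round_labels(series_list[[s]])),
                paste0("subtype ", s, " series lacks BP3/BP4"))
  }
  if (is.null(keys)) {
    keys <- sort(unique(unlist(lapply(series_list, function(ser) {
      e <- enrichment_filter(ser, pseudocount = pseudocount)
      e$key[e$passes_filter]
    }))))
  }
  assert_that(length(keys) >= 1, "no keys to score")

  universe <- sort(unique(c(keys, unlist(lapply(series_list, function(ser) {
    unlist(lapply(ser$tables[late], function(t) t$data$key))
  })))))
  K <- length(universe)

  a <- vapply(subtypes, function(s) {
    ser <- series_list[[s]]
    ps <- vapply(late, function(r) {
      t <- ser$tables[[r]]
      idx <- match(keys, t$data$key)
      x <- ifelse(is.na(idx), 0, t$data$count[idx])
      (x + pseudocount) / (t$n + pseudocount * K)
    }, numeric(length(keys)))
    if (length(keys) == 1) mean(ps) else rowMeans(ps)
  }, numeric(length(keys)))
  if (length(keys) == 1) {
    a <- matrix(a, nrow = 1, dimnames = list(NULL, subtypes))
  }

  raw <- vapply(subtypes, function(s) {
    ser <- series_list[[s]]
    rowSums(series_counts(ser, keys)[, late, drop = FALSE])
  }, numeric(length(keys)))
  if (length(keys) == 1) raw <- matrix(raw, nrow = 1)
  seen <- rowSums(raw) > 0
  if (pseudocount == 0) seen <- rowSums(a) > 0
  if (any(!seen)) {
    warning(sum(!seen), " clone(s) absent from all subtypes dropped")
    keys <- keys[seen]
    a <- a[seen, , drop = FALSE]
    assert_that(length(keys) >= 1, "all clones absent from all subtypes")
  }

  shares <- a / rowSums(a)
  top <- apply(shares, 1, max)
  ambiguous <- rowSums(abs(shares - top) < 1e-9) > 1
  assigned <- subtypes[apply(shares, 1, which.max)]

  vals <- if (mode == "zscore") {
    t(apply(shares, 1, function(r) (r - mean(r)) / stats::sd(r)))
  } else shares
  out <- data.frame(key = keys, vals, assigned_subtype = assigned,
                    selectivity_score = top, ambiguous = ambiguous,
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("selectivity_matrix", "data.frame")
  attr(out, "subtypes") <- subtypes
  attr(out, "mode") <- mode
  out
}

#' Unique and overlapping clonotypes across strata
#'
#' Venn-style membership: for every key observed in any input, which inputs
#' contain it, plus the count of keys in each exclusive intersection region.
#'
#' @param tables Named list of `clonotype_table`s or character key sets.
#' @return List with `membership` (data frame: `key` + one logical column
#'   per input) and `regions` (named counts; names like `"A"`, `"A&B"`).
#' @export
#' @examples
#' overlap_sets(list(x = c("A", "B"), y = c("B", "C")))$regions
overlap_sets <- function(tables) {
  assert_that(length(tables) >= 2 && !is.null(names(tables)),
              "tables must be a named list of two or more sets")
  sets <- lapply(tables, function(t) {
    if (inherits(t, "clonotype_table")) unique(t$data$key) else unique(t)
  })
  lvls <- unlist(lapply(tables, function(t) {
    if (inherits(t, "clonotype_table")) t$key_level else NULL
  }))
  assert_that(length(unique(lvls)) <= 1, "tables must share key_level")
  keys <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(s) keys %in% s, logical(length(keys)))
  if (length(keys) == 1) {
    memb <- matrix(memb, nrow = 1, dimnames = list(NULL, names(sets)))
  }
  region <- apply(memb, 1, function(r) paste(names(sets)[r], collapse = "&"))
  regions <- table(region)
  list(membership = data.frame(key = keys, memb, row.names = NULL,
                               check.names = FALSE, stringsAsFactors = FALSE),
       regions = setNames(as.integer(regions), names(regions)))
}

#' Compare Sanger-picked clones with NGS repertoires
#'
#' Annotates Sanger-sequenced clone inserts, deduplicates them at the
#' CDR3-amino-acid level, and asks which of those CDR3s occur anywhere in
#' the late-round (BP3/BP4) NGS clonotype tables — the NGS-vs-Sanger
#' concordance readout.
#'
#' @param sanger FASTA path or named character vector of insert coding
#'   sequences (frame-anchored, as from colony PCR).
#' @param ngs_tables List of `clonotype_table`s from BP3/BP4 keyed at
#'   `cdr3_aa` level.
#' @param scaffold Scaffold used for annotation.
#' @return List: `n_sanger` (annotatable input clones), `n_excluded`
#'   (unannotatable, logged), `n_unique_cdr3`, `fraction_found` (of unique
#'   CDR3s, between 0 and 1), `percent_found`, and `per_clone` (data frame
#'   `cdr3_aa`, `found`, `ngs_count` summed over tables; the abundance
#'   overlay data).
#' @export
sanger_compare <- function(sanger, ngs_tables, scaffold = vhh_scaffold()) {
  if (is.character(sanger) && length(sanger) == 1 && file.exists(sanger)) {
    sanger <- read_fasta(sanger)
  }
  assert_that(length(sanger) >= 1, "no Sanger records supplied")
  if (inherits(ngs_tables, "clonotype_table")) ngs_tables <- list(ngs_tables)
  bad_lvl <- vapply(ngs_tables, function(t) t$key_level != "cdr3_aa",
                    logical(1))
  assert_that(!any(bad_lvl), "ngs_tables must be keyed at cdr3_aa level")

  ann <- annotate_vhh(unname(sanger), scaffold = scaffold)
  usable <- !is.na(ann$cdr3_aa) & ann$complete
  n_excluded <- sum(!usable)
  if (n_excluded > 0) {
    message("sanger_compare: excluded ", n_excluded,
            " unannotatable record(s)")
  }
  assert_that(any(usable), "no annotatable Sanger records")
  cdr3 <- unique(ann$cdr3_aa[usable])

  ngs_counts <- lapply(ngs_tables, function(t) {
    idx <- match(cdr3, t$data$key)
    ifelse(is.na(idx), 0, t$data$count[idx])
  })
  total <- Reduce(`+`, ngs_counts)
  per_clone <- data.frame(cdr3_aa = cdr3, found = total > 0,
                          ngs_count = total, stringsAsFactors = FALSE)
  list(n_sanger = sum(usable), n_excluded = n_excluded,
       n_unique_cdr3 = length(cdr3),
       fraction_found = mean(per_clone$found),
       percent_found = 100 * mean(per_clone$found),
       per_clone = per_clone)
}
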
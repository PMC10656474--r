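test_that("clone tracking reports per-round proportions with zero fill", {
  s <- toy_series(c(A = 8, B = 2), c(A = 5, B = 5), c(B = 10), c(B = 7,
                                                                 C = 3))
  tr <- track_clones(s, c("A", "C"))
  expect_equal(unname(unlist(tr[tr$key == "A", -1])), c(0.8, 0.5, 0, 0))
  expect_equal(unname(unlist(tr[tr$key == "C", -1])), c(0, 0, 0, 0.3))
  expect_warning(track_clones(s, "ZZZ"), "absent")
  expect_equal(unname(unlist(suppressWarnings(
    track_clones(s, "ZZZ"))[1, -1])), rep(0, 4))
})

test_that("top-clone fate ranks by anchor round and truncates with warning", {
  s <- toy_series(c(A = 8, B = 2), c(A = 5, B = 5), c(B = 10),
                  c(B = 7, C = 3))
  top <- top_clone_fate(s, 1, "BP4")
  expect_equal(top$key, "B")
  expect_warning(all_clones <- top_clone_fate(s, 10, "BP1"), "exceeds")
  expect_equal(nrow(all_clones), 2)
})

test_that("enrichment filter computes late-over-early mass ratios", {
  # proportions (0.001, 0.001, 0.01, 0.02) with negligible pseudocount
  s <- toy_series(c(X = 1, bulk = 999), c(X = 1, bulk = 999),
                  c(X = 10, bulk = 990), c(X = 20, bulk = 980))
  e <- enrichment_filter(s, pseudocount = 1e-9)
  xrow <- e[e$key == "X", ]
  expect_equal(xrow$enrichment_ratio, 15, tolerance = 1e-4)
  expect_true(xrow$passes_filter)
  # flat trajectories do not pass (ratio exactly 1)
  flat <- toy_series(c(A = 5, B = 5), c(A = 5, B = 5), c(A = 5, B = 5),
                     c(A = 5, B = 5))
  ef <- enrichment_filter(flat, pseudocount = 0)
  expect_true(all(ef$enrichment_ratio == 1))
  expect_false(any(ef$passes_filter))
  # absence from both late rounds fails regardless of the early signal
  gone <- toy_series(c(A = 9, B = 1), c(A = 9, B = 1), c(B = 10),
                     c(B = 10))
  eg <- enrichment_filter(gone)
  expect_false(eg$passes_filter[eg$key == "A"])
  # missing round is named in the error
  expect_error(enrichment_filter(toy_series(c(A = 1), c(A = 1), c(A = 1))),
               "BP4")
})

test_that("enrichment ratios are exactly depth invariant", {
  s1 <- toy_series(c(A = 10, B = 30, C = 60), c(A = 20, B = 20, C = 60),
                   c(A = 40, B = 10, C = 50), c(A = 60, B = 5, C = 35))
  scaled <- lapply(seq_along(s1$tables), function(i) {
    d <- s1$tables[[i]]$data
    k <- c(1, 10, 3, 7)[i]   # different depth per round
    clonotype_table(d$key, d$count * k)
  })
  names(scaled) <- names(s1$tables)
  s2 <- biopanning_series(scaled)
  e1 <- enrichment_filter(s1, pseudocount = 0)
  e2 <- enrichment_filter(s2, pseudocount = 0)
  expect_identical(e1$key, e2$key)
  expect_identical(e1$enrichment_ratio, e2$enrichment_ratio)
})

test_that("every passing clone has late mass exceeding early mass", {
  cfg <- simulation_config(n_clones = 400, n_binders_per_subtype = 4,
                           reads_per_sample = 400, n_replicates = 1,
                           capture_size = 1e4, seed = 17)
  sim <- simulate_biopanning(cfg, emit = "counts")
  tt <- sim$truth
  tabs <- lapply(paste0("BP", 1:4), function(r) {
    d <- tt[tt$round == r & tt$subtype == "CD8", ]
    clonotype_table(d$clone_id, d$reads)
  })
  names(tabs) <- paste0("BP", 1:4)
  e <- enrichment_filter(biopanning_series(tabs))
  expect_true(all(e$late_mass[e$passes_filter] >
                    e$early_mass[e$passes_filter]))
  expect_true(all(e$enrichment_ratio > 0))
})

test_that("selectivity shares are normalized, order-stable, and exclusive", {
  mk <- function(bp3, bp4) {
    biopanning_series(list(
      BP1 = clonotype_table(names(bp3), rep(1, length(bp3))),
      BP2 = clonotype_table(names(bp3), rep(1, length(bp3))),
      BP3 = clonotype_table(names(bp3), as.numeric(bp3)),
      BP4 = clonotype_table(names(bp4), as.numeric(bp4))))
  }
  bg <- c(W = 20, Z = 5)                      # equal totals per subtype
  with_q <- c(Q = 10, W = 10, Z = 5)          # Q only in CD11c
  only_c <- list(
    CD11b = mk(bg, bg),
    CD11c = mk(with_q, with_q),
    CD8 = mk(bg, bg),
    CD4CD25neg = mk(bg, bg),
    CD4CD25pos = mk(bg, bg))
  sel <- selectivity_matrix(only_c, keys = "Q", pseudocount = 0)
  expect_equal(sel$CD11c, 1)
  expect_equal(sel$CD11b + sel$CD8 + sel$CD4CD25neg + sel$CD4CD25pos, 0)
  expect_equal(sel$assigned_subtype, "CD11c")
  expect_false(sel$ambiguous)
  # symmetric clone: equal shares, flagged ambiguous, tie to input order
  sym <- selectivity_matrix(only_c, keys = "Z", pseudocount = 0)
  expect_equal(unname(unlist(sym[1, names(only_c)])), rep(0.2, 5),
               tolerance = 1e-9)
  expect_true(sym$ambiguous)
  expect_equal(sym$assigned_subtype, "CD11b")
  # permuting input order permutes columns but not values
  perm <- rev(names(only_c))
  sel2 <- selectivity_matrix(only_c[perm], keys = "Q", pseudocount = 0)
  expect_equal(sel2$CD11c, 1)
  # rows always sum to 1 with pseudocounts too
  sel3 <- selectivity_matrix(only_c, keys = c("Q", "Z"), pseudocount = 0.5)
  expect_equal(rowSums(sel3[, names(only_c)]), c(1, 1), tolerance = 1e-9,
               ignore_attr = TRUE)
  # clone absent everywhere is dropped with a warning
  expect_warning(selectivity_matrix(only_c, keys = c("Q", "NOPE")),
                 "dropped")
})

test_that("overlap regions match brute-force enumeration", {
  ov <- overlap_sets(list(x = c("A", "B"), y = c("B", "C")))
  expect_equal(ov$regions[["x"]], 1)
  expect_equal(ov$regions[["y"]], 1)
  expect_equal(ov$regions[["x&y"]], 1)
  same <- overlap_sets(list(a = c("A", "B"), b = c("A", "B")))
  expect_equal(names(same$regions), "a&b")
  expect_equal(same$regions[["a&b"]], 2)
  # three constructed sets against enumeration
  sets <- list(s1 = c("a", "b", "c", "d"), s2 = c("b", "c", "e"),
               s3 = c("c", "d", "e", "f"))
  ov3 <- overlap_sets(sets)
  keys <- sort(unique(unlist(sets)))
  expected <- table(vapply(keys, function(k) {
    paste(names(sets)[vapply(sets, function(s) k %in% s, logical(1))],
          collapse = "&")
  }, character(1)))
  expect_equal(ov3$regions[sort(names(expected))],
               setNames(as.integer(expected), names(expected))[
                 sort(names(expected))])
})

test_that("Sanger picks are scored by CDR3 membership in late rounds", {
  lib <- small_library()
  picks <- lib$clones[1:5, ]
  ngs <- build_clonotypes(rep(picks$cdr3_aa[1:4], times = c(5, 3, 2, 1)),
                          key_level = "cdr3_aa")
  res <- sanger_compare(setNames(picks$nt_cds, picks$clone_id), list(ngs))
  expect_equal(res$n_unique_cdr3, 5)
  expect_equal(res$fraction_found, 0.8)
  expect_equal(res$percent_found, 80)
  expect_equal(sum(res$per_clone$ngs_count), 11)
  # subset and disjoint extremes
  res_all <- sanger_compare(setNames(picks$nt_cds[1:4], picks$clone_id[1:4]),
                            list(ngs))
  expect_equal(res_all$fraction_found, 1)
  other <- build_clonotypes("WWWWYYYY", key_level = "cdr3_aa")
  res_none <- sanger_compare(setNames(picks$nt_cds, picks$clone_id),
                             list(other))
  expect_equal(res_none$fraction_found, 0)
})
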
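test_that("clonotype tabulation groups, orders, and counts correctly", {
  tab <- build_clonotypes(c("A", "A", "B"))
  expect_equal(tab$data$key, c("A", "B"))
  expect_equal(tab$data$count, c(2, 1))
  expect_equal(tab$data$proportion, c(2 / 3, 1 / 3))
  expect_equal(tab$f1, 1)
  expect_equal(tab$f2, 1)
  # empty input gives an empty table with n = 0
  empty <- build_clonotypes(character(0))
  expect_equal(empty$n, 0)
  expect_equal(empty$s_obs, 0)
  expect_error(shannon(empty), "n = 0")
})

test_that("synonymous nucleotide variants collapse at the amino-acid level", {
  lib <- small_library()
  nt <- lib$clones$nt_cds[1]
  # re-encode the same protein with different codons
  nt2 <- withr::with_seed(99, panrep:::encode_codons(lib$clones$aa[1]))
  expect_false(identical(nt, nt2))
  ann <- annotate_vhh(c(nt, nt2))
  tab <- build_clonotypes(ann, key_level = "full_aa")
  expect_equal(tab$s_obs, 1)
  expect_equal(tab$data$count, 2)
})

test_that("replicate merging sums counts and preserves totals", {
  t1 <- build_clonotypes("A")
  t2 <- build_clonotypes(c("A", "B", "B"))
  m <- merge_replicates(list(t1, t2))
  expect_equal(m$data$key, c("A", "B"))
  expect_equal(m$data$count, c(2, 2))
  expect_equal(m$n, t1$n + t2$n)
  expect_identical(merge_replicates(list(t1)), t1)
  t3 <- build_clonotypes(c("X"), key_level = "cdr3_aa")
  expect_error(merge_replicates(list(t1, t3)), "key level")
})

test_that("percent unique reflects clonal concentration", {
  expect_equal(percent_unique(build_clonotypes(c("A", "B", "C"))), 100)
  expect_equal(percent_unique(clonotype_table(c("a", "b"), c(2, 1))),
               100 * 2 / 3, tolerance = 1e-9)
  expect_equal(percent_unique(clonotype_table("a", 3)), 100 / 3,
               tolerance = 1e-9)
})

test_that("rank- and count-binned clonality partition the repertoire", {
  tab <- clonotype_table(c("a", "b", "c"), c(60, 30, 10))
  by_rank <- clonality_by_rank(tab, list(c(1, 2), c(3, 10)))
  expect_equal(unname(by_rank), c(0.9, 0.1))
  single <- clonality_by_rank(clonotype_table("a", 5),
                              list(c(1, 10), c(11, 100)))
  expect_equal(unname(single), c(1, 0))
  unif <- clonality_by_rank(
    clonotype_table(sprintf("k%03d", 1:100), rep(2, 100)),
    list(c(1, 10), c(11, 100)))
  expect_equal(unname(unif), c(0.1, 0.9))
  tab2 <- clonotype_table(c("a", "b", "c", "d"), c(1, 2, 3, 100))
  by_count <- clonality_by_count(tab2, list(c(1, 1), c(2, 3), c(4, Inf)))
  expect_equal(unname(by_count), c(1 / 106, 5 / 106, 100 / 106))
  expect_error(clonality_by_rank(tab, list(c(1, 5), c(3, 10))), "overlap")
})

test_that("classic diversity indices match closed forms and direct sums", {
  expect_equal(shannon(rep(1, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon(10), 0)
  expect_equal(shannon(c(1, 2, 3, 4)), 1.27985422583445,
               tolerance = 1e-10)  # frozen from direct -sum(p log p)
  s <- simpson(c(1, 1, 2))
  expect_equal(unname(s["simpson"]), 0.375)
  expect_equal(unname(s["inverse_simpson"]), 8 / 3, tolerance = 1e-12)
  expect_equal(unname(simpson(5)), c(1, 1))
  expect_equal(unname(simpson(rep(3, 7))["inverse_simpson"]), 7,
               tolerance = 1e-12)
})

test_that("Hill numbers obey their identities on arbitrary tables", {
  for (tab in random_tables()) {
    expect_equal(true_diversity(tab, 0), tab$s_obs, tolerance = 1e-9)
    expect_equal(true_diversity(tab, 1), exp(shannon(tab)),
                 tolerance = 1e-9)
    expect_equal(true_diversity(tab, 2),
                 unname(simpson(tab)["inverse_simpson"]), tolerance = 1e-9)
    # non-increasing in q
    dq <- true_diversity(tab, c(0, 0.5, 1, 1.5, 2, 3, 5))
    expect_true(all(diff(dq) <= 1e-9))
  }
  # equally abundant types: D_q = S for every order
  expect_equal(true_diversity(rep(4, 9), c(0, 1, 2, 7)), rep(9, 4),
               tolerance = 1e-9)
})

test_that("independent oracles confirm Shannon, Simpson and rarefaction", {
  for (tab in random_tables(5, seed = 21)) {
    x <- tab$data$count
    expect_equal(shannon(tab), vegan::diversity(x, "shannon"),
                 tolerance = 1e-9)
    expect_equal(unname(simpson(tab)["inverse_simpson"]),
                 vegan::diversity(x, "invsimpson"), tolerance = 1e-9)
    m <- max(1, floor(sum(x) / 2))
    expect_equal(rarefaction(tab, m),
                 as.numeric(suppressWarnings(vegan::rarefy(x, m))),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("analytic rarefaction matches enumeration and Monte Carlo", {
  # counts [2,2], m = 2: of the C(4,2)=6 draws, 4 contain both types
  expect_equal(rarefaction(c(2, 2), 2), 5 / 3, tolerance = 1e-12)
  expect_equal(rarefaction(c(2, 2), c(1, 4)), c(1, 2))
  x <- c(5, 3, 2, 1, 1)
  n <- sum(x)
  pool <- rep(seq_along(x), x)
  for (m in c(3, 6, 9)) {
    mc <- withr::with_seed(8, replicate(1000, {
      length(unique(sample(pool, m)))
    }))
    se <- stats::sd(mc) / sqrt(length(mc))
    expect_lt(abs(rarefaction(x, m) - mean(mc)), 3 * se + 1e-9)
  }
  expect_error(rarefaction(x, n + 1), "extrapolation")
})

test_that("Chao1 extrapolation follows the worked case and its limits", {
  # counts [1,1,2]: f1=2, f2=1, n=4 -> f0 = (3/4)*4/2 = 1.5, asymptote 4.5
  expect_equal(extrapolation(c(1, 1, 2), 4 + 1e9), 4.5, tolerance = 1e-6)
  expect_equal(panrep:::chao1_f0(4, 2, 1), 1.5)
  # no singletons: flat at observed richness
  expect_equal(extrapolation(c(2, 3, 5), c(11, 20)), c(3, 3))
  # meets the interpolated branch continuously at m = n
  x <- c(4, 2, 1, 1)
  n <- sum(x)
  expect_equal(rarefaction(x, n), length(x), tolerance = 1e-12)
  expect_equal(extrapolation(x, n + 1e-9), length(x), tolerance = 1e-6)
  curve <- rarefaction_curve(clonotype_table(letters[1:4], x))
  expect_true(all(diff(curve$richness[curve$method == "interpolated"]) >=
                    -1e-9))
  expect_true(all(curve$richness <= length(x) +
                    panrep:::chao1_f0(n, 1, 0) + 3))
})

test_that("error-variant collapsing absorbs minor neighbors only", {
  parent <- strrep("QVKLW", 4)
  child <- paste0(substr(parent, 1, 19), "A")   # 1 mismatch
  far <- strrep("AAAAG", 4)
  tab <- clonotype_table(c(parent, child, far), c(200, 4, 5))
  den <- denoise_clonotypes(tab)
  expect_equal(den$s_obs, 2)
  expect_equal(den$data$count[den$data$key == parent], 204)
  # a near-equal neighbor is not absorbed (ratio guard)
  tab2 <- clonotype_table(c(parent, child), c(30, 25))
  expect_equal(denoise_clonotypes(tab2)$s_obs, 2)
})
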
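table_counts <- function(x) {
  if (inherits(x, "clonotype_table")) {
    assert_that(x$n > 0, "diversity statistics are undefined for n = 0")
    x$data$count
  } else {
    counts <- as.numeric(x)
    counts <- counts[counts > 0]
    assert_that(length(counts) > 0, "need at least one positive count")
    counts
  }
}

#' Shannon entropy of a clonotype table
#'
#' `H = -sum(p_i log p_i)` in nats (divide by `log(2)` for bits).
#'
#' @param table A `clonotype_table` or a vector of counts.
#' @return Entropy in nats.
#' @export
#' @examples
#' shannon(c(1, 2, 3, 4))
shannon <- function(table) {
  p <- table_counts(table)
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Simpson concentration and inverse Simpson diversity
#'
#' @param table A `clonotype_table` or a vector of counts.
#' @return Named vector: `simpson` (`sum(p_i^2)`) and `inverse_simpson`.
#' @export
#' @examples
#' simpson(c(1, 1, 2))
simpson <- function(table) {
  p <- table_counts(table)
  p <- p / sum(p)
  s <- sum(p^2)
  c(simpson = s, inverse_simpson = 1 / s)
}

#' True diversity (Hill number) of order q
#'
#' The effective number of equally abundant types:
#' `D_q = (sum p_i^q)^(1/(1-q))` for `q != 1`, with the continuity limit
#' `D_1 = exp(H)`. `D_0` is observed richness, `D_2` the inverse Simpson
#' index.
#'
#' @param table A `clonotype_table` or a vector of counts.
#' @param q Nonnegative order (vectorized).
#' @return Effective number of types, one value per `q`.
#' @export
#' @examples
#' true_diversity(c(1, 1, 2), q = c(0, 1, 2))
true_diversity <- function(table, q = 1) {
  p <- table_counts(table)
  p <- p / sum(p)
  assert_that(all(q >= 0), "q must be >= 0")
  vapply(q, function(qq) {
    if (abs(qq - 1) < 1e-12) exp(-sum(p * log(p)))
    else sum(p^qq)^(1 / (1 - qq))
  }, numeric(1))
}

#' Expected richness under subsampling (analytic rarefaction)
#'
#' Hypergeometric expectation of the number of distinct clonotypes in a
#' without-replacement subsample of size `m`:
#' `E[S(m)] = S_obs - sum_i C(n - x_i, m) / C(n, m)`, evaluated in log space.
#'
#' @param table A `clonotype_table` or a vector of counts.
#' @param depths Subsample sizes, each in `[1, n]`.
#' @return Expected richness per depth.
#' @export
#' @examples
#' rarefaction(c(2, 2), 2)  # 5/3
rarefaction <- function(table, depths) {
  x <- table_counts(table)
  n <- sum(x)
  assert_that(all(depths >= 1 & depths <= n),
              "rarefaction depths must lie in [1, n]; use extrapolation() beyond n")
  vapply(depths, function(m) {
    absent <- exp(lchoose(n - x, m) - lchoose(n, m))
    length(x) - sum(absent)
  }, numeric(1))
}

#' Estimated richness beyond the observed depth (Chao1-style extrapolation)
#'
#' Estimates unseen richness from singletons and doubletons,
#' `f0 = ((n-1)/n) f1^2 / (2 f2)` (or `((n-1)/n) f1 (f1-1) / 2` when
#' `f2 = 0`), and extrapolates
#' `E[S(n + m*)] = S_obs + f0 (1 - (1 - f1 / (n f0 + f1))^m*)`.
#' With no singletons the curve is flat at `S_obs`.
#'
#' @param table A `clonotype_table` or a vector of counts.
#' @param depths Total depths, each `> n`.
#' @return Estimated richness per depth.
#' @export
#' @examples
#' extrapolation(c(1, 1, 2), 8)
extrapolation <- function(table, depths) {
  x <- table_counts(table)
  n <- sum(x)
  s_obs <- length(x)
  assert_that(all(depths > n), "extrapolation depths must exceed n")
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  f0 <- chao1_f0(n, f1, f2)
  vapply(depths, function(m) {
    mstar <- m - n
    if (f1 == 0 || f0 == 0) return(as.numeric(s_obs))
    s_obs + f0 * (1 - (1 - f1 / (n * f0 + f1))^mstar)
  }, numeric(1))
}

chao1_f0 <- function(n, f1, f2) {
  if (f1 == 0) return(0)
  if (f2 > 0) ((n - 1) / n) * f1^2 / (2 * f2)
  else ((n - 1) / n) * f1 * (f1 - 1) / 2
}

#' Combined rarefaction/extrapolation curve
#'
#' Interpolated richness up to the observed depth and Chao1-style
#' extrapolation beyond it (capped at `cap * n`, default twice the observed
#' depth); the two branches meet continuously at `m = n`.
#'
#' @param table A `clonotype_table` or a vector of counts.
#' @param n_points Number of evenly spaced depths per branch.
#' @param cap Extrapolation cap as a multiple of the observed depth.
#' @return Data frame `depth`, `richness`, `method`
#'   (`interpolated` / `extrapolated`).
#' @export
rarefaction_curve <- function(table, n_points = 20, cap = 2) {
  x <- table_counts(table)
  n <- sum(x)
  d_in <- unique(pmax(1, round(seq(1, n, length.out = n_points))))
  out <- data.frame(depth = d_in, richness = rarefaction(x, d_in),
                    method = "interpolated", stringsAsFactors = FALSE)
  if (cap > 1 && n >= 1) {
    d_ex <- unique(round(seq(n, cap * n, length.out = n_points)))
    d_ex <- d_ex[d_ex > n]
    if (length(d_ex)) {
      out <- rbind(out, data.frame(depth = d_ex,
                                   richness = extrapolation(x, d_ex),
                                   method = "extrapolated",
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Full diversity summary for a clonotype table
#'
#' @param table A `clonotype_table`.
#' @param q Hill orders to report.
#' @return List with `shannon`, `simpson`, `inverse_simpson`, `hill`
#'   (named by order), `s_obs`, `n`, `f1`, `f2`, `percent_unique`.
#' @export
diversity_report <- function(table, q = c(0, 1, 2)) {
  s <- simpson(table)
  list(n = table$n, s_obs = table$s_obs, f1 = table$f1, f2 = table$f2,
       shannon = shannon(table),
       simpson = unname(s["simpson"]),
       inverse_simpson = unname(s["inverse_simpson"]),
       hill = setNames(true_diversity(table, q), paste0("q", q)),
       percent_unique = percent_unique(table))
}
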
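# Nonparametric tests used by the ISH and clinical modules. All of them use
# mid-ranks for ties and switch automatically to exact enumeration of the
# permutation null on small samples; the normal approximations carry the
# standard tie corrections and a 0.5 continuity correction.

rank_test_result <- function(statistic, p, method, ...) {
  structure(c(list(statistic = statistic, p = p, method = method), list(...)),
            class = "linc_rank_test")
}

#' @export
print.linc_rank_test <- function(x, ...) {
  cat(sprintf("<linc_rank_test> %s: statistic = %.4g, p = %.4g\n",
              x$method, x$statistic, x$p))
  invisible(x)
}

# all ways to choose n1 of N indices; returns matrix with n1 rows
all_group_assignments <- function(N, n1) combn(N, n1)

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Statistic is the mid-rank sum of the first group. When
#' `n1 + n2 <= exact_max` (default 12) the two-sided p-value is computed by
#' exhaustive enumeration of all group assignments of the pooled mid-ranks;
#' otherwise a tie-corrected normal approximation with continuity
#' correction is used.
#'
#' @param scores_a,scores_b Non-empty numeric vectors.
#' @param exact_max Largest pooled size for automatic exact enumeration.
#' @return A `linc_rank_test` with `statistic` (rank sum of group a), `p`,
#'   `method`, `n1`, `n2`.
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 2), c(0, 0, 1))
rank_sum_test <- function(scores_a, scores_b, exact_max = 12) {
  stop_unless(length(scores_a) > 0 && length(scores_b) > 0,
              "input error: both groups must be non-empty")
  n1 <- length(scores_a); n2 <- length(scores_b); N <- n1 + n2
  r <- rank(c(scores_a, scores_b))  # mid-ranks
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  if (N <= exact_max) {
    idx <- all_group_assignments(N, n1)
    ws <- colSums(matrix(r[idx], nrow = n1))
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-12)
    return(rank_test_result(w, p, "exact_permutation", n1 = n1, n2 = n2))
  }
  ties <- table(r)
  v <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (v <= 0) return(rank_test_result(w, 1, "rank_sum_normal_tie_corrected",
                                      n1 = n1, n2 = n2))
  z <- (abs(w - mu) - 0.5) / sqrt(v)
  p <- min(1, 2 * pnorm(-max(z, 0)))
  rank_test_result(w, p, "rank_sum_normal_tie_corrected", n1 = n1, n2 = n2)
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Zero differences are dropped (classical Wilcoxon; set `pratt = TRUE` to
#' rank zeros before dropping them, Pratt's method). The statistic is the
#' mid-rank sum of the positive differences. Up to `exact_max` (default 12)
#' nonzero pairs the two-sided p-value enumerates all `2^n` sign flips;
#' beyond that a tie-corrected normal approximation with continuity
#' correction is used. The p-value is invariant to negating all
#' differences.
#'
#' @param d Vector of paired differences with at least one nonzero value.
#' @param exact_max Largest nonzero-pair count for exact enumeration.
#' @param pratt Use Pratt's zero-handling. Default `FALSE`.
#' @return A `linc_rank_test` with `statistic` (positive-rank sum), `p`,
#'   `method`, `n_pairs`.
#' @export
#' @examples
#' signed_rank_test(c(1, 1, 2, -1))
signed_rank_test <- function(d, exact_max = 12, pratt = FALSE) {
  d <- d[!is.na(d)]
  if (all(d == 0)) {
    warn("all differences are zero; degenerate signed-rank p = 1")
    return(rank_test_result(0, 1, "signed_rank_normal", n_pairs = 0L))
  }
  if (pratt) {
    r_all <- rank(abs(d))
    keep <- d != 0
    r <- r_all[keep]; dk <- d[keep]
  } else {
    dk <- d[d != 0]
    r <- rank(abs(dk))
  }
  n <- length(dk)
  w <- sum(r[dk > 0])
  mu <- sum(r) / 2
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- as.vector(signs %*% r)
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-12)
    return(rank_test_result(w, p, "exact_permutation", n_pairs = n))
  }
  ties <- table(r)
  v <- sum(r^2) / 4  # equals n(n+1)(2n+1)/24 - tie correction under mid-ranks
  if (v <= 0) return(rank_test_result(w, 1, "signed_rank_normal", n_pairs = n))
  z <- (abs(w - mu) - 0.5) / sqrt(v)
  p <- min(1, 2 * pnorm(-max(z, 0)))
  rank_test_result(w, p, "signed_rank_normal", n_pairs = n)
}

# enumerate all distinct assignments of N items into groups of sizes `sizes`;
# calls f(list of index vectors) and collects its numeric results
enumerate_partitions <- function(N, sizes, f) {
  out <- numeric(0)
  recurse <- function(remaining, sizes_left, acc) {
    if (length(sizes_left) == 1) {
      out[[length(out) + 1]] <<- f(c(acc, list(remaining)))
      return(invisible(NULL))
    }
    picks <- combn(length(remaining), sizes_left[1], simplify = FALSE)
    for (pk in picks) {
      recurse(remaining[-pk], sizes_left[-1], c(acc, list(remaining[pk])))
    }
  }
  recurse(seq_len(N), sizes, list())
  unlist(out)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic on mid-ranks; p-value from the chi-square
#' distribution with `k - 1` degrees of freedom, or by exhaustive
#' enumeration of the permutation null when the total sample size is at
#' most `exact_max` (default 10). With all values equal, H is defined as 0
#' and p = 1.
#'
#' @param values Numeric vector.
#' @param groups Group labels (>= 2 levels, each non-empty).
#' @param exact_max Largest total n for exact enumeration.
#' @return A `linc_rank_test` with `statistic` (H), `p`, `method`, `df`.
#' @export
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
kruskal_wallis <- function(values, groups, exact_max = 10) {
  groups <- as.factor(groups)
  stop_unless(nlevels(groups) >= 2, "input error: need >= 2 groups")
  stop_unless(all(table(groups) > 0), "input error: a group has size 0")
  stop_unless(length(values) == length(groups),
              "input error: values and groups differ in length")
  N <- length(values)
  r <- rank(values)
  h_of <- function(rr) {
    rs <- tapply(rr, groups, sum)
    ns <- tabulate(groups)
    h <- 12 / (N * (N + 1)) * sum(rs^2 / ns) - 3 * (N + 1)
    ties <- table(rr)
    corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
    if (corr <= 0) 0 else h / corr
  }
  h <- h_of(r)
  k <- nlevels(groups)
  if (N <= exact_max) {
    sizes <- as.integer(table(groups))
    hs <- enumerate_partitions(N, sizes, function(parts) {
      # parts assign indices to groups; recompute H for that labelling
      rs <- vapply(parts, function(ix) sum(r[ix]), numeric(1))
      ns <- vapply(parts, length, numeric(1))
      hh <- 12 / (N * (N + 1)) * sum(rs^2 / ns) - 3 * (N + 1)
      ties <- table(r)
      corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
      if (corr <= 0) 0 else hh / corr
    })
    p <- mean(hs >= h - 1e-12)
    return(rank_test_result(h, p, "exact_permutation", df = k - 1))
  }
  p <- pchisq(h, df = k - 1, lower.tail = FALSE)
  rank_test_result(h, p, "chi_square_tie_corrected", df = k - 1)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by hypergeometric enumeration: the probabilities of
#' all tables with the observed margins that are no more probable than the
#' observed one are summed. The odds ratio is the sample cross-product
#' ratio `(a d) / (b c)`; it is invariant under transposition of the table.
#'
#' @param tab 2x2 matrix (or vector of length 4, filled column-wise) of
#'   non-negative integer counts.
#' @return Tibble `p`, `odds_ratio`.
#' @export
#' @examples
#' fisher_exact(matrix(c(5, 5, 5, 5), 2))
fisher_exact <- function(tab) {
  tab <- matrix(as.vector(tab), 2, 2)
  stop_unless(all(is.finite(tab)) && all(tab >= 0) && all(tab == round(tab)),
              "input error: counts must be non-negative integers")
  a <- tab[1, 1]
  m <- sum(tab[, 1]); n_col2 <- sum(tab[, 2]); k <- sum(tab[1, ])
  support <- max(0, k - n_col2):min(k, m)
  dens <- dhyper(support, m, n_col2, k)
  p_obs <- dhyper(a, m, n_col2, k)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  p <- min(1, p)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  tibble(p = p, odds_ratio = or)
}
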
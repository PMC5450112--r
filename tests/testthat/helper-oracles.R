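# Independent oracles used across the suite. Each is written as the most
# literal transcription of the definition (loops, full enumeration), kept
# deliberately separate from the package's vectorized implementations.

# BH step-up straight from the definition: adj_i = min_{j: p_(j) >= p_i over
# rank order} m * p_(j) / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[ord[j]] / j, numeric(1))
    adj_sorted[i] <- min(1, min(vals))
  }
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# per-marker paired stats by explicit loop
oracle_paired_stats <- function(mat_tumor, mat_normal) {
  t(vapply(seq_len(nrow(mat_tumor)), function(i) {
    d <- mat_tumor[i, ] - mat_normal[i, ]
    d <- d[is.finite(d)]
    c(n = length(d), log2fc = mean(d), s2 = var(d))
  }, numeric(3)))
}

# product-limit estimate by longhand loop over a sorted risk table
oracle_km <- function(times, events) {
  tk <- sort(unique(times))
  s <- 1
  out <- data.frame(time = tk, survival = NA_real_)
  for (i in seq_along(tk)) {
    at_risk <- sum(times >= tk[i])
    d <- sum(times == tk[i] & events)
    s <- s * (1 - d / at_risk)
    out$survival[i] <- s
  }
  out
}

# log-rank O-E / variance terms by independent per-time tabulation
oracle_logrank <- function(times, events, groups) {
  g1 <- sort(unique(groups))[1]
  evt_times <- sort(unique(times[events == 1]))
  o <- e <- v <- 0
  for (t in evt_times) {
    risk <- times >= t
    n <- sum(risk); n1 <- sum(risk & groups == g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & groups == g1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * n1 * (n - n1) * (n - d) / (n^2 * (n - 1))
  }
  (o - e)^2 / v
}

# exact two-sided rank-sum p by counting subsets, written recursively
oracle_ranksum_exact <- function(a, b) {
  r <- rank(c(a, b))
  n1 <- length(a); N <- length(r)
  mu <- n1 * (N + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  hits <- 0; total <- 0
  pick <- function(start, left, acc) {
    if (left == 0) {
      total <<- total + 1
      if (abs(acc - mu) >= obs - 1e-12) hits <<- hits + 1
      return(invisible(NULL))
    }
    for (j in start:(N - left + 1)) pick(j + 1, left - 1, acc + r[j])
  }
  pick(1, n1, 0)
  hits / total
}

# exact signed-rank p by iterating over all sign patterns via bit masks
oracle_signedrank_exact <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(d)
  mu <- sum(r) / 2
  obs <- abs(sum(r[d > 0]) - mu)
  hits <- 0
  for (mask in 0:(2^n - 1)) {
    pos <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    if (abs(sum(r[pos]) - mu) >= obs - 1e-12) hits <- hits + 1
  }
  hits / 2^n
}

# exact Kruskal-Wallis p by enumerating label permutations (small N)
oracle_kruskal_exact <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values)
  r <- rank(values)
  h_stat <- function(rr, gg) {
    rs <- tapply(rr, gg, sum)
    ns <- table(gg)
    h <- 12 / (N * (N + 1)) * sum(rs^2 / ns) - 3 * (N + 1)
    ties <- table(rr)
    h / (1 - sum(ties^3 - ties) / (N^3 - N))
  }
  obs <- h_stat(r, groups)
  perms <- gtools_permutations(N)
  hs <- apply(perms, 1, function(pm) h_stat(r[pm], groups))
  mean(hs >= obs - 1e-12)
}

# all permutations of 1..n (row-wise), recursive
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, sub + (sub >= k))))
}

# Pearson correlation of mid-ranks computed longhand
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# classical paired t-test two-sided p from the closed form
oracle_paired_t_p <- function(d) {
  n <- length(d)
  tval <- mean(d) / sqrt(var(d) / n)
  2 * pt(-abs(tval), n - 1)
}

# type-7 percentile by explicit linear interpolation between order statistics
oracle_quantile7 <- function(x, prob) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * prob + 1
  lo <- floor(h)
  xs[lo] + (h - lo) * (xs[min(lo + 1, n)] - xs[lo])
}
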
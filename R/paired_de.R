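#' Per-marker paired statistics on the log2 scale
#'
#' For each marker, forms the per-pair differences
#' `d_i = log2(tumor) - log2(normal)` and reports their mean (the log2 fold
#' change), sample variance (df = n - 1) and the number of complete pairs.
#' A pair with a missing cell is dropped for that marker only
#' (complete-pairs analysis); markers with fewer than two complete pairs
#' are dropped with a warning.
#'
#' @param expr Long log2 expression tibble (`marker_id`, `sample_id`,
#'   `expr`).
#' @param design Tibble with `pair_id`, `normal_sample`, `tumor_sample`;
#'   each sample may appear once and at least two pairs are required.
#' @return Tibble `marker_id`, `n`, `log2fc`, `s2`.
#' @export
paired_stats <- function(expr, design) {
  stop_unless(all(c("pair_id", "normal_sample", "tumor_sample") %in% names(design)),
              "input error: design needs pair_id, normal_sample, tumor_sample")
  stop_unless(nrow(design) >= 2, "input error: fewer than 2 pairs")
  samps <- c(design$normal_sample, design$tumor_sample)
  stop_unless(!anyDuplicated(samps), "input error: a sample appears in more than one pair")
  missing_samples <- setdiff(samps, unique(expr$sample_id))
  stop_unless(length(missing_samples) == 0,
              "input error: samples absent from expression table: %s",
              paste(missing_samples, collapse = ", "))

  d_tbl <- expr %>%
    filter(.data$sample_id %in% samps) %>%
    mutate(role = if_else(.data$sample_id %in% design$tumor_sample, "tumor", "normal"),
           pair_id = if_else(.data$role == "tumor",
                             design$pair_id[match(.data$sample_id, design$tumor_sample)],
                             design$pair_id[match(.data$sample_id, design$normal_sample)])) %>%
    select("marker_id", "pair_id", "role", "expr") %>%
    tidyr::pivot_wider(names_from = "role", values_from = "expr") %>%
    mutate(d = .data$tumor - .data$normal) %>%
    filter(is.finite(.data$d))

  out <- d_tbl %>%
    group_by(.data$marker_id) %>%
    summarise(n = dplyr::n(), log2fc = mean(.data$d),
              s2 = if (dplyr::n() >= 2) var(.data$d) else NA_real_,
              .groups = "drop")
  dropped <- out$marker_id[out$n < 2]
  if (length(dropped)) {
    warn(sprintf("%d marker(s) dropped with < 2 complete pairs", length(dropped)))
    out <- filter(out, .data$n >= 2)
  }
  stop_unless(nrow(out) > 0, "input error: no marker has 2 complete pairs")
  out
}

# inverse of trigamma() by Newton iteration on the log scale
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:75) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif) / y < 1e-10) break
    }
    y
  }, numeric(1))
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits the scaled-F model of the moderated t-statistic by moment matching
#' on `log(s2)`: under the model `s2 ~ s0_2 * F(df, d0)`, the mean and
#' variance of `log(s2)` are closed forms in digamma/trigamma functions.
#' The prior degrees of freedom `d0` solve
#' `trigamma(d0/2) = var(e)` where `e = log(s2) - digamma(df/2) + log(df/2)`
#' and `var(e)` is corrected by `-trigamma(df/2)`; the prior variance
#' `s0_2` follows from the mean equation. When the observed dispersion of
#' `log(s2)` is no larger than sampling noise alone implies, the
#' `d0 = Inf` branch returns the geometric-mean-based `s0_2`.
#'
#' The estimator is scale-equivariant: multiplying every `s2` by `c`
#' multiplies `s0_2` by `c` and leaves `d0` unchanged.
#'
#' @param s2 Vector of per-marker sample variances (>= 10 positive values).
#' @param df Residual degrees of freedom of each `s2` (scalar, `n - 1`).
#' @return A `linc_eb_prior` list with `d0`, `s0_2`, `df`, `n_used`.
#' @export
estimate_prior <- function(s2, df) {
  stop_unless(is.numeric(df) && length(df) == 1 && df >= 1,
              "input error: df must be a single value >= 1")
  s2 <- s2[is.finite(s2)]
  if (all(s2 == 0)) {
    abort("degenerate input: all variances are zero; check the noise model")
  }
  pos <- s2[s2 > 0]
  stop_unless(length(pos) >= 10,
              "input error: need >= 10 markers with positive variance")
  z <- log(pos)
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(ebar)
  }
  structure(list(d0 = d0, s0_2 = s0_2, df = df, n_used = length(pos)),
            class = "linc_eb_prior")
}

#' @export
print.linc_eb_prior <- function(x, ...) {
  cat(sprintf("<linc_eb_prior> d0 = %s, s0_2 = %.4g (df = %g, %d markers)\n",
              format(x$d0, digits = 4), x$s0_2, x$df, x$n_used))
  invisible(x)
}

#' Moderated paired t-statistics
#'
#' Shrinks each marker's variance toward the prior as the convex
#' combination `s2_tilde = (d0 * s0_2 + (n-1) * s2) / (d0 + n - 1)` and
#' tests `log2fc` with `t = log2fc / sqrt(s2_tilde / n)` on `d0 + n - 1`
#' degrees of freedom (standard normal when `d0 = Inf`). With `d0 = 0` the
#' ordinary paired t-test is recovered.
#'
#' @param stats Output of [paired_stats()].
#' @param prior A `linc_eb_prior` from [estimate_prior()] (fitted on the
#'   same residual df).
#' @return `stats` extended with `s2_tilde`, `t_mod`, `df_total`, `p`.
#' @export
moderated_t <- function(stats, prior) {
  stop_unless(inherits(prior, "linc_eb_prior"),
              "input error: prior must come from estimate_prior()")
  d0 <- prior$d0
  s0_2 <- prior$s0_2
  df <- stats$n - 1
  s2_tilde <- if (is.infinite(d0)) rep(s0_2, nrow(stats)) else {
    (d0 * s0_2 + df * stats$s2) / (d0 + df)
  }
  t_mod <- stats$log2fc / sqrt(s2_tilde / stats$n)
  df_total <- d0 + df
  p <- if (is.infinite(d0)) 2 * pnorm(-abs(t_mod)) else 2 * pt(-abs(t_mod), df_total)
  if (any(s2_tilde == 0)) {
    warn("some moderated variances are exactly 0; their p-values are set to 0")
    p[s2_tilde == 0] <- 0
  }
  stats %>%
    mutate(s2_tilde = s2_tilde, t_mod = t_mod, df_total = df_total, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Computes the step-up adjusted values `min_k>=rank { p_(k) * m / k }`,
#' capped at 1, with monotonicity enforced and ties handled by stable rank
#' order. Output order matches input order.
#'
#' @param p Vector of p-values in `[0, 1]` (`NA` allowed, passed through).
#' @return Vector of BH-adjusted values (FDR).
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
bh_adjust <- function(p) {
  ok <- !is.na(p)
  stop_unless(all(p[ok] >= 0 & p[ok] <= 1), "input error: p-values outside [0,1]")
  m <- sum(ok)
  out <- rep(NA_real_, length(p))
  if (m == 0) return(out)
  pv <- p[ok]
  ord <- order(pv, method = "radix")        # stable
  adj <- pv[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))              # enforce step-up monotonicity
  adj <- pmin(adj, 1)
  res <- numeric(m)
  res[ord] <- adj
  out[ok] <- res
  out
}

#' Select candidate markers with the discovery filter
#'
#' Keeps a marker iff `p < p_max` and `fdr < fdr_max` and
#' `|log2fc| > min_abs_log2fc` — all strict inequalities, so boundary
#' values are rejected.
#'
#' @param results Tibble with `p`, `fdr` and `log2fc` (e.g. [moderated_t()]
#'   output after [bh_adjust()]).
#' @param p_max,fdr_max,min_abs_log2fc Filter thresholds; defaults 0.005,
#'   0.15 and 1.
#' @return The filtered tibble, with a `direction` column (`up`/`down`).
#' @export
select_candidates <- function(results, p_max = 0.005, fdr_max = 0.15,
                              min_abs_log2fc = 1) {
  stop_unless(all(c("p", "fdr", "log2fc") %in% names(results)),
              "input error: results need p, fdr, log2fc")
  results %>%
    filter(.data$p < p_max, .data$fdr < fdr_max,
           abs(.data$log2fc) > min_abs_log2fc) %>%
    mutate(direction = if_else(.data$log2fc > 0, "up", "down"))
}

#' Aggregate candidate markers to intergenic loci
#'
#' Maps each candidate marker to at most one locus by interval containment
#' (marker 1-based position against 0-based half-open BED intervals) and
#' tallies loci by direction. Loci whose passing markers disagree in sign
#' are flagged `discordant` and excluded from the up/down tallies; a marker
#' contained in more than one locus is an ambiguity error. Markers that
#' fall in no locus are dropped.
#'
#' @param candidates Output of [select_candidates()].
#' @param marker_map Tibble `marker_id`, `chrom`, `pos` (1-based).
#' @param loci BED-style tibble `chrom`, `start`, `end`, `locus_id`
#'   (0-based half-open).
#' @return A `linc_locus_calls` list: `locus_calls` tibble (`locus_id`,
#'   `direction` in up/down/discordant, `n_markers_support`, `markers`) and
#'   `summary` (`n_up_loci`, `n_up_markers`, `n_down_loci`,
#'   `n_down_markers`, `n_discordant_loci`).
#' @export
aggregate_to_loci <- function(candidates, marker_map, loci) {
  stop_unless(all(c("marker_id", "chrom", "pos") %in% names(marker_map)),
              "input error: marker_map needs marker_id, chrom, pos")
  stop_unless(all(c("chrom", "start", "end", "locus_id") %in% names(loci)),
              "input error: loci need chrom, start, end, locus_id")
  cand <- candidates %>%
    inner_join(marker_map, by = "marker_id")
  # containment in half-open coordinates: start <= pos - 1 < end
  hits <- cand %>%
    inner_join(loci, by = "chrom", relationship = "many-to-many") %>%
    filter(.data$start <= .data$pos - 1, .data$pos - 1 < .data$end)
  multi <- hits %>% count(.data$marker_id) %>% filter(.data$n > 1)
  if (nrow(multi)) {
    amb <- hits %>% filter(.data$marker_id %in% multi$marker_id)
    abort(sprintf("ambiguity error: marker %s maps to overlapping loci: %s",
                  multi$marker_id[1],
                  paste(amb$locus_id[amb$marker_id == multi$marker_id[1]],
                        collapse = ", ")))
  }
  locus_calls <- hits %>%
    group_by(.data$locus_id) %>%
    summarise(
      n_markers_support = dplyr::n(),
      direction = if (all(.data$log2fc > 0)) "up"
                  else if (all(.data$log2fc < 0)) "down" else "discordant",
      markers = list(.data$marker_id),
      .groups = "drop")
  summary <- tibble(
    n_up_loci = sum(locus_calls$direction == "up"),
    n_up_markers = sum(locus_calls$n_markers_support[locus_calls$direction == "up"]),
    n_down_loci = sum(locus_calls$direction == "down"),
    n_down_markers = sum(locus_calls$n_markers_support[locus_calls$direction == "down"]),
    n_discordant_loci = sum(locus_calls$direction == "discordant"))
  structure(list(locus_calls = locus_calls, summary = summary),
            class = "linc_locus_calls")
}

#' @export
print.linc_locus_calls <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<linc_locus_calls> %d up loci (%d markers), %d down loci (%d markers), %d discordant\n",
              s$n_up_loci, s$n_up_markers, s$n_down_loci, s$n_down_markers,
              s$n_discordant_loci))
  invisible(x)
}
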
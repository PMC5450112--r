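#' Tidy a Cox proportional-hazards fit
#'
#' @param x A `linc_cox` object.
#' @param ... Unused.
#' @return Tibble with one row per coefficient: `term`, `estimate` (log
#'   hazard ratio), `hazard_ratio`, `std_error`, `statistic` (Wald z),
#'   `p_value`.
#' @method tidy linc_cox
#' @export
tidy.linc_cox <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         hazard_ratio = exp(unname(x$coefficients)),
         std_error = unname(x$se),
         statistic = unname(x$coefficients / x$se),
         p_value = unname(x$wald_p))
}

#' Glance at a Cox proportional-hazards fit
#'
#' @param x A `linc_cox` object.
#' @param ... Unused.
#' @return One-row tibble: `n`, `n_events`, `loglik_null`, `loglik`,
#'   `score_statistic`, `score_df`, `score_p`, `iterations`.
#' @method glance linc_cox
#' @export
glance.linc_cox <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events,
         loglik_null = unname(x$loglik["null"]),
         loglik = unname(x$loglik["fitted"]),
         score_statistic = x$score_test$statistic,
         score_df = x$score_test$df,
         score_p = x$score_test$p,
         iterations = x$iter)
}

#' Tidy a rank-test result
#'
#' @param x A `linc_rank_test` object.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `p_value`, `method`.
#' @method tidy linc_rank_test
#' @export
tidy.linc_rank_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p, method = x$method)
}

#' Tidy a discovery run into its per-marker results
#'
#' @param x A `linc_discovery` object.
#' @param ... Unused.
#' @return The per-marker DEResult tibble.
#' @method tidy linc_discovery
#' @export
tidy.linc_discovery <- function(x, ...) x$results

#' Glance at a discovery run
#'
#' @param x A `linc_discovery` object.
#' @param ... Unused.
#' @return One-row tibble of headline counts.
#' @method glance linc_discovery
#' @export
glance.linc_discovery <- function(x, ...) {
  dplyr::bind_cols(
    tibble(n_pairs = nrow(x$design_used),
           n_pairs_excluded = length(x$qc$excluded_pairs),
           n_markers = nrow(x$results),
           n_candidates = nrow(x$candidates),
           d0 = x$prior$d0, s0_2 = x$prior$s0_2),
    x$loci$summary)
}
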
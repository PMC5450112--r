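#' Score an RNA-ISH specimen on the 0/1/2 rubric
#'
#' Semi-quantitative RNAscope scoring: 0 for no staining or fewer than one
#' dot per ten cells (`dots_per_cell < 0.1`); 2 when dots are abundant
#' (`> 10` per cell) *and* more than 10% of dots sit in clusters; 1
#' otherwise. Specimens with many dots but little clustering satisfy only
#' part of the score-2 definition and are conservatively assigned 1. The
#' score is monotone non-decreasing in `dots_per_cell` at fixed
#' `cluster_fraction`.
#'
#' @param dots_per_cell Mean dots per cell (>= 0), vectorized.
#' @param cluster_fraction Fraction of dots in clusters, in `[0, 1]`.
#' @return Integer vector of scores in `{0, 1, 2}`.
#' @export
#' @examples
#' score_specimen(c(0.05, 5, 15), c(0.5, 0.02, 0.15))  # 0 1 2
score_specimen <- function(dots_per_cell, cluster_fraction) {
  stop_unless(all(is.finite(dots_per_cell)) && all(dots_per_cell >= 0),
              "input error: dots_per_cell must be finite and >= 0")
  stop_unless(all(is.finite(cluster_fraction)) &&
                all(cluster_fraction >= 0 & cluster_fraction <= 1),
              "input error: cluster_fraction must be in [0,1]")
  ifelse(dots_per_cell < 0.1, 0L,
         ifelse(dots_per_cell > 10 & cluster_fraction > 0.10, 2L, 1L))
}

#' Combine two independent observers' scores
#'
#' Equal scores stand; scores one level apart take the lower (conservative)
#' value; scores two levels apart cannot be reconciled automatically and
#' return `NA` with an adjudication flag.
#'
#' @param observer_a,observer_b Integer scores in `{0, 1, 2}`, vectorized.
#' @return Tibble with `score` (NA where adjudication is needed) and
#'   `adjudicate` (logical).
#' @export
#' @examples
#' consensus_score(c(2, 1, 0), c(2, 2, 2))
consensus_score <- function(observer_a, observer_b) {
  ok <- function(x) all(x %in% c(0L, 1L, 2L))
  stop_unless(ok(observer_a) && ok(observer_b),
              "input error: observer scores must be in {0,1,2}")
  gap <- abs(observer_a - observer_b)
  tibble(score = ifelse(gap == 2, NA_integer_,
                        as.integer(pmin(observer_a, observer_b))),
         adjudicate = gap == 2)
}

#' Control-probe QC filter for ISH specimens
#'
#' Excludes specimens whose positive control (POLR2) scored 0 (RNA
#' degradation) or whose negative control (dapB) scored 2 (background
#' failure).
#'
#' @param specimens Tibble with `polr2_score` and `dapb_score` columns.
#' @return List: `retained` (tibble), `excluded` (tibble with `reason`),
#'   `report` (counts by reason).
#' @export
ish_qc_filter <- function(specimens) {
  stop_unless(all(c("polr2_score", "dapb_score") %in% names(specimens)),
              "input error: control scores missing (polr2_score, dapb_score)")
  stop_unless(!anyNA(specimens$polr2_score) && !anyNA(specimens$dapb_score),
              "input error: control scores contain NA")
  out <- specimens %>%
    mutate(reason = case_when(
      .data$polr2_score == 0 ~ "RNA degradation (POLR2 = 0)",
      .data$dapb_score == 2 ~ "background failure (dapB = 2)",
      TRUE ~ NA_character_))
  list(retained = out %>% filter(is.na(.data$reason)) %>% select(-"reason"),
       excluded = out %>% filter(!is.na(.data$reason)),
       report = out %>% filter(!is.na(.data$reason)) %>% count(.data$reason))
}

#' Staining positivity rate
#'
#' Fraction of specimens with score >= 1, with the percent rounded to the
#' nearest integer as reported in ISH summaries.
#'
#' @param scores Non-empty vector of scores in `{0, 1, 2}`.
#' @return Tibble `n_positive`, `n_total`, `fraction`, `percent`.
#' @export
#' @examples
#' positivity_rate(c(rep(1, 63), rep(0, 25)))  # 63/88 = 72%
positivity_rate <- function(scores) {
  scores <- scores[!is.na(scores)]
  stop_unless(length(scores) > 0, "input error: empty score list")
  n_pos <- sum(scores >= 1)
  tibble(n_positive = n_pos, n_total = length(scores),
         fraction = n_pos / length(scores),
         percent = round(100 * n_pos / length(scores)))
}
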
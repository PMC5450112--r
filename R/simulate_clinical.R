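#' Simulate an RNA-ISH specimen table
#'
#' Emulates a tissue-microarray RNAscope experiment: per specimen a mean
#' dot-per-cell count (gamma-distributed, tumor mean shifted upward by
#' `effect`), the fraction of dots occurring in clusters, and scores for the
#' positive (POLR2) and negative (dapB) control probes. A planted fraction of
#' specimens is RNA-degraded: their POLR2 control scores 0, which the QC
#' filter uses to exclude them. The first `min(n_tumor, n_normal)` tumors are
#' paired with the normals (shared `pair_id`), mimicking matched
#' tumor/adjacent-normal cores.
#'
#' @param n_tumor,n_normal Specimen counts per group.
#' @param degraded_frac Probability that a specimen is RNA-degraded.
#' @param effect Shift (dots/cell) added to the tumor-group mean. Default 3.
#' @param seed Integer RNG seed.
#' @return Tibble with columns `specimen_id`, `group`, `pair_id`,
#'   `dots_per_cell`, `cluster_fraction`, `polr2_score`, `dapb_score`,
#'   `obs_a`, `obs_b` (two observer scores of the target probe) and the
#'   ground-truth flag `truth_degraded`.
#' @export
#' @examples
#' tma <- simulate_ish_table(20, 10, degraded_frac = 0.1, seed = 3)
simulate_ish_table <- function(n_tumor, n_normal, degraded_frac = 0.14,
                               effect = 3, seed = 1L) {
  stop_unless(is.numeric(n_tumor) && is.numeric(n_normal) &&
                n_tumor >= 0 && n_normal >= 0,
              "configuration error: counts must be >= 0")
  stop_unless(is.numeric(degraded_frac) && degraded_frac >= 0 && degraded_frac <= 1,
              "configuration error: degraded_frac must be in [0,1]")
  stop_unless(is.finite(effect), "configuration error: effect must be finite")
  set.seed(seed)
  n <- n_tumor + n_normal
  group <- rep(c("tumor", "normal"), c(n_tumor, n_normal))
  n_pairs <- min(n_tumor, n_normal)
  pair_id <- rep(NA_character_, n)
  if (n_pairs > 0) {
    pair_id[seq_len(n_pairs)] <- sprintf("TP%03d", seq_len(n_pairs))
    pair_id[n_tumor + seq_len(n_pairs)] <- sprintf("TP%03d", seq_len(n_pairs))
  }
  # normal baseline mean 0.6 dots/cell, right-skewed; tumor mean + effect
  shape <- 0.5
  mu <- ifelse(group == "tumor", 0.6 + effect, 0.6)
  dots <- rgamma(n, shape = shape, scale = mu / shape)
  # clustering grows with dot density
  cluster_fraction <- rbeta(n, 1 + dots / 2, 8)
  degraded <- runif(n) < degraded_frac
  polr2 <- ifelse(degraded, 0L, sample(1:2, n, replace = TRUE, prob = c(0.2, 0.8)))
  dapb <- rbinom(n, 1, 0.05)
  true_score <- score_specimen(dots, cluster_fraction)
  # second observer occasionally scores one level lower
  obs_b <- pmax(true_score - rbinom(n, 1, 0.1), 0L)
  tibble(
    specimen_id = sprintf("S%03d", seq_len(n)),
    group = group, pair_id = pair_id,
    dots_per_cell = dots, cluster_fraction = cluster_fraction,
    polr2_score = as.integer(polr2), dapb_score = as.integer(dapb),
    obs_a = as.integer(true_score), obs_b = as.integer(obs_b),
    truth_degraded = degraded)
}

#' Simulate a clinical survival cohort with categorized expression
#'
#' Generates TCGA-style clinical records: a right-skewed (log-normal)
#' RPKM-like expression value calibrated so that a fraction `frac_high`
#' exceeds the analysis cutpoint of 1.0, age uniform on 35-80 years, AJCC
#' and tumor-size stage labels with a mild stage-dependent expression shift,
#' exponential event times under proportional hazards in the binary
#' expression group and age, and independent exponential censoring tuned so
#' that each record is censored with probability `censor_rate`. A planted
#' fraction of records receives follow-up time 0 or a missing stage to
#' exercise the cohort exclusion rules.
#'
#' @param n Number of patients (>= 2).
#' @param frac_high Target fraction with expression above the cutpoint 1.0.
#' @param hr_high Hazard ratio of the high-expression group. Must be > 0.
#' @param hr_age_per_year Hazard ratio per year of age (centred at 60).
#' @param censor_rate Per-record probability of censoring before the event.
#' @param excluded_frac Fraction of records planted with follow-up 0 or
#'   missing stage. Default 0.
#' @param stage_shift Additive shift of log-expression per stage level
#'   beyond I; emulates rising expression with pathologic stage. Default 0.25.
#' @param seed Integer RNG seed.
#' @return Tibble of `patient_id`, `expression`, `vital_status`,
#'   `days_to_death`, `days_to_last_followup`, `age`, `ajcc_stage`,
#'   `t_stage`, plus ground-truth columns `truth_group` and
#'   `truth_excluded`.
#' @export
#' @examples
#' cohort <- simulate_survival_cohort(300, hr_high = 2.5, seed = 11)
simulate_survival_cohort <- function(n, frac_high = 0.4, hr_high = 2.5,
                                     hr_age_per_year = 1.02,
                                     censor_rate = 0.6,
                                     excluded_frac = 0,
                                     stage_shift = 0.25,
                                     seed = 1L) {
  stop_unless(is.numeric(n) && n >= 2, "configuration error: n must be >= 2")
  stop_unless(hr_high > 0 && hr_age_per_year > 0,
              "configuration error: hazard ratios must be > 0")
  stop_unless(censor_rate >= 0 && censor_rate < 1,
              "configuration error: censor_rate must be in [0,1)")
  stop_unless(frac_high > 0 && frac_high < 1,
              "configuration error: frac_high must be in (0,1)")
  set.seed(seed)
  n <- as.integer(n)

  ajcc_lab <- c("I", "II", "III", "IV")
  stage_idx <- sample(1:4, n, replace = TRUE, prob = c(0.17, 0.58, 0.22, 0.03))
  t_idx <- sample(1:4, n, replace = TRUE, prob = c(0.27, 0.59, 0.10, 0.04))

  # log-normal expression; sdlog 1.5 gives the long right tail of RPKM data,
  # meanlog places quantile(1 - frac_high) at the cutpoint log(1) = 0
  sdlog <- 1.5
  mulog <- sdlog * qnorm(frac_high) + (stage_idx - 1) * stage_shift
  # re-centre so the marginal P(expr > 1) stays ~ frac_high despite the shift
  mulog <- mulog - mean((stage_idx - 1) * stage_shift)
  expression <- rlnorm(n, mulog, sdlog)

  age <- runif(n, 35, 80)
  high <- expression > 1
  h0 <- log(2) / 2000  # baseline median survival ~ 2000 days
  h <- h0 * hr_high^high * hr_age_per_year^(age - 60)
  t_event <- rexp(n, rate = h)
  if (censor_rate > 0) {
    t_cens <- rexp(n, rate = h * censor_rate / (1 - censor_rate))
  } else {
    t_cens <- rep(Inf, n)
  }
  event <- t_event <= t_cens
  time <- ceiling(pmin(t_event, t_cens))

  excl <- runif(n) < excluded_frac
  # split planted exclusions between zero follow-up and missing stage
  excl_zero <- excl & (runif(n) < 0.5)
  ajcc <- ajcc_lab[stage_idx]
  ajcc[excl & !excl_zero] <- NA_character_
  time[excl_zero] <- 0

  tibble(
    patient_id = sprintf("TCGA%04d", seq_len(n)),
    expression = expression,
    vital_status = ifelse(event, "dead", "alive"),
    days_to_death = ifelse(event, time, NA_real_),
    days_to_last_followup = ifelse(event, NA_real_, time),
    age = age,
    ajcc_stage = ajcc,
    t_stage = paste0("T", t_idx),
    truth_group = ifelse(high, "high", "low"),
    truth_excluded = excl)
}

#' Simulate per-gene knockdown differential-expression statistics
#'
#' Emits two GeneStat tables (one per shRNA treatment vs a common vector
#' control) with planted shared hits, treatment-specific hits and null
#' genes. Shared hits receive a common base log2 fold change plus small
#' treatment-specific noise, so their fold changes are strongly rank-
#' correlated between treatments; true hits receive left-skewed p-values,
#' null genes uniform ones.
#'
#' @param n_genes Total genes per table.
#' @param n_shared Genes differentially expressed under both treatments.
#' @param n_a_only,n_b_only Treatment-specific hit counts.
#' @param effect_sd SD of the planted base |log2FC| (drawn half-normal,
#'   shifted away from zero by 1). Default 1.
#' @param seed Integer RNG seed.
#' @return List with tibbles `a` and `b` (`gene_id`, `log2fc`, `p`) and a
#'   `truth` tibble of planted hit classes.
#' @export
simulate_knockdown_stats <- function(n_genes = 5000, n_shared = 122,
                                     n_a_only = 51, n_b_only = 199,
                                     effect_sd = 1, seed = 1L) {
  stop_unless(n_shared + n_a_only <= n_genes && n_shared + n_b_only <= n_genes,
              "configuration error: hit counts exceed n_genes")
  set.seed(seed)
  gene_id <- sprintf("G%05d", seq_len(n_genes))
  class <- rep("null", n_genes)
  class[seq_len(n_shared)] <- "shared"
  class[n_shared + seq_len(n_a_only)] <- "a_only"
  class[n_shared + n_a_only + seq_len(n_b_only)] <- "b_only"

  base_fc <- sign(rnorm(n_genes)) * (1 + abs(rnorm(n_genes, 0, effect_sd)))
  one_table <- function(active) {
    fc <- ifelse(active, base_fc + rnorm(n_genes, 0, 0.15),
                 rnorm(n_genes, 0, 0.15))
    # strong planted effects: p well below typical DE thresholds, log-uniform
    p <- ifelse(active, 10^(-runif(n_genes, 3.5, 12)), runif(n_genes))
    tibble(gene_id = gene_id, log2fc = fc, p = p)
  }
  list(a = one_table(class %in% c("shared", "a_only")),
       b = one_table(class %in% c("shared", "b_only")),
       truth = tibble(gene_id = gene_id, class = class))
}
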
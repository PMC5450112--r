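#' Categorize an RPKM-like expression value
#'
#' Initial categories follow skewed-expression binning rather than
#' percentiles: `<=1`, `>1-5`, `>5-10`, `>10` (the last open-ended, the
#' observed maximum in the motivating cohort being ~83). Because survival
#' is similar across the upper categories, the analysis covariate is the
#' binary collapse: `low` (<= 1, boundary inclusive) vs `high` (> 1).
#'
#' @param expression Non-negative numeric vector (RPKM-like).
#' @return Tibble `expression`, `initial_category` (ordered factor),
#'   `group` (factor low/high).
#' @export
#' @examples
#' categorize_expression(c(0.39, 1, 4.28, 12))
categorize_expression <- function(expression) {
  stop_unless(all(is.finite(expression)) && all(expression >= 0),
              "input error: expression must be finite and >= 0")
  init <- cut(expression, breaks = c(-Inf, 1, 5, 10, Inf),
              labels = c("<=1", ">1-5", ">5-10", ">10"),
              right = TRUE, ordered_result = TRUE)
  tibble(expression = expression,
         initial_category = init,
         group = factor(ifelse(expression > 1, "high", "low"),
                        levels = c("low", "high")))
}

# derive (time, event) from TCGA-style vital status fields
surv_time_event <- function(records) {
  stop_unless(all(c("vital_status", "days_to_death", "days_to_last_followup")
                  %in% names(records)),
              "input error: need vital_status, days_to_death, days_to_last_followup")
  dead <- records$vital_status == "dead"
  time <- ifelse(dead, records$days_to_death, records$days_to_last_followup)
  stop_unless(!anyNA(time), "input error: survival time undefined for some records")
  stop_unless(all(time >= 0), "input error: negative survival time")
  tibble(time = time, event = dead)
}

#' Apply the clinical cohort exclusions
#'
#' Removes records with zero follow-up time and records whose pathologic
#' stage is not available, and derives the survival time (days to death
#' for the dead, days to last follow-up, censored, for the alive).
#'
#' @param records Clinical tibble with `vital_status`, `days_to_death`,
#'   `days_to_last_followup` and `ajcc_stage` columns.
#' @return List: `cohort` (retained records plus `time`, `event` columns)
#'   and `report` (exclusion counts by reason).
#' @export
apply_exclusions <- function(records) {
  te <- surv_time_event(records)
  records <- records %>% mutate(time = te$time, event = te$event)
  stage_na <- is.na(records$ajcc_stage) |
    tolower(trimws(records$ajcc_stage)) %in% c("not available", "na", "")
  reason <- case_when(records$time == 0 ~ "follow-up days = 0",
                      stage_na ~ "stage not available",
                      TRUE ~ NA_character_)
  list(cohort = records[is.na(reason), , drop = FALSE],
       report = tibble(reason = reason[!is.na(reason)]) %>% count(.data$reason))
}

#' Kaplan-Meier product-limit estimate per group
#'
#' At each distinct observed time the at-risk count, event count and
#' censoring count are tabulated; subjects censored at a time are still at
#' risk for events at that same time (events first), and the survival
#' probability is the running product of `1 - d_k / n_k` over event times.
#'
#' @param times Non-negative follow-up times.
#' @param events Logical (or 0/1) event indicators.
#' @param groups Group labels; default a single group.
#' @return A `linc_km` tibble: `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`.
#' @export
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))
km_estimate <- function(times, events, groups = rep("all", length(times))) {
  stop_unless(length(times) > 0, "input error: empty group")
  stop_unless(all(times >= 0), "input error: negative times")
  events <- as.logical(events)
  groups <- as.factor(groups)
  stop_unless(all(table(groups) > 0), "input error: empty group")
  out <- purrr::map_dfr(levels(groups), function(g) {
    t_g <- times[groups == g]; e_g <- events[groups == g]
    tk <- sort(unique(t_g))
    n_risk <- vapply(tk, function(t) sum(t_g >= t), numeric(1))
    n_event <- vapply(tk, function(t) sum(t_g == t & e_g), numeric(1))
    n_cens <- vapply(tk, function(t) sum(t_g == t & !e_g), numeric(1))
    tibble(group = g, time = tk, n_risk = n_risk, n_event = n_event,
           n_censor = n_cens,
           survival = cumprod(1 - n_event / n_risk))
  })
  class(out) <- c("linc_km", class(out))
  out
}

#' Two-group log-rank test
#'
#' Sums observed-minus-expected event counts for the first group over all
#' distinct event times, with the hypergeometric variance at each time,
#' and refers `(O - E)^2 / V` to chi-square with one degree of freedom.
#' The statistic is invariant to relabelling the groups.
#'
#' @param times,events As in [km_estimate()].
#' @param groups Binary group labels.
#' @return A `linc_rank_test` with `statistic` (chi-square), `p`, `df`,
#'   `observed`, `expected` for the first group level.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(groups)
  stop_unless(nlevels(groups) == 2, "input error: log-rank needs exactly 2 groups")
  stop_unless(all(table(groups) >= 1), "input error: a group has no subjects")
  events <- as.logical(events)
  if (!any(events)) {
    warn("no events in either group; degenerate log-rank p = 1")
    return(rank_test_result(0, 1, "logrank_chisq", df = 1,
                            observed = 0, expected = 0))
  }
  g1 <- levels(groups)[1]
  tk <- sort(unique(times[events]))
  o_minus_e <- 0; v <- 0; obs <- 0; expd <- 0
  for (t in tk) {
    at <- times >= t
    n_t <- sum(at)
    n1 <- sum(at & groups == g1)
    d_t <- sum(times == t & events)
    d1 <- sum(times == t & events & groups == g1)
    e1 <- d_t * n1 / n_t
    obs <- obs + d1
    expd <- expd + e1
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n_t > 1) {
      v <- v + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  if (v <= 0) {
    warn("log-rank variance is zero; degenerate p = 1")
    return(rank_test_result(0, 1, "logrank_chisq", df = 1,
                            observed = obs, expected = expd))
  }
  chisq <- o_minus_e^2 / v
  rank_test_result(chisq, pchisq(chisq, 1, lower.tail = FALSE),
                   "logrank_chisq", df = 1, observed = obs, expected = expd)
}

#' Cox proportional-hazards fit by Newton-Raphson
#'
#' Maximizes the Breslow partial likelihood with Newton-Raphson
#' (convergence when the largest absolute score component falls below
#' `tol`, default 1e-8, or after `max_iter` = 50 iterations; step-halving
#' guards against overshooting). Wald tests are reported per coefficient,
#' and the score test evaluated at zero — which on tie-free data with a
#' single binary covariate equals the log-rank chi-square — is included.
#'
#' @param times,events As in [km_estimate()] (>= 2 events required).
#' @param covariates Numeric matrix or data frame of covariates (e.g.
#'   binary expression group and age); columns must be finite.
#' @param tol,max_iter Newton-Raphson controls.
#' @return A `linc_cox` object; see [tidy.linc_cox()] and
#'   [glance.linc_cox()].
#' @export
cox_fit <- function(times, events, covariates, tol = 1e-8, max_iter = 50) {
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  stop_unless(all(is.finite(x)), "input error: covariates must be finite")
  events <- as.logical(events)
  stop_unless(sum(events) >= 2, "input error: need >= 2 events")
  n <- length(times); p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))

  ord <- order(times, decreasing = TRUE)  # risk sets by cumulative sums
  t_s <- times[ord]; e_s <- events[ord]; x_s <- x[ord, , drop = FALSE]
  # index of the last row of each distinct time block (risk set boundary)
  block_end <- cumsum(rle(t_s)$lengths)
  block_time <- t_s[block_end]
  # events per distinct time, and sum of covariates over events
  d_t <- vapply(seq_along(block_end), function(i) {
    ix <- (c(0, block_end)[i] + 1):block_end[i]
    sum(e_s[ix])
  }, numeric(1))
  keep <- d_t > 0
  xe_sum <- colSums(x_s[e_s, , drop = FALSE])

  partial <- function(beta) {
    eta <- drop(x_s %*% beta)
    eta <- eta - max(eta)  # guard overflow; cancels in all ratios
    w <- exp(eta)
    c0 <- cumsum(w)
    c1 <- apply(w * x_s, 2, cumsum)
    # p x p second moments, stored as p^2 cumsum columns
    xx <- x_s[, rep(seq_len(p), each = p), drop = FALSE] *
      x_s[, rep(seq_len(p), times = p), drop = FALSE]
    c2 <- apply(w * xx, 2, cumsum)
    i_t <- block_end[keep]; d <- d_t[keep]
    s0 <- c0[i_t]
    s1 <- matrix(c1[i_t, ], ncol = p)
    s2 <- matrix(c2[i_t, ], ncol = p * p)
    ll <- sum(eta[e_s]) - sum(d * log(s0))
    u <- xe_sum - colSums(d * s1 / s0)
    sbar <- s1 / s0
    imat <- matrix(colSums(d * (s2 / s0 -
      sbar[, rep(seq_len(p), each = p), drop = FALSE] *
      sbar[, rep(seq_len(p), times = p), drop = FALSE])), p, p)
    list(ll = ll, u = u, imat = imat)
  }

  beta <- rep(0, p)
  pl0 <- partial(beta)
  score0 <- pl0$u
  imat0 <- pl0$imat
  ll_old <- pl0$ll
  u <- pl0$u; imat <- pl0$imat
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    step <- tryCatch(solve(imat, u), error = function(e)
      abort("diagnostic error: singular information matrix (separation or collinearity?)"))
    fac <- 1
    repeat {
      beta_new <- beta + fac * step
      pl <- partial(beta_new)
      if (is.finite(pl$ll) && pl$ll >= ll_old - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-8) abort("diagnostic error: Cox partial likelihood failed to increase")
    }
    beta <- beta_new; ll_old <- pl$ll; u <- pl$u; imat <- pl$imat
    if (max(abs(beta)) > 15) {
      abort("diagnostic error: monotone likelihood (complete separation?)")
    }
    if (max(abs(u)) < tol) { converged <- TRUE; break }
  }
  if (!converged) abort("diagnostic error: Cox fit did not converge in max_iter iterations")

  vcov <- solve(imat)
  se <- sqrt(diag(vcov))
  z <- beta / se
  score_stat <- drop(t(score0) %*% solve(imat0, score0))
  structure(
    list(coefficients = setNames(beta, colnames(x)),
         se = setNames(se, colnames(x)), vcov = vcov,
         loglik = c(null = pl0$ll, fitted = ll_old),
         score_test = list(statistic = score_stat, df = p,
                           p = pchisq(score_stat, p, lower.tail = FALSE)),
         n = n, n_events = sum(events), iter = iter,
         ties = "breslow", wald_p = setNames(2 * pnorm(-abs(z)), colnames(x))),
    class = "linc_cox")
}

#' @export
print.linc_cox <- function(x, ...) {
  cat(sprintf("<linc_cox> n = %d, events = %d, ties = %s (%d iterations)\n",
              x$n, x$n_events, x$ties, x$iter))
  print(tidy(x))
  invisible(x)
}

#' Stage-wise expression summary table
#'
#' Collapses stage sub-labels onto their main level (IA/IB to I, T1a/b/c
#' to T1, ...), reports per-stage n, median, quartiles (type-7 linear
#' interpolation), mean and SD of expression, and attaches the
#' Kruskal-Wallis p-value comparing expression across stages (skipped when
#' only one stage is present).
#'
#' @param cohort Tibble with an expression column and a stage column.
#' @param stage Name of the stage column. Default `"ajcc_stage"`.
#' @param expression Name of the expression column. Default
#'   `"expression"`.
#' @return List: `table` (per-stage tibble) and `kruskal_p`.
#' @export
stagewise_summary <- function(cohort, stage = "ajcc_stage",
                              expression = "expression") {
  stop_unless(all(c(stage, expression) %in% names(cohort)),
              "input error: missing stage or expression column")
  x <- cohort[[expression]]
  st <- collapse_stage(cohort[[stage]])
  keep <- !is.na(st)
  x <- x[keep]; st <- droplevels(factor(st[keep]))
  tab <- tibble(stage = st, expression = x) %>%
    group_by(.data$stage) %>%
    summarise(n = dplyr::n(),
              median = median(.data$expression),
              q1 = quantile(.data$expression, 0.25, type = 7, names = FALSE),
              q3 = quantile(.data$expression, 0.75, type = 7, names = FALSE),
              mean = mean(.data$expression),
              sd = sd(.data$expression),
              .groups = "drop")
  kp <- if (nlevels(st) >= 2) kruskal_wallis(x, st)$p else NA_real_
  list(table = tab, kruskal_p = kp)
}

#' Collapse pathologic stage sub-labels to their main level
#'
#' `IA`/`IB` become `I`, `IIIC` becomes `III`, `T1a`-`T1c` become `T1`,
#' `T4d` becomes `T4`; unparseable or "not available" labels become `NA`.
#'
#' @param stage Character vector of AJCC or tumor-size stage labels.
#' @return Character vector of collapsed labels.
#' @export
#' @examples
#' collapse_stage(c("IA", "IIIC", "T1b", "not available"))
collapse_stage <- function(stage) {
  s <- toupper(trimws(as.character(stage)))
  s[s %in% c("NOT AVAILABLE", "NA", "")] <- NA
  s <- sub("^STAGE\\s*", "", s)
  out <- ifelse(grepl("^T[1-4]", s), sub("^(T[1-4]).*$", "\\1", s),
                ifelse(grepl("^(IV|III|II|I)", s),
                       sub("^(IV|III|II|I).*$", "\\1", s), NA))
  out
}
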
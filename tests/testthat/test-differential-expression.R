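make_expr <- function(mat_tumor, mat_normal) {
  n_pairs <- ncol(mat_tumor)
  markers <- sprintf("m%03d", seq_len(nrow(mat_tumor)))
  design <- tibble::tibble(pair_id = sprintf("P%d", seq_len(n_pairs)),
                           normal_sample = sprintf("P%dN", seq_len(n_pairs)),
                           tumor_sample = sprintf("P%dT", seq_len(n_pairs)))
  long <- dplyr::bind_rows(
    tibble::tibble(marker_id = rep(markers, n_pairs),
                   sample_id = rep(design$tumor_sample, each = length(markers)),
                   expr = as.vector(mat_tumor)),
    tibble::tibble(marker_id = rep(markers, n_pairs),
                   sample_id = rep(design$normal_sample, each = length(markers)),
                   expr = as.vector(mat_normal)))
  list(expr = long, design = design, markers = markers)
}

test_that("paired statistics match their closed forms and a loop oracle", {
  f1 <- make_expr(matrix(2, 1, 5), matrix(1, 1, 5))
  s1 <- paired_stats(f1$expr, f1$design)
  expect_equal(s1$log2fc, 1)
  expect_equal(s1$s2, 0)

  f2 <- make_expr(matrix(c(1, 3), 1, 2), matrix(c(1, 1), 1, 2))
  s2 <- paired_stats(f2$expr, f2$design)
  expect_equal(s2$log2fc, 1)
  expect_equal(s2$s2, 2)

  set.seed(5)
  mt <- matrix(rnorm(200), 20, 10); mn <- matrix(rnorm(200), 20, 10)
  f3 <- make_expr(mt, mn)
  got <- paired_stats(f3$expr, f3$design)
  want <- oracle_paired_stats(mt, mn)
  expect_equal(got$log2fc, unname(want[, "log2fc"]), tolerance = 1e-12)
  expect_equal(got$s2, unname(want[, "s2"]), tolerance = 1e-12)

  expect_error(paired_stats(f3$expr, f3$design[1, ]), "fewer than 2 pairs")
})

test_that("missing cells drop only the affected pair for that marker", {
  mt <- matrix(rnorm(20), 4, 5); mn <- matrix(rnorm(20), 4, 5)
  f <- make_expr(mt, mn)
  f$expr$expr[f$expr$marker_id == "m002" & f$expr$sample_id == "P3T"] <- NA
  got <- paired_stats(f$expr, f$design)
  expect_equal(got$n[got$marker_id == "m002"], 4)
  expect_equal(got$n[got$marker_id == "m001"], 5)
  d <- (mt[2, ] - mn[2, ])[-3]
  expect_equal(got$log2fc[got$marker_id == "m002"], mean(d))
})

test_that("prior estimation recovers planted hyperparameters and their symmetries", {
  set.seed(11)
  df <- 4
  s2 <- 0.05 * stats::rf(50000, df, 4)
  prior <- estimate_prior(s2, df)
  expect_lt(abs(prior$d0 - 4) / 4, 0.15)
  expect_lt(abs(prior$s0_2 - 0.05) / 0.05, 0.10)

  # scale equivariance
  prior_c <- estimate_prior(s2 * 3, df)
  expect_equal(prior_c$d0, prior$d0, tolerance = 1e-9)
  expect_equal(prior_c$s0_2, prior$s0_2 * 3, tolerance = 1e-9)

  # zero dispersion of log s2 takes the infinite-d0 branch
  flat <- estimate_prior(rep(0.2, 50), df)
  expect_identical(flat$d0, Inf)
  expect_gt(flat$s0_2, 0)

  expect_error(estimate_prior(rep(0, 50), df), "degenerate")
})

test_that("prior estimation agrees with an independent empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(12)
  s2 <- 0.1 * stats::rf(5000, 4, 6)
  prior <- estimate_prior(s2, 4)
  sq <- limma::squeezeVar(s2, df = 4)
  expect_equal(prior$d0, sq$df.prior, tolerance = 0.02 * sq$df.prior)
  expect_equal(prior$s0_2, sq$var.prior, tolerance = 0.02 * sq$var.prior)
})

test_that("the d0 = 0 limit reproduces the classical paired t-test", {
  set.seed(7)
  mt <- matrix(rnorm(150, 0.3), 15, 10); mn <- matrix(rnorm(150), 15, 10)
  f <- make_expr(mt, mn)
  stats <- paired_stats(f$expr, f$design)
  prior0 <- structure(list(d0 = 0, s0_2 = 1, df = 9, n_used = 15),
                      class = "linc_eb_prior")
  got <- moderated_t(stats, prior0)
  for (i in seq_len(nrow(got))) {
    d <- mt[i, ] - mn[i, ]
    tt <- t.test(mt[i, ], mn[i, ], paired = TRUE)
    expect_equal(got$t_mod[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(got$p[i], tt$p.value, tolerance = 1e-10)
    expect_equal(got$p[i], oracle_paired_t_p(d), tolerance = 1e-10)
  }
})

test_that("the d0 = Inf limit uses the prior variance and the normal reference", {
  stats <- tibble::tibble(marker_id = "m", n = 5, log2fc = 0.8, s2 = 1)
  prior <- structure(list(d0 = Inf, s0_2 = 0.25, df = 4, n_used = 100),
                     class = "linc_eb_prior")
  got <- moderated_t(stats, prior)
  expect_equal(got$t_mod, 0.8 / sqrt(0.25 / 5))
  expect_equal(got$p, 2 * pnorm(-abs(got$t_mod)))
})

test_that("moderation shrinks the variance toward the prior from either side", {
  prior <- structure(list(d0 = 4, s0_2 = 0.5, df = 4, n_used = 100),
                     class = "linc_eb_prior")
  stats <- tibble::tibble(marker_id = c("lo", "hi"), n = 5,
                          log2fc = 1, s2 = c(0.1, 2))
  got <- moderated_t(stats, prior)
  expect_gt(got$s2_tilde[1], 0.1)
  expect_lt(got$s2_tilde[1], 0.5)
  expect_lt(got$s2_tilde[2], 2)
  expect_gt(got$s2_tilde[2], 0.5)
})

test_that("BH adjustment matches the step-up oracle and reference implementation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  # permutation invariance
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.5, 1.2)), "input error")
})

test_that("candidate filter enforces strict inequalities on all three axes", {
  res <- tibble::tibble(
    marker_id = c("keep", "fc_at_boundary", "p_at_boundary", "fdr_at_boundary"),
    p = c(0.004, 0.004, 0.005, 0.004),
    fdr = c(0.10, 0.10, 0.10, 0.15),
    log2fc = c(1.3, 1.0, 1.3, -1.3))
  kept <- select_candidates(res)
  expect_equal(kept$marker_id, "keep")
  expect_equal(kept$direction, "up")
})

test_that("negating tumor/normal roles flips fold changes and preserves p-values", {
  set.seed(9)
  mt <- matrix(rnorm(100, 0.5), 10, 10); mn <- matrix(rnorm(100), 10, 10)
  f <- make_expr(mt, mn)
  flipped_design <- dplyr::mutate(f$design,
                                  tmp = normal_sample,
                                  normal_sample = tumor_sample,
                                  tumor_sample = tmp)[, names(f$design)]
  s1 <- paired_stats(f$expr, f$design)
  s2 <- paired_stats(f$expr, flipped_design)
  prior <- estimate_prior(s1$s2, df = 9)
  r1 <- moderated_t(s1, prior)
  r2 <- moderated_t(s2, prior)
  expect_equal(r1$log2fc, -r2$log2fc)
  expect_equal(abs(r1$t_mod), abs(r2$t_mod))
  expect_equal(r1$p, r2$p)
  expect_equal(bh_adjust(r1$p), bh_adjust(r2$p))
})

test_that("locus aggregation tallies directions and flags discordance", {
  map <- tibble::tibble(marker_id = c("a", "b", "c"),
                        chrom = "chr10", pos = c(101, 151, 301))
  loci <- tibble::tibble(chrom = "chr10", start = c(100, 280),
                         end = c(200, 400), locus_id = c("L1", "L2"))
  one <- tibble::tibble(marker_id = "a", p = 1e-4, fdr = 0.01, log2fc = 1.5,
                        direction = "up")
  agg1 <- aggregate_to_loci(one, map, loci)
  expect_equal(agg1$locus_calls$direction, "up")
  expect_equal(agg1$locus_calls$n_markers_support, 1)

  disc <- tibble::tibble(marker_id = c("a", "b"), p = 1e-4, fdr = 0.01,
                         log2fc = c(1.5, -1.5), direction = c("up", "down"))
  agg2 <- aggregate_to_loci(disc, map, loci)
  expect_equal(agg2$locus_calls$direction, "discordant")
  expect_equal(agg2$summary$n_up_loci, 0)
  expect_equal(agg2$summary$n_discordant_loci, 1)

  overlapping <- dplyr::bind_rows(loci,
    tibble::tibble(chrom = "chr10", start = 120, end = 260, locus_id = "L3"))
  in_both <- tibble::tibble(marker_id = "b", p = 1e-4, fdr = 0.01,
                            log2fc = 1.5, direction = "up")
  expect_error(aggregate_to_loci(in_both, map, overlapping), "ambiguity")
})

test_that("half-open containment places boundary markers correctly", {
  loci <- tibble::tibble(chrom = "chr10", start = 100, end = 200,
                         locus_id = "L1")
  # 1-based position 101 is 0-based 100 = start (inside); position 200 is
  # 0-based 199 (inside); position 201 is 0-based 200 = end (outside)
  map <- tibble::tibble(marker_id = c("at_start", "at_end", "past_end"),
                        chrom = "chr10", pos = c(101, 200, 201))
  cand <- tibble::tibble(marker_id = map$marker_id, p = 1e-4, fdr = 0.01,
                         log2fc = 2, direction = "up")
  agg <- aggregate_to_loci(cand, map, loci)
  expect_setequal(agg$locus_calls$markers[[1]], c("at_start", "at_end"))
})

test_that("a planted multi-marker cohort aggregates to the planted summary", {
  cohort <- simulate_cohort(sim_config(
    n_pairs = 5, n_tech_replicates = 0, n_markers = 50, n_loci = 3,
    markers_per_locus = c(2, 2), frac_true_up = 1, frac_true_down = 0,
    planted_log2fc = 3, n_qc_fail_pairs = 0, seed = 61L))
  disc <- run_discovery(cohort)
  expect_equal(disc$loci$summary$n_up_loci, 3)
  expect_equal(disc$loci$summary$n_up_markers, 6)
  expect_equal(disc$loci$summary$n_down_loci, 0)
})
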
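#' Run the full discovery pipeline on a cohort
#'
#' Chains every discovery stage: technical replicates are averaged on the
#' raw scale, genotypes are called from gDNA, pairs failing genotyping QC
#' are excluded, ds-cDNA channels are quantified genotype-aware, arrays are
#' median-scaled and log2-transformed, per-marker paired statistics feed
#' the empirical-Bayes moderated t-test, p-values are BH-adjusted, the
#' candidate filter is applied and candidates are aggregated to loci.
#'
#' @param cohort A `linc_cohort` from [simulate_cohort()], or a list with
#'   the same elements read from disk.
#' @param min_call_rate Per-subject QC threshold. Default 0.95.
#' @param p_max,fdr_max,min_abs_log2fc Candidate filter thresholds;
#'   defaults 0.005, 0.15 and 1.
#' @param scale Median-scale arrays before the log transform? Default TRUE.
#' @return A `linc_discovery` list: `qc` (pair exclusions), `expr`
#'   (normalized log2 expression), `results` (per-marker DEResult tibble),
#'   `prior`, `candidates`, `loci` (a `linc_locus_calls`), and
#'   `design_used`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_markers = 60, n_loci = 10, seed = 2))
#' disc <- run_discovery(cohort)
#' disc$loci$summary
run_discovery <- function(cohort, min_call_rate = 0.95, p_max = 0.005,
                          fdr_max = 0.15, min_abs_log2fc = 1, scale = TRUE) {
  gdna <- average_replicates(cohort$gdna)
  cdna <- average_replicates(cohort$cdna)
  calls <- call_genotypes(gdna)
  qc <- qc_exclude_pairs(calls, cohort$samples, min_call_rate = min_call_rate)
  design_used <- filter(cohort$design, .data$pair_id %in% qc$retained_pairs)
  stop_unless(nrow(design_used) >= 2, "input error: fewer than 2 pairs survive QC")
  keep_samples <- c(design_used$normal_sample, design_used$tumor_sample)
  expr <- quantify_expression(filter(cdna, .data$sample_id %in% keep_samples),
                              calls)
  expr <- normalize_and_log(expr, scale = scale)
  stats <- paired_stats(expr, design_used)
  prior <- estimate_prior(stats$s2, df = max(stats$n) - 1)
  results <- moderated_t(stats, prior) %>%
    mutate(fdr = bh_adjust(.data$p))
  candidates <- select_candidates(results, p_max = p_max, fdr_max = fdr_max,
                                  min_abs_log2fc = min_abs_log2fc)
  loci <- aggregate_to_loci(candidates, cohort$marker_map, cohort$loci)
  structure(
    list(qc = qc, design_used = design_used, expr = expr, prior = prior,
         results = results, candidates = candidates, loci = loci),
    class = "linc_discovery")
}

#' @export
print.linc_discovery <- function(x, ...) {
  cat("<linc_discovery>\n")
  cat(sprintf("  pairs analyzed: %d (excluded: %s)\n", nrow(x$design_used),
              if (length(x$qc$excluded_pairs))
                paste(x$qc$excluded_pairs, collapse = ", ") else "none"))
  cat(sprintf("  markers tested: %d, candidates: %d\n",
              nrow(x$results), nrow(x$candidates)))
  print(x$loci)
  invisible(x)
}
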
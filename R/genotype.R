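#' Average technical-replicate arrays on the raw-intensity scale
#'
#' Technical replicates are independent hybridizations of the same
#' biological sample; averaging their raw channel intensities reduces
#' measurement noise without inflating the number of biological samples.
#'
#' @param intensities Long intensity tibble with `marker_id`, `sample_id`,
#'   `array_id`, `X`, `Y` (and optionally `assay`).
#' @return One row per `(marker_id, sample_id)` with channel means and the
#'   replicate count `n_arrays`.
#' @export
average_replicates <- function(intensities) {
  stop_unless(all(c("marker_id", "sample_id", "X", "Y") %in% names(intensities)),
              "input error: intensity table needs marker_id, sample_id, X, Y")
  intensities %>%
    group_by(.data$marker_id, .data$sample_id) %>%
    summarise(X = mean(.data$X), Y = mean(.data$Y),
              n_arrays = dplyr::n(), .groups = "drop")
}

#' Call genotypes from gDNA channel intensities
#'
#' Computes the allele contrast `theta = X / (X + Y)` per marker and subject
#' and converts it to a diploid call with fixed thresholds: `AA` when theta
#' is at or above `theta_hom_hi`, `BB` at or below `theta_hom_lo`, `AB`
#' inside the central band, and `NoCall` in the gaps between bands or when
#' the total intensity `X + Y` falls below the intensity floor. Calls are
#' invariant to rescaling both channels by a common factor (above the
#' floor), because theta is scale-free.
#'
#' @param gdna gDNA intensity tibble (`marker_id`, `sample_id`, `X`, `Y`);
#'   replicate arrays should be averaged first with [average_replicates()].
#' @param theta_hom_hi,theta_hom_lo Homozygote thresholds (defaults
#'   0.75/0.25).
#' @param ab_band Length-2 central heterozygote band (default
#'   `c(0.35, 0.65)`).
#' @param intensity_floor Minimum `X + Y` for a call; `NULL` (default) uses
#'   5% of the grand median total intensity.
#' @return Tibble `marker_id`, `subject_id`, `theta`, `total`, `call`.
#' @export
#' @examples
#' g <- tibble::tibble(marker_id = "m1", sample_id = "s1", X = 1000, Y = 5)
#' call_genotypes(g)$call
call_genotypes <- function(gdna, theta_hom_hi = 0.75, theta_hom_lo = 0.25,
                           ab_band = c(0.35, 0.65), intensity_floor = NULL) {
  stop_unless(all(c("marker_id", "sample_id", "X", "Y") %in% names(gdna)),
              "input error: gdna needs marker_id, sample_id, X, Y")
  bad <- which(!is.finite(gdna$X) | !is.finite(gdna$Y) | gdna$X < 0 | gdna$Y < 0)
  if (length(bad)) {
    abort(sprintf("input error: negative or non-finite intensity at marker %s, sample %s",
                  gdna$marker_id[bad[1]], gdna$sample_id[bad[1]]))
  }
  stop_unless(0 < theta_hom_lo && theta_hom_lo < theta_hom_hi && theta_hom_hi < 1,
              "input error: need 0 < theta_hom_lo < theta_hom_hi < 1")
  stop_unless(length(ab_band) == 2 && theta_hom_lo <= ab_band[1] &&
                ab_band[2] <= theta_hom_hi,
              "input error: ab_band must lie within the homozygote thresholds")

  total <- gdna$X + gdna$Y
  if (is.null(intensity_floor)) intensity_floor <- 0.05 * median(total)
  theta <- ifelse(total > 0, gdna$X / total, NA_real_)
  call <- case_when(
    total < intensity_floor | is.na(theta) ~ "NoCall",
    theta >= theta_hom_hi ~ "AA",
    theta <= theta_hom_lo ~ "BB",
    theta >= ab_band[1] & theta <= ab_band[2] ~ "AB",
    TRUE ~ "NoCall")
  tibble(marker_id = gdna$marker_id, subject_id = gdna$sample_id,
         theta = theta, total = total, call = call)
}

#' Exclude tumor/normal pairs failing genotyping QC
#'
#' A subject fails when its genotype call rate (fraction of markers not
#' `NoCall`) is below `min_call_rate`; a pair is excluded when either
#' member fails.
#'
#' @param calls Output of [call_genotypes()].
#' @param samples Tibble mapping `sample_id` to `pair_id` (e.g. the
#'   `samples` element of a [simulate_cohort()] result).
#' @param min_call_rate Minimum per-subject call rate. Default 0.95.
#' @return List with `retained_pairs` (character), `design` filtered to the
#'   retained pairs when `samples` carries group labels, and `report` (one
#'   row per subject: call rate, pass flag, exclusion reason).
#' @export
qc_exclude_pairs <- function(calls, samples, min_call_rate = 0.95) {
  stop_unless(all(c("sample_id", "pair_id") %in% names(samples)),
              "input error: unknown pair structure (need sample_id, pair_id)")
  stop_unless(all(unique(calls$subject_id) %in% samples$sample_id),
              "input error: unknown pair structure (subjects missing from `samples`)")
  report <- calls %>%
    group_by(.data$subject_id) %>%
    summarise(call_rate = mean(.data$call != "NoCall"), .groups = "drop") %>%
    left_join(select(samples, subject_id = "sample_id", "pair_id"),
              by = "subject_id") %>%
    mutate(pass = .data$call_rate >= min_call_rate)
  failed_pairs <- unique(report$pair_id[!report$pass])
  report <- report %>%
    mutate(reason = case_when(
      !.data$pass ~ sprintf("call rate %.3f < %.3f", .data$call_rate, min_call_rate),
      .data$pair_id %in% failed_pairs ~ "partner failed QC",
      TRUE ~ ""))
  all_pairs <- unique(samples$pair_id)
  list(retained_pairs = setdiff(all_pairs, failed_pairs),
       excluded_pairs = intersect(all_pairs, failed_pairs),
       report = report)
}

#' Quantify total expression from ds-cDNA channels, genotype-aware
#'
#' Implements the genotype-aware assignment rule: heterozygous (`AB`)
#' markers take the sum of the X and Y channel intensities; homozygous
#' markers take the single active channel (`AA` keeps X, `BB` keeps Y);
#' markers whose gDNA genotype is `NoCall` become missing cells. The
#' provenance of every cell is recorded.
#'
#' @param cdna ds-cDNA intensity tibble (`marker_id`, `sample_id`, `X`,
#'   `Y`); average replicates first.
#' @param calls Genotype calls from [call_genotypes()] keyed by
#'   `(marker_id, subject_id)`; the `subject_id` must match the cDNA
#'   `sample_id`.
#' @return Long expression tibble `marker_id`, `sample_id`, `expr`,
#'   `provenance` in `{het-sum, hom-X, hom-Y, missing}`; `expr` is `NA` for
#'   missing cells.
#' @export
#' @examples
#' cd <- tibble::tibble(marker_id = "m", sample_id = "s", X = 300, Y = 200)
#' gt <- tibble::tibble(marker_id = "m", subject_id = "s", call = "AB")
#' quantify_expression(cd, gt)$expr  # 500
quantify_expression <- function(cdna, calls) {
  stop_unless(all(c("marker_id", "sample_id", "X", "Y") %in% names(cdna)),
              "input error: cdna needs marker_id, sample_id, X, Y")
  joined <- cdna %>%
    left_join(select(calls, "marker_id", sample_id = "subject_id", "call"),
              by = c("marker_id", "sample_id"))
  if (anyNA(joined$call)) {
    miss <- joined[is.na(joined$call), ]
    abort(sprintf("input error: no genotype call for marker %s, sample %s",
                  miss$marker_id[1], miss$sample_id[1]))
  }
  joined %>%
    mutate(
      expr = case_when(
        .data$call == "AB" ~ .data$X + .data$Y,
        .data$call == "AA" ~ .data$X,
        .data$call == "BB" ~ .data$Y,
        TRUE ~ NA_real_),
      provenance = case_when(
        .data$call == "AB" ~ "het-sum",
        .data$call == "AA" ~ "hom-X",
        .data$call == "BB" ~ "hom-Y",
        TRUE ~ "missing")) %>%
    select("marker_id", "sample_id", "expr", "provenance")
}

#' Median-scale arrays and move to the log2 scale
#'
#' Scales each array (sample) so its median expression equals the grand
#' median over all arrays, then applies `log2(e + 1)`. Missing cells
#' propagate. With `scale = FALSE` the median scaling is skipped
#' (pass-through mode) and only the log transform is applied.
#'
#' @param expr Long expression tibble from [quantify_expression()].
#' @param scale Apply per-array median scaling? Default `TRUE`.
#' @return The tibble with `expr` replaced by its normalized log2 value and
#'   a `scale_factor` column recording each array's multiplier.
#' @export
normalize_and_log <- function(expr, scale = TRUE) {
  stop_unless(all(c("marker_id", "sample_id", "expr") %in% names(expr)),
              "input error: expression table needs marker_id, sample_id, expr")
  stop_unless(all(expr$expr >= 0, na.rm = TRUE),
              "input error: negative expression values")
  med <- expr %>%
    group_by(.data$sample_id) %>%
    summarise(array_median = median(.data$expr, na.rm = TRUE), .groups = "drop")
  if (any(med$array_median == 0 | !is.finite(med$array_median))) {
    abort(sprintf("input error: array %s has median 0",
                  med$sample_id[which(med$array_median == 0 |
                                        !is.finite(med$array_median))[1]]))
  }
  grand <- median(expr$expr, na.rm = TRUE)
  expr %>%
    left_join(med, by = "sample_id") %>%
    mutate(scale_factor = if (scale) grand / .data$array_median else 1,
           expr = log2(.data$expr * .data$scale_factor + 1)) %>%
    select(-"array_median")
}

#' Pivot a long expression table to a markers-by-samples matrix
#'
#' @param expr Long expression tibble.
#' @param value Column to spread. Default `"expr"`.
#' @return Numeric matrix, rownames = marker ids, colnames = sample ids.
#' @export
expr_matrix <- function(expr, value = "expr") {
  wide <- expr %>%
    select("marker_id", "sample_id", all_of(value)) %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = all_of(value))
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$marker_id
  m
}
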
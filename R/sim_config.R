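#' Simulation configuration for a paired two-channel array cohort
#'
#' Bundles and validates every knob of the synthetic cohort generator.
#' The defaults reproduce the shape of a seven-pair tumor/normal breast
#' study profiled on a two-colour genotyping BeadChip: 7 pairs (14
#' biological samples), 2 of them additionally hybridized as technical
#' replicates on both assays (32 arrays in total), and 2 pairs planted to
#' fail genotyping QC so that 5 pairs survive to analysis.
#'
#' @param n_pairs Number of tumor/normal pairs (individuals). Default 7.
#' @param n_tech_replicates Number of samples (taken in sample order) that
#'   receive one extra technical-replicate array on both assays. Default 2.
#' @param n_markers Total number of SNP markers on the array. Loci are tiled
#'   with `markers_per_locus` markers each; the remainder are intergenic
#'   background markers belonging to no locus. Default 300.
#' @param n_loci Number of annotated intergenic lncRNA loci. Default 40.
#' @param markers_per_locus Integer range (length-2 vector) of markers per
#'   locus. Default `c(2, 5)`.
#' @param frac_true_up,frac_true_down Proportions of loci planted as up- or
#'   downregulated in tumors. Defaults 0.10 each.
#' @param planted_log2fc Absolute log2 fold change planted at non-null loci.
#'   Default 2.
#' @param intensity_scale Expected total fluorescence (arbitrary units) of a
#'   gDNA marker; cDNA levels are drawn log-normally around a comparable
#'   scale. Default 1000.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   channel noise. Default 0.15.
#' @param maf_range Minor-allele-frequency interval, a subset of (0, 0.5].
#'   Default `c(0.05, 0.5)`.
#' @param background_frac Cross-talk fraction of the active-channel signal
#'   seen on the silent gDNA channel of a homozygous marker. Default 0.04.
#' @param n_qc_fail_pairs Number of pairs planted to fail genotyping QC (both
#'   members have a fifth of their gDNA markers driven below the intensity
#'   floor, call rate about 0.80). Default 2.
#' @param qc_fail_call_rate Target call rate of a planted QC-failure subject.
#'   Default 0.80.
#' @param seed Integer RNG seed; identical seed and config give identical
#'   output, byte for byte when written to disk.
#'
#' @return A `linc_sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_markers = 60, n_loci = 10, seed = 1)
sim_config <- function(n_pairs = 7,
                       n_tech_replicates = 2,
                       n_markers = 300,
                       n_loci = 40,
                       markers_per_locus = c(2, 5),
                       frac_true_up = 0.10,
                       frac_true_down = 0.10,
                       planted_log2fc = 2,
                       intensity_scale = 1000,
                       noise_cv = 0.15,
                       maf_range = c(0.05, 0.5),
                       background_frac = 0.04,
                       n_qc_fail_pairs = 2,
                       qc_fail_call_rate = 0.80,
                       seed = 1L) {
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  for (nm in c("n_pairs", "n_tech_replicates", "n_markers", "n_loci",
               "markers_per_locus", "frac_true_up", "frac_true_down",
               "planted_log2fc", "intensity_scale", "noise_cv", "maf_range",
               "background_frac", "n_qc_fail_pairs", "qc_fail_call_rate",
               "seed")) {
    stop_unless(num_ok(get(nm)), "configuration error: `%s` must be finite numeric", nm)
  }
  stop_unless(n_pairs >= 1 && n_markers >= 1 && n_loci >= 1,
              "configuration error: counts must be >= 1")
  stop_unless(all(markers_per_locus >= 1) && length(markers_per_locus) == 2 &&
                markers_per_locus[1] <= markers_per_locus[2],
              "configuration error: markers_per_locus must be an increasing range >= 1")
  stop_unless(frac_true_up >= 0 && frac_true_down >= 0 &&
                frac_true_up + frac_true_down <= 1,
              "configuration error: effect fractions must be in [0,1] and sum <= 1")
  stop_unless(length(maf_range) == 2 && maf_range[1] > 0 && maf_range[2] <= 0.5 &&
                maf_range[1] <= maf_range[2],
              "configuration error: maf_range must lie in (0, 0.5]")
  stop_unless(noise_cv >= 0, "configuration error: noise_cv must be >= 0")
  stop_unless(n_tech_replicates >= 0 && n_tech_replicates <= 2 * n_pairs,
              "configuration error: n_tech_replicates must be in [0, 2*n_pairs]")
  stop_unless(n_qc_fail_pairs >= 0 && n_qc_fail_pairs <= n_pairs,
              "configuration error: n_qc_fail_pairs must be in [0, n_pairs]")
  stop_unless(n_markers >= n_loci * markers_per_locus[2],
              "configuration error: n_markers too small for n_loci x markers_per_locus")

  structure(
    list(n_pairs = as.integer(n_pairs),
         n_tech_replicates = as.integer(n_tech_replicates),
         n_markers = as.integer(n_markers),
         n_loci = as.integer(n_loci),
         markers_per_locus = as.integer(markers_per_locus),
         frac_true_up = frac_true_up,
         frac_true_down = frac_true_down,
         planted_log2fc = planted_log2fc,
         intensity_scale = intensity_scale,
         noise_cv = noise_cv,
         maf_range = maf_range,
         background_frac = background_frac,
         n_qc_fail_pairs = as.integer(n_qc_fail_pairs),
         qc_fail_call_rate = qc_fail_call_rate,
         seed = as.integer(seed)),
    class = "linc_sim_config"
  )
}

#' @export
print.linc_sim_config <- function(x, ...) {
  cat("<linc_sim_config>\n")
  cat(sprintf("  %d pairs (+%d technical replicate arrays per assay), %d markers, %d loci\n",
              x$n_pairs, x$n_tech_replicates, x$n_markers, x$n_loci))
  cat(sprintf("  planted effects: %.0f%% up / %.0f%% down at |log2FC| = %g; noise CV %g\n",
              100 * x$frac_true_up, 100 * x$frac_true_down, x$planted_log2fc, x$noise_cv))
  invisible(x)
}
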
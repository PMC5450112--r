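# Readers and writers for the pipeline's plain-text dialects. Intensity
# tables travel wide (marker_id then <sample>.X, <sample>.Y columns); the
# package works on the long form internally.

#' Write a cohort's inputs to a directory
#'
#' Emits the file set consumed by the command-line pipeline: wide gDNA and
#' cDNA intensity TSVs, the marker map TSV (1-based positions), the locus
#' BED (0-based half-open, locus IDs in column 4), the design TSV and the
#' ground-truth TSV.
#'
#' @param cohort A `linc_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f <- function(...) file.path(dir, ...)
  write_intensity_tsv(cohort$gdna, f("gdna.tsv"))
  write_intensity_tsv(cohort$cdna, f("cdna.tsv"))
  readr::write_tsv(cohort$marker_map, f("markers.tsv"))
  write_bed(cohort$loci, f("loci.bed"))
  readr::write_tsv(cohort$design, f("design.tsv"))
  readr::write_tsv(cohort$samples, f("samples.tsv"))
  readr::write_tsv(cohort$truth, f("truth.tsv"))
  invisible(f(c("gdna.tsv", "cdna.tsv", "markers.tsv", "loci.bed",
                "design.tsv", "samples.tsv", "truth.tsv")))
}

#' Write a long intensity table as a wide TSV
#'
#' One row per marker; per array a pair of columns `<array>.X`,
#' `<array>.Y`.
#'
#' @param intensities Long tibble (`marker_id`, `array_id`, `X`, `Y`).
#' @param path Output file.
#' @export
write_intensity_tsv <- function(intensities, path) {
  wide <- intensities %>%
    select("marker_id", "array_id", "X", "Y") %>%
    tidyr::pivot_longer(c("X", "Y"), names_to = "channel") %>%
    mutate(col = paste(.data$array_id, .data$channel, sep = ".")) %>%
    select("marker_id", "col", "value") %>%
    tidyr::pivot_wider(names_from = "col", values_from = "value")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read a wide intensity TSV back to long form
#'
#' Inverse of [write_intensity_tsv()]. Sample ids are recovered from array
#' ids by stripping a trailing `_r<k>` replicate suffix.
#'
#' @param path TSV file with `marker_id` then `<array>.X`/`<array>.Y`
#'   columns.
#' @param assay Label stored in the `assay` column.
#' @return Long intensity tibble.
#' @export
read_intensity_tsv <- function(path, assay = NA_character_) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  stop_unless("marker_id" %in% names(wide),
              "input error: %s lacks a marker_id column", path)
  long <- wide %>%
    tidyr::pivot_longer(-"marker_id", names_to = "col") %>%
    tidyr::separate_wider_regex("col",
                                c(array_id = ".*", "\\.", channel = "[XY]$")) %>%
    tidyr::pivot_wider(names_from = "channel", values_from = "value") %>%
    mutate(sample_id = sub("_r\\d+$", "", .data$array_id), assay = assay) %>%
    select("marker_id", "sample_id", "array_id", "assay", "X", "Y")
  long
}

#' Write a BED file (0-based, half-open) of loci
#'
#' @param loci Tibble `chrom`, `start`, `end`, `locus_id`.
#' @param path Output file.
#' @export
write_bed <- function(loci, path) {
  readr::write_tsv(select(loci, "chrom", "start", "end", "locus_id"),
                   path, col_names = FALSE)
  invisible(path)
}

#' Read a locus BED file
#'
#' @param path BED file with at least 4 columns (chrom, start, end, name).
#' @return Tibble `chrom`, `start`, `end`, `locus_id`.
#' @export
read_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "locus_id"),
                  col_types = "ciic", show_col_types = FALSE)
}

#' Write the discovery outputs of a pipeline run
#'
#' Writes the per-marker DEResult TSV, the locus-call TSV, a JSON run
#' summary (filter counts and cell provenance tallies) and a
#' heatmap-ready matrix of per-pair log2 differences for the candidate
#' markers.
#'
#' @param disc A `linc_discovery` from [run_discovery()].
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_discovery <- function(disc, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f <- function(...) file.path(dir, ...)
  readr::write_tsv(disc$results, f("de_results.tsv"))
  lc <- disc$loci$locus_calls %>%
    mutate(markers = purrr::map_chr(.data$markers, paste, collapse = ","))
  readr::write_tsv(lc, f("locus_calls.tsv"))
  summ <- list(
    pairs_analyzed = nrow(disc$design_used),
    pairs_excluded = disc$qc$excluded_pairs,
    n_markers_tested = nrow(disc$results),
    n_candidates = nrow(disc$candidates),
    locus_summary = as.list(disc$loci$summary),
    provenance_counts = as.list(table(disc$expr$provenance)),
    prior = list(d0 = unname(disc$prior$d0), s0_2 = unname(disc$prior$s0_2)))
  jsonlite::write_json(summ, f("run_summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  readr::write_tsv(pair_diff_matrix(disc), f("candidate_pair_diffs.tsv"))
  invisible(f(c("de_results.tsv", "locus_calls.tsv", "run_summary.json",
                "candidate_pair_diffs.tsv")))
}

# markers x pairs table of per-pair log2 differences for candidate markers
pair_diff_matrix <- function(disc) {
  d <- disc$expr %>%
    filter(.data$marker_id %in% disc$candidates$marker_id)
  des <- disc$design_used
  purrr::map_dfr(seq_len(nrow(des)), function(i) {
    tn <- d %>% filter(.data$sample_id == des$tumor_sample[i])
    nn <- d %>% filter(.data$sample_id == des$normal_sample[i])
    inner_join(select(tn, "marker_id", t = "expr"),
               select(nn, "marker_id", n = "expr"), by = "marker_id") %>%
      mutate(pair_id = des$pair_id[i], d = .data$t - .data$n) %>%
      select("marker_id", "pair_id", "d")
  }) %>%
    tidyr::pivot_wider(names_from = "pair_id", values_from = "d")
}
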
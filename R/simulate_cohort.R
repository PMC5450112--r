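#' Simulate a paired tumor/normal two-channel array cohort
#'
#' Generates every input of the discovery pipeline with known ground truth:
#' gDNA and ds-cDNA X/Y channel intensities per marker and array, the marker
#' map, the intergenic-locus annotation, and the planted per-locus truth.
#'
#' Each pair contributes a normal and a tumor sample; both members share the
#' pair's germline genotype, drawn under Hardy-Weinberg equilibrium at each
#' marker's minor-allele frequency. gDNA intensities cluster by genotype
#' (AA: high-X/low-Y, AB: balanced, BB: low-X/high-Y); ds-cDNA total
#' intensity is proportional to the expression level of the marker's locus
#' and is split across channels by the genotype allele balance (0.5/0.5 for
#' AB). Tumor samples of "up" loci are multiplied by `2^planted_log2fc`
#' ("down" loci by its reciprocal). All noise is multiplicative log-normal
#' with coefficient of variation `noise_cv`; at `noise_cv = 0` the channel
#' sums are exact. Samples designated as technical replicates receive a
#' second, independently noised array on both assays. Pairs planted as QC
#' failures have a fraction of their gDNA markers driven below the intensity
#' floor so that their genotype call rate drops to about
#' `qc_fail_call_rate`.
#'
#' @param config A [sim_config()] object.
#' @return A `linc_cohort` list of tibbles:
#' \describe{
#'   \item{gdna, cdna}{long intensity tables: `marker_id`, `sample_id`,
#'     `array_id`, `assay`, `X`, `Y`.}
#'   \item{marker_map}{`marker_id`, `chrom`, `pos` (1-based).}
#'   \item{loci}{BED-style `chrom`, `start`, `end` (0-based half-open),
#'     `locus_id`.}
#'   \item{truth}{`locus_id`, `direction` (up/down/null), `true_log2fc`.}
#'   \item{design}{`pair_id`, `normal_sample`, `tumor_sample`.}
#'   \item{samples}{`sample_id`, `pair_id`, `group`, `qc_fail_planted`,
#'     `tech_replicate`.}
#'   \item{genotypes_true}{`marker_id`, `sample_id`, `genotype` — the
#'     simulated truth, for concordance checks only.}
#' }
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_markers = 60, n_loci = 10, seed = 7))
#' dplyr::count(cohort$truth, direction)
simulate_cohort <- function(config = sim_config()) {
  stop_unless(inherits(config, "linc_sim_config"),
              "configuration error: `config` must come from sim_config()")
  cfg <- config
  set.seed(cfg$seed)

  ## ---- genome layout -------------------------------------------------
  k_range <- seq(cfg$markers_per_locus[1], cfg$markers_per_locus[2])
  k_locus <- if (length(k_range) == 1) rep(k_range, cfg$n_loci) else {
    sample(k_range, cfg$n_loci, replace = TRUE)
  }
  n_locus_markers <- sum(k_locus)
  n_orphan <- cfg$n_markers - n_locus_markers

  cursor <- 10000L
  locus_rows <- vector("list", cfg$n_loci)
  marker_rows <- vector("list", cfg$n_loci)
  for (j in seq_len(cfg$n_loci)) {
    width <- 500L * (k_locus[j] + 1L)
    start0 <- cursor
    pos1 <- start0 + 500L * seq_len(k_locus[j])  # 1-based, strictly inside
    locus_rows[[j]] <- tibble(chrom = "chr10", start = start0,
                              end = start0 + width,
                              locus_id = sprintf("LOC%03d", j))
    marker_rows[[j]] <- tibble(
      marker_id = sprintf("kgp%03d_%02d", j, seq_len(k_locus[j])),
      chrom = "chr10", pos = pos1, locus_id = sprintf("LOC%03d", j))
    cursor <- start0 + width + 5000L
  }
  loci <- bind_rows(locus_rows)
  map_in <- bind_rows(marker_rows)
  map_orphan <- if (n_orphan > 0) {
    tibble(marker_id = sprintf("bg%05d", seq_len(n_orphan)),
           chrom = "chr10", pos = cursor + 1000L * seq_len(n_orphan),
           locus_id = NA_character_)
  } else {
    tibble(marker_id = character(), chrom = character(),
           pos = integer(), locus_id = character())
  }
  marker_map <- bind_rows(map_in, map_orphan)

  ## ---- planted truth -------------------------------------------------
  n_up <- round(cfg$frac_true_up * cfg$n_loci)
  n_down <- round(cfg$frac_true_down * cfg$n_loci)
  direction <- rep("null", cfg$n_loci)
  hit <- sample(cfg$n_loci, n_up + n_down)
  direction[hit[seq_len(n_up)]] <- "up"
  if (n_down > 0) direction[hit[n_up + seq_len(n_down)]] <- "down"
  truth <- tibble(
    locus_id = loci$locus_id,
    direction = direction,
    true_log2fc = ifelse(direction == "up", cfg$planted_log2fc,
                         ifelse(direction == "down", -cfg$planted_log2fc, 0)))

  ## ---- samples and arrays -------------------------------------------
  pair_id <- sprintf("P%d", seq_len(cfg$n_pairs))
  samples <- tibble(
    sample_id = as.vector(t(outer(pair_id, c("N", "T"), paste0))),
    pair_id = rep(pair_id, each = 2),
    group = rep(c("normal", "tumor"), cfg$n_pairs))
  samples$tech_replicate <- seq_len(nrow(samples)) <= cfg$n_tech_replicates
  qc_fail_pairs <- if (cfg$n_qc_fail_pairs > 0) {
    pair_id[cfg$n_pairs - seq_len(cfg$n_qc_fail_pairs) + 1L]
  } else character()
  samples$qc_fail_planted <- samples$pair_id %in% qc_fail_pairs
  design <- tibble(pair_id = pair_id,
                   normal_sample = paste0(pair_id, "N"),
                   tumor_sample = paste0(pair_id, "T"))

  ## ---- germline genotypes (Hardy-Weinberg, shared within a pair) -----
  maf <- runif(cfg$n_markers, cfg$maf_range[1], cfg$maf_range[2])
  n_b <- matrix(rbinom(cfg$n_markers * cfg$n_pairs, 2,
                       rep(maf, cfg$n_pairs)),
                nrow = cfg$n_markers)  # copies of minor allele B per pair
  geno_chr <- c("AA", "AB", "BB")
  genotypes_true <- tibble(
    marker_id = rep(marker_map$marker_id, times = 2 * cfg$n_pairs),
    sample_id = rep(samples$sample_id, each = cfg$n_markers),
    genotype = geno_chr[as.vector(n_b[, rep(seq_len(cfg$n_pairs), each = 2)]) + 1L])

  noise <- function(n) {
    if (cfg$noise_cv == 0) return(rep(1, n))
    sig <- sqrt(log(1 + cfg$noise_cv^2))
    exp(rnorm(n, -sig^2 / 2, sig))
  }

  ## ---- gDNA arrays ----------------------------------------------------
  bg <- cfg$background_frac
  clean_gdna <- function(g) {
    # columns X, Y of the noiseless genotype clusters
    tot <- cfg$intensity_scale
    x <- ifelse(g == "AA", tot * (1 - bg), ifelse(g == "AB", tot / 2, tot * bg))
    cbind(X = x, Y = tot - x)
  }
  rep_samples <- samples$sample_id[samples$tech_replicate]
  gdna_arrays <- tibble(
    sample_id = c(samples$sample_id, rep_samples),
    array_id = c(samples$sample_id, sprintf("%s_r2", rep_samples)))
  gdna <- purrr::map_dfr(seq_len(nrow(gdna_arrays)), function(i) {
    sid <- gdna_arrays$sample_id[i]
    g <- genotypes_true$genotype[genotypes_true$sample_id == sid]
    ch <- clean_gdna(g)
    x <- ch[, "X"] * noise(cfg$n_markers)
    y <- ch[, "Y"] * noise(cfg$n_markers)
    if (sid %in% samples$sample_id[samples$qc_fail_planted]) {
      n_kill <- round((1 - cfg$qc_fail_call_rate) * cfg$n_markers)
      kill <- sample(cfg$n_markers, n_kill)
      x[kill] <- x[kill] * 1e-4
      y[kill] <- y[kill] * 1e-4
    }
    tibble(marker_id = marker_map$marker_id, sample_id = sid,
           array_id = gdna_arrays$array_id[i], assay = "gDNA", X = x, Y = y)
  })

  ## ---- ds-cDNA arrays -------------------------------------------------
  # locus-level baseline expression, right-skewed; orphan markers draw their own
  level_locus <- rlnorm(cfg$n_loci, log(cfg$intensity_scale / 2), 1)
  level_marker <- numeric(cfg$n_markers)
  in_locus <- !is.na(marker_map$locus_id)
  level_marker[in_locus] <-
    level_locus[match(marker_map$locus_id[in_locus], loci$locus_id)]
  level_marker[!in_locus] <- rlnorm(sum(!in_locus), log(cfg$intensity_scale / 2), 1)
  fc_marker <- rep(1, cfg$n_markers)
  fc_marker[in_locus] <-
    2^truth$true_log2fc[match(marker_map$locus_id[in_locus], truth$locus_id)]

  cdna_arrays <- gdna_arrays  # same replicate structure on both assays
  cdna <- purrr::map_dfr(seq_len(nrow(cdna_arrays)), function(i) {
    sid <- cdna_arrays$sample_id[i]
    g <- genotypes_true$genotype[genotypes_true$sample_id == sid]
    is_tumor <- samples$group[match(sid, samples$sample_id)] == "tumor"
    e <- level_marker * (if (is_tumor) fc_marker else 1)
    x_clean <- ifelse(g == "AA", e, ifelse(g == "AB", e / 2, 0))
    y_clean <- e - x_clean
    tibble(marker_id = marker_map$marker_id, sample_id = sid,
           array_id = cdna_arrays$array_id[i], assay = "cDNA",
           X = x_clean * noise(cfg$n_markers),
           Y = y_clean * noise(cfg$n_markers))
  })

  structure(
    list(gdna = gdna, cdna = cdna,
         marker_map = select(marker_map, "marker_id", "chrom", "pos"),
         loci = loci, truth = truth, design = design, samples = samples,
         genotypes_true = genotypes_true, config = cfg),
    class = "linc_cohort")
}

#' @export
print.linc_cohort <- function(x, ...) {
  cat("<linc_cohort>\n")
  cat(sprintf("  %d pairs, %d markers, %d loci; %d gDNA + %d cDNA arrays\n",
              nrow(x$design), nrow(x$marker_map), nrow(x$loci),
              n_distinct(x$gdna$array_id), n_distinct(x$cdna$array_id)))
  tb <- table(x$truth$direction)
  cat("  planted loci:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
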
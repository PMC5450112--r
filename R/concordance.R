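#' Filter per-gene knockdown statistics to significant genes
#'
#' Keeps genes with `p < p_max` (strict), so boundary p-values are
#' rejected.
#'
#' @param stats GeneStat tibble with `gene_id` and `p` columns.
#' @param p_max Significance threshold. Default 0.001.
#' @return The filtered tibble.
#' @export
de_filter <- function(stats, p_max = 0.001) {
  stop_unless(all(c("gene_id", "p") %in% names(stats)),
              "input error: stats need gene_id and p")
  stop_unless(all(stats$p >= 0 & stats$p <= 1, na.rm = TRUE),
              "input error: p-values outside [0,1]")
  filter(stats, .data$p < p_max)
}

#' Overlap between two identifier sets
#'
#' @param set_a,set_b Non-empty vectors of identifiers (duplicates are
#'   collapsed).
#' @return Tibble `n_a`, `n_b`, `n_overlap`, `pct_of_a`, `pct_of_b`,
#'   `min_pct` (percentages of each set covered by the intersection).
#' @export
#' @examples
#' overlap_sets(paste0("p", 1:75), paste0("p", 2:77))
overlap_sets <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  stop_unless(length(a) > 0 && length(b) > 0,
              "input error: overlap percentage undefined for an empty set")
  ov <- length(intersect(a, b))
  tibble(n_a = length(a), n_b = length(b), n_overlap = ov,
         pct_of_a = 100 * ov / length(a),
         pct_of_b = 100 * ov / length(b),
         min_pct = min(100 * ov / length(a), 100 * ov / length(b)))
}

#' Spearman rank correlation with tie handling
#'
#' Pearson correlation of mid-ranks; `rho^2` is reported alongside `rho`
#' because concordance write-ups often print an "R2" for the Spearman
#' analysis. The p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df, or exact
#' permutation enumeration when `n <= 8`.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @param exact_max Largest n for exact enumeration. Default 8.
#' @return Tibble `rho`, `rho2`, `p`, `n`, `method`.
#' @export
spearman_rho <- function(x, y, exact_max = 8) {
  stop_unless(length(x) == length(y), "input error: x and y differ in length")
  n <- length(x)
  stop_unless(n >= 3, "input error: need >= 3 pairs")
  stop_unless(length(unique(x)) > 1 && length(unique(y)) > 1,
              "undefined-correlation error: constant input vector")
  rx <- rank(x); ry <- rank(y)
  rho_of <- function(a, b) {
    suppressWarnings(stats::cor(a, b))
  }
  rho <- rho_of(rx, ry)
  if (n <= exact_max) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(pm) rho_of(rx, ry[pm]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    return(tibble(rho = rho, rho2 = rho^2, p = p, n = n,
                  method = "exact_permutation"))
  }
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), n - 2)
  tibble(rho = rho, rho2 = rho^2, p = min(1, p), n = n,
         method = "t_approximation")
}

# all n! permutations of 1..n as rows (n <= 8)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Concordance report between two knockdown treatments
#'
#' Applies the DE filter to both treatments' GeneStat tables, counts the
#' overlapping significant genes, rank-correlates the log2 fold changes of
#' the overlapping genes, and (optionally) computes pathway-set overlap
#' percentages.
#'
#' @param stats_a,stats_b GeneStat tibbles (`gene_id`, `log2fc`, `p`).
#' @param p_max DE threshold passed to [de_filter()]. Default 0.001.
#' @param pathways_a,pathways_b Optional pathway identifier vectors.
#' @return A `linc_concordance` list: `n_sig_a`, `n_sig_b`, `n_overlap`,
#'   `overlap_genes`, `spearman` (tibble from [spearman_rho()]),
#'   `gene_overlap` and optionally `pathway_overlap` tibbles from
#'   [overlap_sets()].
#' @export
concordance_report <- function(stats_a, stats_b, p_max = 0.001,
                               pathways_a = NULL, pathways_b = NULL) {
  sig_a <- de_filter(stats_a, p_max)
  sig_b <- de_filter(stats_b, p_max)
  shared <- intersect(sig_a$gene_id, sig_b$gene_id)
  sp <- if (length(shared) >= 3) {
    spearman_rho(sig_a$log2fc[match(shared, sig_a$gene_id)],
                 sig_b$log2fc[match(shared, sig_b$gene_id)])
  } else NULL
  out <- list(
    n_sig_a = nrow(sig_a), n_sig_b = nrow(sig_b),
    n_overlap = length(shared), overlap_genes = shared,
    gene_overlap = if (nrow(sig_a) && nrow(sig_b))
      overlap_sets(sig_a$gene_id, sig_b$gene_id) else NULL,
    spearman = sp,
    pathway_overlap = if (!is.null(pathways_a) && !is.null(pathways_b))
      overlap_sets(pathways_a, pathways_b) else NULL)
  structure(out, class = "linc_concordance")
}

#' @export
print.linc_concordance <- function(x, ...) {
  cat(sprintf("<linc_concordance> %d vs %d significant genes, %d overlapping\n",
              x$n_sig_a, x$n_sig_b, x$n_overlap))
  if (!is.null(x$spearman)) {
    cat(sprintf("  Spearman rho = %.4f (rho^2 = %.4f, p = %.3g)\n",
                x$spearman$rho, x$spearman$rho2, x$spearman$p))
  }
  if (!is.null(x$pathway_overlap)) {
    cat(sprintf("  pathway overlap: %d/%d and %d/%d (min %.1f%%)\n",
                x$pathway_overlap$n_overlap, x$pathway_overlap$n_a,
                x$pathway_overlap$n_overlap, x$pathway_overlap$n_b,
                x$pathway_overlap$min_pct))
  }
  invisible(x)
}
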
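# Small cohorts reused across tests; built in code, deterministic.

tiny_config <- function(...) {
  defaults <- list(n_pairs = 5, n_tech_replicates = 0, n_markers = 60,
                   n_loci = 10, markers_per_locus = c(2, 3),
                   n_qc_fail_pairs = 0, seed = 101L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# small censored survival fixture with ties
surv_fixture <- function(seed = 1, n = 40) {
  set.seed(seed)
  tibble::tibble(
    time = sample(1:15, n, replace = TRUE),
    event = stats::rbinom(n, 1, 0.7),
    group = sample(c("a", "b"), n, replace = TRUE))
}
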
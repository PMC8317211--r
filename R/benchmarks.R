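#' Seeded false-discovery-rate and recovery benchmarks
#'
#' Two standard operating checks of the permutation-FDR engine, run on the
#' synthetic study design.
#'
#' `fdr_null_benchmark()` simulates datasets with no true effects (the study
#' layout: 2 plexes, n = 4 per group), normalizes them, and runs the MC vs FC
#' moderated test at the default settings (`s0 = 0.5`, 250 requested
#' randomizations, which for 4 + 4 samples means all 69 distinct non-identity
#' assignments). The per-run empirical false-discovery proportion is
#' `fp / max(1, tp + fp)` from [truth_confusion()]; under a pure null this is
#' 1 when anything is called and 0 otherwise, so its mean over runs estimates
#' the probability of a false discovery and should sit at or below the target
#' FDR up to binomial error. The ANOVA prefilter is disabled so that the
#' permutation engine itself, not the prefilter, is what is measured.
#'
#' `recovery_benchmark()` injects exact 1.0 log2 sex and treatment effects
#' (10% of proteins each) at within-group sd 0.25 and measures pooled
#' sensitivity and empirical FDR over the three pairwise contrasts. Missing
#' cells are disabled so that the measured sensitivity reflects the detection
#' method rather than row-level missing-value filtering.
#'
#' @param n_runs Number of seeded simulation runs.
#' @param n_proteins Proteins per simulated dataset.
#' @param seed Root seed; run r uses deterministic offsets from it.
#' @param config A [test_config()] (the prefilter flag is forced off).
#' @return A tibble with one [truth_confusion()] row per run (and per
#'   contrast for the recovery benchmark). Summarize with
#'   [summarize_benchmark()].
#' @export
fdr_null_benchmark <- function(n_runs = 50, n_proteins = 200, seed = 1L,
                               config = test_config()) {
  config$anova_enabled <- FALSE
  purrr::map_dfr(seq_len(n_runs), function(r) {
    d <- synthetic_design(
      n_proteins = n_proteins,
      frac_sex_de = 0, frac_trt_de_f = 0, frac_trt_de_m = 0,
      seed = seed + 101L * r
    )
    ds <- generate_dataset(d)
    norm <- normalize_pipeline(filter_rows(ds$data), "irs")
    cfg <- config
    cfg$seed <- seed + 31L * r
    comp <- permutation_fdr(norm, "MC", "FC", cfg)
    dplyr::mutate(truth_confusion(ds$truth, comp, "MC_vs_FC"), run = r, .before = 1)
  })
}

#' @rdname fdr_null_benchmark
#' @export
recovery_benchmark <- function(n_runs = 5, n_proteins = 200, seed = 1L,
                               config = test_config()) {
  config$anova_enabled <- FALSE
  purrr::map_dfr(seq_len(n_runs), function(r) {
    d <- synthetic_design(
      n_proteins = n_proteins,
      effect_size_log2 = 1.0, effect_sd_log2 = 0,
      sigma_within = 0.25, frac_missing = 0,
      seed = seed + 101L * r
    )
    ds <- generate_dataset(d)
    norm <- normalize_pipeline(filter_rows(ds$data), "irs")
    cfg <- config
    cfg$seed <- seed + 31L * r
    suite <- run_pairwise_suite(norm, cfg)
    purrr::map_dfr(
      names(suite),
      function(cc) truth_confusion(ds$truth, suite[[cc]], cc)
    ) |>
      dplyr::mutate(run = r, .before = 1)
  })
}

#' @rdname fdr_null_benchmark
#' @param results Tibble returned by either benchmark.
#' @return `summarize_benchmark()`: one row with the mean per-run empirical
#'   FDR, the pooled empirical FDR (`sum(fp) / max(1, sum(tp + fp))`) and the
#'   pooled sensitivity.
#' @export
summarize_benchmark <- function(results) {
  tibble::tibble(
    n_runs = length(unique(results$run)),
    mean_fdr = mean(results$fdr),
    pooled_fdr = sum(results$fp) / max(1, sum(results$tp) + sum(results$fp)),
    pooled_sensitivity = sum(results$tp) / max(1, sum(results$tp) + sum(results$fn))
  )
}
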
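#' Synthetic TMT study design
#'
#' Parameters of the seeded generator that emulates the study layout: two TMT
#' 10-plexes, each carrying two biological replicates of the four sex x
#' treatment groups (MC, FC, MN, FN) plus two pooled reference channels mixing
#' the eight experimental channels of the plex in equal amounts. Per protein
#' and channel the log2 signal is
#' `base + group effect + batch shift(plex) + N(0, sigma_within)`, the
#' intensity is `loading * 2^signal`, and each pooled channel is the
#' loading-scaled arithmetic mean of the plex's eight experimental pre-loading
#' intensities with its own technical noise.
#'
#' @param n_proteins Number of real protein rows (> 0).
#' @param n_plexes Number of TMT runs (default 2).
#' @param reps_per_group Biological replicates of each group per plex
#'   (default 2, i.e. n = 4 per group over two plexes).
#' @param frac_sex_de,frac_trt_de_f,frac_trt_de_m Fractions of proteins with a
#'   true sex effect (MC vs FC), a treatment effect in females (FN vs FC), and
#'   a treatment effect in males (MN vs MC).
#' @param effect_size_log2,effect_sd_log2 Mean absolute log2 effect and its
#'   spread; signs are random.
#' @param sigma_within Within-group log2 standard deviation (> 0 allowed to be
#'   0 for exactness checks).
#' @param sigma_pool Technical log2 noise of the pooled channels.
#' @param base_mean_log2,base_sd_log2 Log-normal base-abundance parameters
#'   (log2 scale), mimicking reporter-ion dynamic range.
#' @param loading_sd_log2 Per-channel loading factors are `2^N(0, sd)`; set 0
#'   for unit loading. Alternatively pass `loading_factors`, one per channel.
#' @param loading_factors Optional explicit per-channel loading multipliers.
#' @param batch_sd_log2 Per-protein, per-plex batch shifts are `N(0, sd)` on
#'   the log2 scale (what IRS removes); set 0 to disable.
#' @param frac_decoy,frac_contaminant Fractions (of `n_proteins`) of appended
#'   decoy/contaminant nuisance rows.
#' @param frac_missing Fraction of cells knocked out completely at random.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A `tmt_synth_design` list.
#' @export
synthetic_design <- function(n_proteins = 300,
                             n_plexes = 2,
                             reps_per_group = 2,
                             frac_sex_de = 0.10,
                             frac_trt_de_f = 0.10,
                             frac_trt_de_m = 0.10,
                             effect_size_log2 = 1.0,
                             effect_sd_log2 = 0.25,
                             sigma_within = 0.25,
                             sigma_pool = 0.05,
                             base_mean_log2 = 20,
                             base_sd_log2 = 1.5,
                             loading_sd_log2 = 0.25,
                             loading_factors = NULL,
                             batch_sd_log2 = 0.40,
                             frac_decoy = 0.03,
                             frac_contaminant = 0.03,
                             frac_missing = 0.01,
                             seed = 1L) {
  if (n_proteins < 1) design_error("n_proteins must be positive")
  if (n_plexes < 1) design_error("n_plexes must be >= 1")
  fr <- c(frac_sex_de, frac_trt_de_f, frac_trt_de_m, frac_decoy,
          frac_contaminant, frac_missing)
  if (any(fr < 0 | fr > 1)) design_error("fractions must lie in [0, 1]")
  if (sigma_within < 0 || sigma_pool < 0) design_error("noise sd must be >= 0")
  structure(as.list(environment()), class = "tmt_synth_design")
}

GROUPS <- c("MC", "FC", "MN", "FN")

synth_channel_design <- function(design) {
  purrr::map_dfr(seq_len(design$n_plexes), function(p) {
    grp <- rep(GROUPS, each = design$reps_per_group)
    n_exp <- length(grp)
    tibble::tibble(
      sample_id = c(
        sprintf("%s_p%d_r%d", grp, p, rep(seq_len(design$reps_per_group), times = 4)),
        sprintf("pool%d_p%d", 1:2, p)
      ),
      plex = sprintf("plex%d", p),
      channel = seq_len(n_exp + 2) - 1L,
      role = c(rep("experimental", n_exp), rep("pooled_reference", 2)),
      sex = c(substr(grp, 1, 1), "none", "none"),
      treatment = c(
        ifelse(substr(grp, 2, 2) == "N", "nicotine", "control"),
        "none", "none"
      )
    )
  })
}

#' Generate a synthetic TMT dataset with known ground truth
#'
#' @param design A [synthetic_design()].
#' @return A list with elements `data` (a raw-scale [tmt_matrix()] including
#'   nuisance rows and missing cells), `truth` (a tibble with per-protein
#'   true base abundance and signed log2 effects; effects are exactly 0 for
#'   proteins not drawn as differential), `loading` (the per-channel loading
#'   multipliers actually used) and `batch_log2` (the proteins x plexes batch
#'   shift matrix).
#' @export
generate_dataset <- function(design) {
  stopifnot(inherits(design, "tmt_synth_design"))
  withr::with_seed(design$seed, generate_dataset_impl(design))
}

generate_dataset_impl <- function(d) {
  chan <- synth_channel_design(d)
  n <- d$n_proteins
  ids <- sprintf("SYNP%04d", seq_len(n))
  genes <- sprintf("Gene%04d", seq_len(n))

  base <- stats::rnorm(n, d$base_mean_log2, d$base_sd_log2)
  draw_effect <- function(frac) {
    eff <- numeric(n)
    idx <- sample.int(n, round(frac * n))
    eff[idx] <- sample(c(-1, 1), length(idx), replace = TRUE) *
      abs(stats::rnorm(length(idx), d$effect_size_log2, d$effect_sd_log2))
    eff
  }
  sex_eff <- draw_effect(d$frac_sex_de)
  trt_f <- draw_effect(d$frac_trt_de_f)
  trt_m <- draw_effect(d$frac_trt_de_m)

  # group means relative to FC: MC = +sex, FN = +trt_f, MN = +sex +trt_m
  group_shift <- function(grp) {
    switch(grp,
      FC = rep(0, n),
      MC = sex_eff,
      FN = trt_f,
      MN = sex_eff + trt_m
    )
  }

  batch <- matrix(stats::rnorm(n * d$n_plexes, 0, d$batch_sd_log2), n, d$n_plexes)
  loading <- d$loading_factors %||%
    2^stats::rnorm(nrow(chan), 0, d$loading_sd_log2)
  if (length(loading) != nrow(chan)) {
    design_error("loading_factors must supply one factor per channel")
  }

  values <- matrix(NA_real_, n, nrow(chan))
  grp_all <- channel_groups(chan)
  for (p in seq_len(d$n_plexes)) {
    in_plex <- chan$plex == sprintf("plex%d", p)
    exp_idx <- which(in_plex & chan$role == "experimental")
    pool_idx <- which(in_plex & chan$role == "pooled_reference")
    pre <- matrix(NA_real_, n, length(exp_idx))
    for (k in seq_along(exp_idx)) {
      j <- exp_idx[k]
      signal <- base + group_shift(grp_all[j]) + batch[, p] +
        stats::rnorm(n, 0, d$sigma_within)
      pre[, k] <- 2^signal
      values[, j] <- loading[j] * pre[, k]
    }
    pool_pre <- rowMeans(pre)
    for (j in pool_idx) {
      values[, j] <- loading[j] * pool_pre * 2^stats::rnorm(n, 0, d$sigma_pool)
    }
  }

  # nuisance rows: decoys and contaminants with unstructured abundances
  n_dec <- round(d$frac_decoy * n)
  n_con <- round(d$frac_contaminant * n)
  extra <- n_dec + n_con
  if (extra > 0) {
    nuis <- 2^matrix(
      stats::rnorm(extra * nrow(chan), d$base_mean_log2, d$base_sd_log2),
      extra, nrow(chan)
    )
    values <- rbind(values, nuis)
  }
  records <- tibble::tibble(
    protein_id = c(ids, sprintf("REV__D%03d", seq_len(n_dec)),
                   sprintf("CON__C%03d", seq_len(n_con))),
    gene_name = c(genes, rep("", extra)),
    is_reverse = c(rep(FALSE, n), rep(TRUE, n_dec), rep(FALSE, n_con)),
    is_contaminant = c(rep(FALSE, n + n_dec), rep(TRUE, n_con)),
    only_identified_by_site = FALSE
  )

  if (d$frac_missing > 0) {
    cells <- length(values)
    knock <- sample.int(cells, round(d$frac_missing * cells))
    values[knock] <- NA_real_
  }

  truth <- tibble::tibble(
    protein_id = ids, gene_name = genes, base_log2 = base,
    sex_effect = sex_eff, trt_effect_f = trt_f, trt_effect_m = trt_m
  )
  list(
    data = tmt_matrix(values, records, chan, scale = "raw"),
    truth = truth,
    # injected nuisance parameters, exposed so recovery can be tested
    loading = stats::setNames(loading, chan$sample_id),
    batch_log2 = batch
  )
}

#' Write a synthetic dataset to disk
#'
#' Emits the protein-group TSV and design TSV consumed by
#' [read_protein_groups()], plus the ground truth as TSV.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_dataset <- function(dataset, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    protein_groups = file.path(dir, paste0(prefix, "_proteinGroups.txt")),
    design = file.path(dir, paste0(prefix, "_design.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.tsv"))
  )
  write_protein_groups(dataset$data, paths[["protein_groups"]])
  write_design(tmt_design(dataset$data), paths[["design"]])
  readr::write_tsv(dataset$truth, paths[["truth"]])
  invisible(paths)
}

truth_effect_col <- function(contrast) {
  switch(contrast,
    MC_vs_FC = , sex = "sex_effect",
    FN_vs_FC = , treatment_f = "trt_effect_f",
    MN_vs_MC = , treatment_m = "trt_effect_m",
    input_error(paste0("unknown contrast: ", contrast))
  )
}

#' Confusion counts of a differential call set against ground truth
#'
#' Proteins in the truth table absent from the result (e.g. removed by a
#' prefilter) count as not called, so a true effect lost upstream is a false
#' negative. Nuisance rows are not part of the truth table and must not appear
#' in the result.
#'
#' @param truth Ground-truth tibble from [generate_dataset()].
#' @param result A comparison result (see [permutation_fdr()]), or any tibble
#'   with `protein_id` and logical `significant`.
#' @param contrast Which truth column defines a real effect: one of
#'   `"MC_vs_FC"`/`"sex"`, `"FN_vs_FC"`/`"treatment_f"`,
#'   `"MN_vs_MC"`/`"treatment_m"`.
#' @return One-row tibble with `tp`, `fp`, `tn`, `fn`, empirical `fdr`
#'   (`fp / max(1, tp + fp)`) and `sensitivity` (`tp / max(1, tp + fn)`).
#' @export
truth_confusion <- function(truth, result, contrast = "MC_vs_FC") {
  col <- truth_effect_col(contrast)
  stray <- setdiff(result$protein_id, truth$protein_id)
  if (length(stray)) {
    input_error(paste0("result contains proteins absent from truth: ", stray[1]))
  }
  called <- result$protein_id[result$significant]
  is_de <- truth[[col]] != 0
  is_called <- truth$protein_id %in% called
  tp <- sum(is_de & is_called)
  fp <- sum(!is_de & is_called)
  fn <- sum(is_de & !is_called)
  tn <- sum(!is_de & !is_called)
  tibble::tibble(
    contrast = contrast, tp = tp, fp = fp, tn = tn, fn = fn,
    fdr = fp / max(1, tp + fp), sensitivity = tp / max(1, tp + fn)
  )
}

#' Synthetic annotation: gene sets and interaction edges
#'
#' Local stand-ins for pathway gene sets and a scored interaction network so
#' the enrichment and clustering stages can run on simulated data. Gene sets
#' are random blocks of the supplied universe; the edge table plants dense
#' cliques (recoverable complexes) on random subsets and sprinkles random
#' background edges with sub-threshold scores.
#'
#' @param genes Character vector of gene symbols (the universe).
#' @param n_sets,set_size Number and size of the random gene sets.
#' @param n_cliques,clique_size Planted dense complexes in the edge table.
#' @param n_background Random low-score background edges.
#' @param seed Integer seed.
#' @return `synthetic_gene_sets()`: a `tmt_gene_sets`; `synthetic_edge_table()`:
#'   an edge tibble as from [read_edge_table()].
#' @export
synthetic_gene_sets <- function(genes, n_sets = 20, set_size = 15, seed = 1L) {
  withr::with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) {
      sample(genes, min(set_size, length(genes)))
    })
    names(sets) <- sprintf("SET_%02d", seq_len(n_sets))
    gene_set_collection(sets, sprintf("synthetic pathway %d", seq_len(n_sets)))
  })
}

#' @rdname synthetic_gene_sets
#' @export
synthetic_edge_table <- function(genes, n_cliques = 3, clique_size = 6,
                                 n_background = 200, seed = 1L) {
  withr::with_seed(seed, {
    genes <- toupper(genes)
    edges <- list()
    for (i in seq_len(n_cliques)) {
      mem <- sample(genes, min(clique_size, length(genes)))
      pairs <- utils::combn(sort(mem), 2)
      edges[[i]] <- tibble::tibble(
        node_a = pairs[1, ], node_b = pairs[2, ],
        combined_score = stats::runif(ncol(pairs), 0.85, 0.999)
      )
    }
    bg_a <- sample(genes, n_background, replace = TRUE)
    bg_b <- sample(genes, n_background, replace = TRUE)
    keep <- bg_a != bg_b
    edges[[n_cliques + 1]] <- tibble::tibble(
      node_a = pmin(bg_a[keep], bg_b[keep]),
      node_b = pmax(bg_a[keep], bg_b[keep]),
      combined_score = stats::runif(sum(keep), 0.15, 0.9)
    )
    dplyr::bind_rows(edges) |>
      dplyr::group_by(.data$node_a, .data$node_b) |>
      dplyr::summarise(combined_score = max(.data$combined_score), .groups = "drop")
  })
}
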
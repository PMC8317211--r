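#' Configuration for the differential-testing engine
#'
#' Defaults follow the study settings: moderated tests at FDR < 0.05 with
#' `s0 = 0.5`, permutation-based FDR with 250 randomizations, and an ANOVA
#' prefilter at FDR < 0.05. The `s0` constant is added to the standard error
#' of the two-sample statistic so that small-variance proteins need a minimum
#' fold change to reach significance; `s0 = 0` recovers the classic pooled
#' *t* statistic.
#'
#' @param s0 Non-negative moderation constant on the log2 scale.
#' @param fdr Target false-discovery rate in (0, 1).
#' @param n_permutations Number of label randomizations (>= 1). When the
#'   number of distinct label assignments is no larger, all of them are
#'   enumerated instead (minus the identity).
#' @param anova_fdr BH level of the ANOVA prefilter.
#' @param anova_enabled Whether [run_pairwise_suite()] applies the prefilter.
#' @param welch Use Welch (unpooled) standard errors instead of the pooled
#'   form.
#' @param perm_aggregate Aggregate permutation false-positive counts by their
#'   `"mean"` (default) or `"median"`.
#' @param pi0 Assumed proportion of true nulls (fixed at 1: conservative).
#' @param seed Integer seed driving the permutation draw.
#' @return A `tmt_test_config` list.
#' @export
test_config <- function(s0 = 0.5, fdr = 0.05, n_permutations = 250,
                        anova_fdr = 0.05, anova_enabled = TRUE,
                        welch = FALSE, perm_aggregate = c("mean", "median"),
                        pi0 = 1, seed = 1L) {
  if (s0 < 0) config_error("s0 must be >= 0")
  if (fdr <= 0 || fdr >= 1) config_error("fdr must lie in (0, 1)")
  if (n_permutations < 1) config_error("n_permutations must be >= 1")
  perm_aggregate <- match.arg(perm_aggregate)
  structure(as.list(environment()), class = "tmt_test_config")
}

#' ANOVA prefilter across the four experimental groups
#'
#' Per protein, a one-way fixed-effects F test across the sex x treatment
#' groups; Benjamini-Hochberg adjustment across proteins; only proteins with
#' `q < anova_fdr` are retained for pairwise testing. Proteins constant
#' across all samples (zero between- and within-group variance) have an
#' undefined F and are dropped.
#'
#' @param x A log2-scale [tmt_matrix()] with >= 2 groups of >= 2 replicates.
#' @param config A [test_config()].
#' @return The filtered [tmt_matrix()] with the per-protein F/p/q table in the
#'   `anova_table` attribute.
#' @export
anova_prefilter <- function(x, config = test_config()) {
  d <- tmt_design(x)
  exp_cols <- which(d$role == "experimental")
  groups <- channel_groups(d)[exp_cols]
  if (length(unique(groups)) < 2) config_error("need >= 2 groups for ANOVA")
  if (any(table(groups) < 2)) config_error("need >= 2 replicates per group")
  v <- intensity_values(x)[, exp_cols, drop = FALSE]
  n_tot <- length(exp_cols)
  k <- length(unique(groups))
  if (n_tot - k <= 0) config_error("zero residual degrees of freedom")

  gm <- rowMeans(v)
  ssb <- 0
  ssw <- 0
  for (g in unique(groups)) {
    cols <- groups == g
    mg <- rowMeans(v[, cols, drop = FALSE])
    ssb <- ssb + sum(cols) * (mg - gm)^2
    ssw <- ssw + rowSums((v[, cols, drop = FALSE] - mg)^2)
  }
  const <- ssb + ssw <= 0 | rowSums(is.na(v)) > 0
  f <- (ssb / (k - 1)) / (ssw / (n_tot - k))
  p <- stats::pf(f, k - 1, n_tot - k, lower.tail = FALSE)
  p[const] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[!const] <- stats::p.adjust(p[!const], method = "BH")
  keep <- !const & q < config$anova_fdr

  tab <- tibble::tibble(
    protein_id = x$protein_id, f = f, p = p, q = q, retained = keep
  )
  out <- restore_tmt(as.data.frame(x)[keep, , drop = FALSE], x)
  attr(out, "norm_factors") <- attr(x, "norm_factors")
  attr(out, "anova_table") <- tab
  out
}

#' s0-moderated two-sample statistic
#'
#' `d = (mean_a - mean_b) / (se + s0)` with the pooled two-sample standard
#' error (or Welch's, when requested). At `s0 = 0` this is exactly the classic
#' two-sample *t* statistic.
#'
#' @param a,b Numeric vectors of log2 values (>= 2 each).
#' @param s0 Moderation constant on the same scale as the values.
#' @param welch Use unpooled standard errors.
#' @return List with `diff` (`mean(a) - mean(b)`), `se` and `d`.
#' @export
#' @examples
#' d_statistic(c(2, 2), c(1, 1), s0 = 0.5) # se = 0, d = 2
d_statistic <- function(a, b, s0 = 0.5, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    input_error("each group needs >= 2 values")
  }
  st <- d_stat_mat(rbind(c(a, b)), seq_along(a), length(a) + seq_along(b), s0, welch)
  list(diff = st$diff[1], se = st$se[1], d = st$d[1])
}

# vectorized over proteins: Y is proteins x samples
d_stat_mat <- function(Y, ia, ib, s0, welch = FALSE) {
  na <- length(ia)
  nb <- length(ib)
  ma <- rowMeans(Y[, ia, drop = FALSE])
  mb <- rowMeans(Y[, ib, drop = FALSE])
  va <- rowSums((Y[, ia, drop = FALSE] - ma)^2) / (na - 1)
  vb <- rowSums((Y[, ib, drop = FALSE] - mb)^2) / (nb - 1)
  se <- if (welch) {
    sqrt(va / na + vb / nb)
  } else {
    sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2) * (1 / na + 1 / nb))
  }
  diff <- ma - mb
  list(diff = diff, se = se, d = diff / (se + s0))
}

# distinct label assignments (positions of group A within the pooled samples),
# identity excluded; exhaustive when feasible, otherwise uniform without
# replacement
perm_assignments <- function(n, na, n_permutations) {
  total <- choose(n, na)
  identity_key <- paste(seq_len(na), collapse = ",")
  if (total - 1 < 2) input_error("fewer than 2 distinct permutations available")
  if (total <= n_permutations + 1) {
    all_ass <- utils::combn(n, na)
    keys <- apply(all_ass, 2, paste, collapse = ",")
    return(list(ass = all_ass[, keys != identity_key, drop = FALSE], exhaustive = TRUE))
  }
  seen <- character(0)
  out <- matrix(0L, na, 0)
  while (ncol(out) < n_permutations) {
    draw <- sort(sample.int(n, na))
    key <- paste(draw, collapse = ",")
    if (key == identity_key || key %in% seen) next
    seen <- c(seen, key)
    out <- cbind(out, draw)
  }
  list(ass = out, exhaustive = FALSE)
}

count_ge <- function(t, sorted) length(sorted) - findInterval(t, sorted, left.open = TRUE)

#' Two-group moderated test with permutation-based FDR
#'
#' The per-protein statistic is the s0-moderated `d` of [d_statistic()]
#' computed between the test and reference groups. Group labels are then
#' shuffled (group sizes preserved; all distinct assignments enumerated when
#' there are no more of them than `n_permutations`, the identity excluded) and
#' `|d|` recomputed for every protein under every shuffle. For a threshold
#' `t`, the estimated FDR is the average permutation count of `|d| >= t`
#' times `pi0`, divided by the observed count; each protein's q-value is the
#' smallest estimated FDR over thresholds that still admit it (observed
#' thresholds at or below its own `|d|`), so q-values are monotone
#' non-increasing in `|d|`. A protein is significant
#' when `q < fdr`; its direction is the sign of the log2 fold change
#' (test minus reference mean).
#'
#' @param x A log2-scale [tmt_matrix()].
#' @param test_group,ref_group Two of the group labels of
#'   [channel_groups()] (e.g. `"MN"`, `"MC"`).
#' @param config A [test_config()].
#' @return A `tmt_comparison` tibble: `protein_id`, `gene_name`, `log2_fc`,
#'   `d`, `q_value`, `significant`, `direction`, plus the comparison label and
#'   configuration as attributes.
#' @export
permutation_fdr <- function(x, test_group, ref_group, config = test_config()) {
  d <- tmt_design(x)
  groups <- channel_groups(d)
  ia_s <- which(groups == test_group)
  ib_s <- which(groups == ref_group)
  if (length(ia_s) < 2 || length(ib_s) < 2) {
    input_error("each group needs >= 2 channels")
  }
  Y <- intensity_values(x)[, c(ia_s, ib_s), drop = FALSE]
  if (anyNA(Y)) input_error("missing values must be filtered before testing")
  na <- length(ia_s)
  n <- ncol(Y)
  obs <- d_stat_mat(Y, seq_len(na), na + seq_len(n - na), config$s0, config$welch)
  absd <- abs(obs$d)

  perms <- withr::with_seed(
    config$seed,
    perm_assignments(n, na, config$n_permutations)
  )
  nperm <- ncol(perms$ass)
  perm_abs <- matrix(NA_real_, nrow(Y), nperm)
  for (j in seq_len(nperm)) {
    ia <- perms$ass[, j]
    ib <- setdiff(seq_len(n), ia)
    perm_abs[, j] <- abs(d_stat_mat(Y, ia, ib, config$s0, config$welch)$d)
  }

  sorted_obs <- sort(absd)
  num <- if (config$perm_aggregate == "mean") {
    all_perm <- sort(as.vector(perm_abs))
    vapply(absd, function(t) count_ge(t, all_perm), numeric(1)) / nperm
  } else {
    counts <- apply(perm_abs, 2, function(col) {
      sc <- sort(col)
      vapply(absd, function(t) count_ge(t, sc), numeric(1))
    })
    apply(counts, 1, stats::median)
  }
  denom <- vapply(absd, function(t) count_ge(t, sorted_obs), numeric(1))
  fdr_raw <- pmin(1, config$pi0 * num / pmax(denom, 1))
  # q at |d| = t is the smallest estimated FDR over thresholds at or below t
  # (any such threshold still admits the protein): suffix minimum in
  # descending-|d| order, which also enforces monotonicity in |d|
  ord <- order(absd, decreasing = TRUE)
  q <- numeric(length(absd))
  q[ord] <- rev(cummin(rev(fdr_raw[ord])))

  out <- tibble::tibble(
    protein_id = x$protein_id,
    gene_name = x$gene_name,
    log2_fc = obs$diff,
    d = obs$d,
    q_value = q,
    significant = q < config$fdr,
    direction = ifelse(obs$diff >= 0, "up", "down")
  )
  structure(out,
    class = c("tmt_comparison", class(out)),
    comparison = paste0(test_group, "_vs_", ref_group),
    test_group = test_group, ref_group = ref_group,
    config = config, n_permutations_used = nperm,
    exhaustive = perms$exhaustive
  )
}

#' The study's three pairwise comparisons
#'
#' Runs MC vs FC (reference FC), FN vs FC (reference FC) and MN vs MC
#' (reference MC) on a normalized log2 dataset, optionally after the ANOVA
#' prefilter. Each comparison gets its own deterministic permutation stream
#' derived from `config$seed`.
#'
#' @param x A log2-scale [tmt_matrix()] containing the four groups.
#' @param config A [test_config()].
#' @return A `tmt_suite`: a named list of `tmt_comparison` results
#'   (`MC_vs_FC`, `FN_vs_FC`, `MN_vs_MC`) with the ANOVA table (if run)
#'   attached. `glance()` gives the per-comparison up/down counts;
#'   `tidy()` stacks the per-protein tables.
#' @export
run_pairwise_suite <- function(x, config = test_config()) {
  groups <- channel_groups(tmt_design(x))
  missing <- setdiff(GROUPS, groups)
  if (length(missing)) {
    design_error(paste0("dataset lacks group(s): ", paste(missing, collapse = ", ")))
  }
  anova_tab <- NULL
  if (config$anova_enabled) {
    x <- anova_prefilter(x, config)
    anova_tab <- attr(x, "anova_table")
  }
  plan <- list(
    MC_vs_FC = c("MC", "FC"),
    FN_vs_FC = c("FN", "FC"),
    MN_vs_MC = c("MN", "MC")
  )
  results <- purrr::imap(plan, function(pair, nm) {
    cfg <- config
    cfg$seed <- config$seed + match(nm, names(plan))
    permutation_fdr(x, pair[1], pair[2], cfg)
  })
  structure(results,
    class = "tmt_suite", config = config, anova_table = anova_tab,
    n_universe = nrow(x)
  )
}

#' @export
glance.tmt_comparison <- function(x, ...) {
  tibble::tibble(
    comparison = attr(x, "comparison"),
    n_tested = nrow(x),
    n_significant = sum(x$significant),
    n_up = sum(x$significant & x$direction == "up"),
    n_down = sum(x$significant & x$direction == "down"),
    n_permutations = attr(x, "n_permutations_used"),
    exhaustive = attr(x, "exhaustive")
  )
}

#' @export
tidy.tmt_comparison <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(comparison = attr(x, "comparison"), .before = 1)
}

#' @export
glance.tmt_suite <- function(x, ...) {
  purrr::map_dfr(x, glance)
}

#' @export
tidy.tmt_suite <- function(x, ...) {
  purrr::map_dfr(x, tidy)
}

#' @export
print.tmt_suite <- function(x, ...) {
  cat("# pairwise differential-expression suite\n")
  print(glance(x))
  invisible(x)
}

#' Volcano plot of a comparison
#'
#' @param object A `tmt_comparison` from [permutation_fdr()].
#' @param ... Unused.
#' @return A ggplot of log2 fold change against `-log10(q)`, significant
#'   proteins coloured by direction.
#' @export
autoplot.tmt_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(
      neg_log10_q = -log10(pmax(.data$q_value, 1e-6)),
      call = dplyr::case_when(
        .data$significant & .data$direction == "up" ~ "up",
        .data$significant ~ "down",
        TRUE ~ "ns"
      )
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$log2_fc, .data$neg_log10_q, colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(up = "red3", down = "green4", ns = "grey60")) +
    ggplot2::labs(
      title = attr(object, "comparison"),
      x = "log2 fold change", y = "-log10(q)"
    )
}

#' Extract the significant, directional protein list of a comparison
#'
#' Identifier is the gene symbol (upper-cased), falling back to the accession
#' when the symbol is empty; this is the matching key used by the overlap and
#' enrichment stages.
#'
#' @param result A `tmt_comparison`.
#' @param direction Optionally restrict to `"up"` or `"down"`.
#' @return Tibble with `identifier` and `direction`.
#' @export
significant_proteins <- function(result, direction = NULL) {
  out <- tibble::as_tibble(result) |>
    dplyr::filter(.data$significant) |>
    dplyr::mutate(
      identifier = toupper(ifelse(nzchar(.data$gene_name), .data$gene_name, .data$protein_id))
    ) |>
    dplyr::select("identifier", "direction")
  if (!is.null(direction)) out <- out[out$direction == direction, ]
  out
}
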
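# rows usable for per-plex factor computation: present in all channels of the plex
plex_complete <- function(v, cols) {
  rowSums(is.na(v[, cols, drop = FALSE])) == 0
}

#' Sample-loading normalization
#'
#' First normalization stage: within each plex a single multiplicative factor
#' per channel scales every channel's total reporter intensity to the plex
#' average, correcting small pipetting and labeling differences. Totals are
#' computed over proteins present in all channels of the plex; the factor for
#' channel j is `mean(totals) / total_j`.
#'
#' @param x A raw-scale [tmt_matrix()].
#' @return The scaled [tmt_matrix()]; the per-channel factors are recorded
#'   under `norm_factors(x)$sl` (columns `sample_id`, `plex`, `factor`).
#' @export
sample_loading_normalize <- function(x) {
  d <- tmt_design(x)
  v <- intensity_values(x)
  factors <- numeric(nrow(d))
  for (p in unique(d$plex)) {
    cols <- which(d$plex == p)
    use <- plex_complete(v, cols)
    if (!any(use)) input_error(sprintf("plex %s has no complete proteins", p))
    totals <- colSums(v[use, cols, drop = FALSE])
    if (any(totals == 0)) {
      input_error(sprintf("plex %s has a channel with zero total intensity", p))
    }
    factors[cols] <- mean(totals) / totals
  }
  out <- set_intensity_values(x, sweep(v, 2, factors, `*`), scale = "normalized")
  add_norm_factors(out,
    sl = tibble::tibble(sample_id = d$sample_id, plex = d$plex, factor = factors)
  )
}

#' Trimmed-mean-of-M-values (TMM) scaling factors
#'
#' Second normalization stage, the method originally developed for RNA-seq
#' library composition, computed within each plex. The reference channel is
#' the one whose upper quartile is closest to the plex mean upper quartile.
#' For every other channel, per-protein log ratios `M = log2(x_j / x_ref)` and
#' average intensities `A = 0.5 * log2(x_j * x_ref)` are double-trimmed (by
#' default the top and bottom 30% of M and 5% of A) and the factor is 2 to the
#' precision-weighted mean of the surviving M values. Factors are then
#' rescaled to multiply to 1 within the plex (geometric-mean anchoring).
#'
#' @param x A [tmt_matrix()] with positive values for the proteins used.
#' @param trim_m,trim_a Two-sided trim fractions for M and A (defaults 0.30
#'   and 0.05).
#' @param min_kept Minimum number of proteins that must survive trimming.
#' @return Tibble with `sample_id`, `plex`, `raw_factor` (before anchoring)
#'   and `factor` (anchored; product 1 per plex).
#' @export
tmm_factors <- function(x, trim_m = 0.30, trim_a = 0.05, min_kept = 10) {
  d <- tmt_design(x)
  v <- intensity_values(x)
  out <- vector("list", length(unique(d$plex)))
  for (pi in seq_along(unique(d$plex))) {
    p <- unique(d$plex)[pi]
    cols <- which(d$plex == p)
    use <- plex_complete(v, cols) & rowSums(v[, cols, drop = FALSE] <= 0, na.rm = TRUE) == 0
    m <- v[use, cols, drop = FALSE]
    if (length(cols) == 1) {
      out[[pi]] <- tibble::tibble(
        sample_id = d$sample_id[cols], plex = p, raw_factor = 1, factor = 1
      )
      next
    }
    if (!any(use)) input_error(sprintf("plex %s has no usable proteins for TMM", p))
    uq <- apply(m, 2, stats::quantile, probs = 0.75)
    ref <- which.min(abs(uq - mean(uq)))
    totals <- colSums(m)
    raw <- vapply(seq_along(cols), function(j) {
      if (j == ref) return(1)
      tmm_one(m[, j], m[, ref], totals[j], totals[ref], trim_m, trim_a, min_kept)
    }, numeric(1))
    out[[pi]] <- tibble::tibble(
      sample_id = d$sample_id[cols], plex = p, raw_factor = raw,
      factor = raw / geo_mean(raw)
    )
  }
  dplyr::bind_rows(out)
}

tmm_one <- function(x, r, nx, nr, trim_m, trim_a, min_kept) {
  M <- log2(x / r)
  A <- 0.5 * log2(x * r)
  n <- length(M)
  loM <- floor(n * trim_m) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1
  hiA <- n + 1 - loA
  rM <- rank(M)
  rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (sum(keep) < min_kept) {
    input_error("too few proteins survive TMM trimming")
  }
  # precision weights: inverse asymptotic variance of M (delta method)
  w <- (nx - x[keep]) / (nx * x[keep]) + (nr - r[keep]) / (nr * r[keep])
  w[w <= 0] <- min(w[w > 0], 1e-8)
  2^(sum(M[keep] / w) / sum(1 / w))
}

#' @rdname tmm_factors
#' @description `tmm_normalize()` computes the factors and divides every
#'   channel by its anchored factor.
#' @export
tmm_normalize <- function(x, trim_m = 0.30, trim_a = 0.05, min_kept = 10) {
  f <- tmm_factors(x, trim_m, trim_a, min_kept)
  f <- f[match(tmt_design(x)$sample_id, f$sample_id), ]
  out <- set_intensity_values(
    x, sweep(intensity_values(x), 2, f$factor, `/`),
    scale = "normalized"
  )
  add_norm_factors(out, tmm = f)
}

#' Internal reference scaling (IRS) across plexes
#'
#' Third normalization stage for designs with pooled reference channels. Per
#' protein, the plex reference is the geometric mean of that plex's pooled
#' channels; the target is the geometric mean of the plex references; every
#' channel of a plex is multiplied by `target / reference`, after which the
#' pooled-channel reference of each protein is identical across plexes. The
#' operation is idempotent. Proteins with a missing or zero pooled value in
#' any plex cannot be scaled and are dropped; the count is recorded under
#' `norm_factors(x)$irs$n_dropped`.
#'
#' @param x A [tmt_matrix()] (raw or normalized scale) whose design has at
#'   least one `pooled_reference` channel per plex.
#' @return The rescaled [tmt_matrix()] with per-protein, per-plex factors in
#'   `norm_factors(x)$irs`.
#' @export
irs_normalize <- function(x) {
  d <- tmt_design(x)
  plexes <- unique(d$plex)
  if (length(plexes) == 1) {
    return(add_norm_factors(x, irs = list(
      factors = matrix(1, nrow(x), 1, dimnames = list(x$protein_id, plexes)),
      n_dropped = 0L
    )))
  }
  v <- intensity_values(x)
  refs <- vapply(plexes, function(p) {
    pools <- which(d$plex == p & d$role == "pooled_reference")
    if (!length(pools)) design_error(sprintf("plex %s has no pooled_reference channel", p))
    exp(rowMeans(log(v[, pools, drop = FALSE])))
  }, numeric(nrow(v)))
  refs <- matrix(refs,
    nrow = nrow(v),
    dimnames = list(x$protein_id, plexes)
  )
  ok <- rowSums(!is.finite(refs) | refs <= 0) == 0
  n_dropped <- sum(!ok)
  v <- v[ok, , drop = FALSE]
  refs <- refs[ok, , drop = FALSE]
  target <- exp(rowMeans(log(refs)))
  factors <- target / refs
  for (pi in seq_along(plexes)) {
    cols <- which(d$plex == plexes[pi])
    v[, cols] <- v[, cols, drop = FALSE] * factors[, pi]
  }
  rec <- protein_records(x)[ok, ]
  out <- tmt_matrix(v, rec, d, scale = "normalized")
  attr(out, "norm_factors") <- attr(x, "norm_factors")
  add_norm_factors(out, irs = list(factors = factors, n_dropped = n_dropped))
}

#' Linear-model batch correction on the log2 scale
#'
#' Alternative third stage: per protein, an additive two-way model
#' `value = group mean + plex offset` (sum-to-zero plex coding) is fit by
#' least squares and the fitted plex offsets are subtracted. Group-mean
#' differences are unchanged by construction; a pure additive plex shift is
#' removed exactly. Pooled channels participate as their own group.
#'
#' @param x A log2-scale [tmt_matrix()] in which every group is observed in
#'   more than one plex (otherwise batch is confounded with group).
#' @return The corrected [tmt_matrix()]; the per-plex offsets actually valid
#'   for complete rows are recorded under `norm_factors(x)$batch`.
#' @export
linear_batch_correct <- function(x) {
  if (tmt_scale(x) != "log2") input_error("linear_batch_correct expects log2 scale")
  d <- tmt_design(x)
  plexes <- unique(d$plex)
  if (length(plexes) == 1) {
    return(add_norm_factors(x, batch = tibble::tibble(plex = plexes, offset = 0)))
  }
  group <- factor(channel_groups(d))
  plex <- factor(d$plex)
  tab <- table(group, plex)
  if (any(rowSums(tab > 0) < 2)) {
    tmt_abort("batch is confounded with group: some group is observed in a single plex",
      "tmtde_confounding_error")
  }
  X <- stats::model.matrix(
    ~ 0 + group + plex,
    contrasts.arg = list(plex = stats::contr.sum)
  )
  batch_cols <- grep("^plex", colnames(X))
  v <- intensity_values(x)
  complete <- rowSums(is.na(v)) == 0
  corrected <- v
  if (any(complete)) {
    fit <- stats::lm.fit(X, t(v[complete, , drop = FALSE]))
    offs <- X[, batch_cols, drop = FALSE] %*% fit$coefficients[batch_cols, , drop = FALSE]
    corrected[complete, ] <- v[complete, , drop = FALSE] - t(offs)
  }
  for (i in which(!complete)) {
    obs <- !is.na(v[i, ])
    if (sum(obs) <= ncol(X)) next # not estimable, leave as is
    fi <- stats::lm.fit(X[obs, , drop = FALSE], v[i, obs])
    co <- fi$coefficients[batch_cols]
    co[is.na(co)] <- 0
    corrected[i, obs] <- v[i, obs] - drop(X[obs, batch_cols, drop = FALSE] %*% co)
  }
  out <- set_intensity_values(x, corrected, scale = "log2")
  add_norm_factors(out, batch = list(design_columns = colnames(X)[batch_cols]))
}

#' Full three-stage normalization
#'
#' Applies, in order: sample-loading scaling within plex, TMM within plex,
#' then either internal reference scaling across plexes on the intensity scale
#' followed by log2, or log2 followed by linear-model batch correction. The
#' IRS branch is appropriate when pooled reference channels are reliable; the
#' linear-model branch when the data are too variable for them.
#'
#' @param x A raw-scale [tmt_matrix()].
#' @param batch_method `"irs"` or `"linear_model"`.
#' @param trim_m,trim_a TMM trim fractions, passed to [tmm_normalize()].
#' @return A log2-scale [tmt_matrix()]; all stage factors are available via
#'   [norm_factors()] (elements `sl`, `tmm`, and `irs` or `batch`, plus
#'   `method_batch`).
#' @export
normalize_pipeline <- function(x, batch_method = c("irs", "linear_model"),
                               trim_m = 0.30, trim_a = 0.05) {
  batch_method <- match.arg(batch_method)
  x <- sample_loading_normalize(x)
  x <- tmm_normalize(x, trim_m, trim_a)
  x <- if (batch_method == "irs") {
    log2_transform(irs_normalize(x))
  } else {
    linear_batch_correct(log2_transform(x))
  }
  add_norm_factors(x, method_batch = batch_method)
}
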
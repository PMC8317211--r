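#' Quality-control report for a normalized dataset
#'
#' Summarizes a log2-scale dataset the way multi-plex TMT studies are usually
#' sanity-checked: per-channel intensity quartiles (box-plot summaries),
#' per-group coefficients of variation, all pairwise Pearson correlations of
#' log2 values, and a PCA of the sample profiles. CVs are computed per protein
#' on the intensity scale (`100 * sd / mean` of `2^x`, sample standard
#' deviation) and averaged within each group; well-normalized replicates sit
#' in the low single digits of percent. PCA uses protein-wise centering only
#' (no unit-variance scaling), via singular value decomposition, on proteins
#' without missing values.
#'
#' @param x A log2-scale [tmt_matrix()] with at least 2 channels.
#' @return A `tmt_qc` list with elements `channel_summary`, `cv` (per-group
#'   mean CV %), `cv_per_protein`, `correlation` (matrix), `pca` (scores
#'   tibble) and `var_explained`.
#' @export
qc_report <- function(x) {
  if (tmt_scale(x) != "log2") input_error("qc_report expects a log2-scale matrix")
  d <- tmt_design(x)
  if (nrow(d) < 2) input_error("qc_report needs at least 2 channels")
  v <- intensity_values(x)
  groups <- channel_groups(d)

  channel_summary <- tibble::tibble(
    sample_id = d$sample_id, plex = d$plex, group = groups,
    q25 = apply(v, 2, stats::quantile, 0.25, na.rm = TRUE),
    median = apply(v, 2, stats::median, na.rm = TRUE),
    q75 = apply(v, 2, stats::quantile, 0.75, na.rm = TRUE)
  )

  lin <- 2^v
  cv_rows <- list()
  for (g in unique(groups)) {
    cols <- which(groups == g)
    if (length(cols) < 2) {
      warning(sprintf("group %s has a single replicate; CV skipped", g), call. = FALSE)
      next
    }
    m <- lin[, cols, drop = FALSE]
    cv <- 100 * apply(m, 1, stats::sd) / rowMeans(m)
    cv_rows[[g]] <- tibble::tibble(group = g, protein_id = x$protein_id, cv = cv)
  }
  cv_per_protein <- dplyr::bind_rows(cv_rows)
  cv <- cv_per_protein |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_cv = mean(.data$cv, na.rm = TRUE), .groups = "drop")

  correlation <- stats::cor(v, use = "pairwise.complete.obs", method = "pearson")

  complete <- rowSums(is.na(v)) == 0
  pc <- stats::prcomp(t(v[complete, , drop = FALSE]), center = TRUE, scale. = FALSE)
  var_explained <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(4, ncol(pc$x))
  pca <- dplyr::bind_cols(
    tibble::tibble(sample_id = d$sample_id, plex = d$plex, group = groups),
    tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE])
  )

  structure(
    list(
      channel_summary = channel_summary, cv = cv,
      cv_per_protein = cv_per_protein, correlation = correlation,
      pca = pca, var_explained = var_explained
    ),
    class = "tmt_qc"
  )
}

#' @export
print.tmt_qc <- function(x, ...) {
  cat("# QC report\n")
  cat(sprintf(
    "  mean CV by group: %s\n",
    paste(sprintf("%s %.1f%%", x$cv$group, x$cv$mean_cv), collapse = ", ")
  ))
  off <- x$correlation[lower.tri(x$correlation)]
  cat(sprintf("  pairwise Pearson: %.3f-%.3f\n", min(off), max(off)))
  cat(sprintf(
    "  PCA variance explained: %s\n",
    paste(sprintf("%.1f%%", 100 * utils::head(x$var_explained, 3)), collapse = ", ")
  ))
  invisible(x)
}

#' @export
glance.tmt_qc <- function(x, ...) {
  off <- x$correlation[lower.tri(x$correlation)]
  tibble::tibble(
    n_channels = nrow(x$channel_summary),
    mean_cv = mean(x$cv$mean_cv),
    min_pearson = min(off),
    pc1_var = x$var_explained[1],
    pc2_var = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_
  )
}

#' Plot a QC report
#'
#' @param object A `tmt_qc` from [qc_report()].
#' @param type `"pca"` (sample scores on the first two components), `"cv"`
#'   (group mean CV bars), `"box"` (channel quartile summaries) or `"cor"`
#'   (correlation heat map).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tmt_qc <- function(object, type = c("pca", "cv", "box", "cor"), ...) {
  type <- match.arg(type)
  switch(type,
    pca = {
      ve <- 100 * object$var_explained
      ggplot2::ggplot(object$pca, ggplot2::aes(
        .data$PC1, .data$PC2, colour = .data$group, shape = .data$plex
      )) +
        ggplot2::geom_point(size = 3) +
        ggplot2::labs(
          x = sprintf("PC1 (%.1f%%)", ve[1]),
          y = sprintf("PC2 (%.1f%%)", ve[2])
        )
    },
    cv = ggplot2::ggplot(object$cv, ggplot2::aes(.data$group, .data$mean_cv)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = NULL, y = "mean CV (%)"),
    box = {
      long <- tidyr::pivot_longer(
        object$channel_summary, c("q25", "median", "q75"),
        names_to = "stat", values_to = "value"
      )
      ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$value,
        colour = .data$stat
      )) +
        ggplot2::geom_point() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5)) +
        ggplot2::labs(x = NULL, y = "log2 intensity")
    },
    cor = {
      cm <- tibble::as_tibble(object$correlation, rownames = "sample_a") |>
        tidyr::pivot_longer(-"sample_a", names_to = "sample_b", values_to = "r")
      ggplot2::ggplot(cm, ggplot2::aes(.data$sample_a, .data$sample_b, fill = .data$r)) +
        ggplot2::geom_tile() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5)) +
        ggplot2::labs(x = NULL, y = NULL)
    }
  )
}
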
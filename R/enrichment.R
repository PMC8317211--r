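#' Gene-set over-representation analysis
#'
#' One-sided hypergeometric test of a query gene list against each set of a
#' collection, within a stated background universe: the p-value is the
#' upper-tail probability `P[X >= k]` of drawing at least the observed overlap
#' when `n_query` genes are sampled without replacement from the universe.
#' Sets are intersected with the universe first and sets with an empty
#' intersection are skipped (they are untestable and do not enter the BH
#' denominator). Benjamini-Hochberg q-values are computed across the tested
#' sets; rows are sorted by q, then p, then set name. The natural universe is
#' the full list of quantified proteins after filtering.
#'
#' @param query Character vector of gene symbols (case-insensitive); must be a
#'   subset of `universe`.
#' @param universe Character vector of background gene symbols.
#' @param collection A `tmt_gene_sets` (see [read_gmt()]) or named list of
#'   symbol vectors.
#' @return A `tmt_enrichment` tibble: `set_name`, `n_query_in_set`, `n_query`,
#'   `n_set_in_universe`, `n_universe`, `p_value`, `q_value`, `overlap`
#'   (list-column of shared symbols).
#' @export
enrich <- function(query, universe, collection) {
  query <- unique(toupper(query))
  universe <- unique(toupper(universe))
  if (!length(query)) input_error("query is empty")
  if (!length(universe)) input_error("universe is empty")
  if (!length(collection)) input_error("gene-set collection is empty")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    input_error(paste0("query gene not in universe: ", outside[1]))
  }
  sets <- lapply(collection, function(s) intersect(toupper(s), universe))
  keep <- lengths(sets) > 0
  sets <- sets[keep]
  if (!length(sets)) input_error("no gene set overlaps the universe")

  N <- length(universe)
  n <- length(query)
  rows <- purrr::imap_dfr(sets, function(members, nm) {
    K <- length(members)
    hits <- intersect(query, members)
    k <- length(hits)
    tibble::tibble(
      set_name = nm,
      n_query_in_set = k, n_query = n,
      n_set_in_universe = K, n_universe = N,
      p_value = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      overlap = list(hits)
    )
  })
  rows$q_value <- stats::p.adjust(rows$p_value, method = "BH")
  rows <- rows[order(rows$q_value, rows$p_value, rows$set_name), ]
  rows <- dplyr::relocate(rows, "q_value", .after = "p_value")
  structure(rows, class = c("tmt_enrichment", class(rows)))
}

#' Top-k significantly enriched sets
#'
#' Reporting convention for enrichment figures: at most `k` sets passing the
#' q cutoff, fewer (possibly zero) when fewer are significant — an empty
#' report is a valid result, not an error.
#'
#' @param rows A `tmt_enrichment` from [enrich()] (already sorted).
#' @param k Maximum number of rows (default 5).
#' @param q_cutoff Significance cutoff on the BH q-value.
#' @return The head of the significant rows, same class.
#' @export
top_k_report <- function(rows, k = 5, q_cutoff = 0.05) {
  out <- rows[rows$q_value < q_cutoff, , drop = FALSE]
  utils::head(out, k)
}

#' @export
tidy.tmt_enrichment <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(overlap = purrr::map_chr(.data$overlap, paste, collapse = ";"))
}

#' Bar plot of enrichment results
#'
#' @param object A `tmt_enrichment`.
#' @param k Number of top sets to show.
#' @param ... Unused.
#' @return A ggplot of `-log10(q)` per set.
#' @export
autoplot.tmt_enrichment <- function(object, k = 10, ...) {
  df <- utils::head(tibble::as_tibble(object), k)
  df$set_name <- factor(df$set_name, levels = rev(df$set_name))
  ggplot2::ggplot(df, ggplot2::aes(-log10(.data$q_value), .data$set_name)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "-log10(q)", y = NULL)
}
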
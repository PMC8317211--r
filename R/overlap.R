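#' Overlap between two directional differential lists
#'
#' Intersects two significant-protein lists by identifier (case-normalized)
#' and splits the shared proteins into same- and opposite-direction sets, with
#' the percentages used to report cross-comparison convergence: the common
#' count as a share of each list, and the same-direction count as a share of
#' the common set. Exact percentages are stored; report them rounded to one
#' decimal half-away-from-zero via [round_half_up()] or [tidy()].
#'
#' @param list_a,list_b Tibbles with columns `identifier` and `direction`
#'   (`"up"`/`"down"`), e.g. from [significant_proteins()]. Identifiers must
#'   be unique within each list.
#' @param label_a,label_b Optional display labels.
#' @return A one-row `tmt_overlap` tibble: `n_a`, `n_b`, `n_common`,
#'   `n_same_direction`, `n_opposite_direction`, `pct_of_a`, `pct_of_b`,
#'   `pct_same_of_common`, plus list-columns of the member partitions.
#' @export
overlap_summary <- function(list_a, list_b, label_a = "A", label_b = "B") {
  list_a <- normalize_dir_list(list_a, "list_a")
  list_b <- normalize_dir_list(list_b, "list_b")
  common <- intersect(list_a$identifier, list_b$identifier)
  dir_a <- list_a$direction[match(common, list_a$identifier)]
  dir_b <- list_b$direction[match(common, list_b$identifier)]
  same <- common[dir_a == dir_b]
  opposite <- common[dir_a != dir_b]
  n_a <- nrow(list_a)
  n_b <- nrow(list_b)
  n_common <- length(common)
  out <- tibble::tibble(
    label_a = label_a, label_b = label_b,
    n_a = n_a, n_b = n_b, n_common = n_common,
    n_same_direction = length(same),
    n_opposite_direction = length(opposite),
    pct_of_a = if (n_a > 0) 100 * n_common / n_a else NA_real_,
    pct_of_b = if (n_b > 0) 100 * n_common / n_b else NA_real_,
    pct_same_of_common = if (n_common > 0) 100 * length(same) / n_common else NA_real_,
    members_common = list(common),
    members_same = list(same),
    members_opposite = list(opposite),
    members_only_a = list(setdiff(list_a$identifier, common)),
    members_only_b = list(setdiff(list_b$identifier, common))
  )
  structure(out, class = c("tmt_overlap", class(out)))
}

normalize_dir_list <- function(x, what) {
  x <- tibble::as_tibble(x)
  if (!all(c("identifier", "direction") %in% names(x))) {
    input_error(paste0(what, " needs columns identifier and direction"))
  }
  x$identifier <- toupper(x$identifier)
  if (anyDuplicated(x$identifier)) {
    input_error(paste0("duplicate identifier in ", what))
  }
  x
}

#' @export
tidy.tmt_overlap <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select(!dplyr::starts_with("members_")) |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("pct_"), ~ round_half_up(.x, 1)))
}

#' Overlap summaries for a plan of comparison pairs
#'
#' @param results Named list of `tmt_comparison` objects (e.g. the elements
#'   of one or more [run_pairwise_suite()] results).
#' @param plan Tibble with columns `a`, `b` (names into `results`) and
#'   optionally `label`.
#' @return A `tmt_overlap` tibble with one row per planned pair.
#' @export
overlap_matrix <- function(results, plan) {
  plan <- tibble::as_tibble(plan)
  missing <- setdiff(unique(c(plan$a, plan$b)), names(results))
  if (length(missing)) {
    input_error(paste0("pairing references missing comparison: ", missing[1]))
  }
  rows <- purrr::pmap(plan, function(a, b, ...) {
    dots <- list(...)
    s <- overlap_summary(
      significant_proteins(results[[a]]),
      significant_proteins(results[[b]]),
      label_a = a, label_b = b
    )
    if (!is.null(dots$label)) s <- dplyr::mutate(s, label = dots$label, .before = 1)
    s
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("tmt_overlap", class(tibble::tibble())))
}

#' Serialize overlap summaries to a flat TSV-ready tibble
#'
#' @param x A `tmt_overlap`.
#' @return Tibble with member lists collapsed to `;`-separated strings and
#'   percentages rounded for reporting.
#' @export
overlap_report <- function(x) {
  tibble::as_tibble(x) |>
    dplyr::mutate(
      dplyr::across(dplyr::starts_with("members_"), ~ purrr::map_chr(.x, paste, collapse = ";")),
      dplyr::across(dplyr::starts_with("pct_"), ~ round_half_up(.x, 1))
    )
}
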
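#' @importFrom rlang .data
NULL

META_COLS <- c(
  "protein_id", "gene_name",
  "is_reverse", "is_contaminant", "only_identified_by_site"
)

#' TMT intensity table
#'
#' The central container of the package: a tibble with one row per protein
#' group, the five metadata columns `protein_id`, `gene_name`, `is_reverse`,
#' `is_contaminant`, `only_identified_by_site`, and one numeric column per
#' channel (named by `sample_id`). The channel design (plex, channel index,
#' role, sex, treatment) travels along as an attribute, as does the scale of
#' the values (`"raw"`, `"normalized"` or `"log2"`). Missing measurements are
#' `NA`; zero reporter intensities are converted to `NA` on read so that a
#' later log2 transform never produces `-Inf`.
#'
#' @param values Numeric matrix, proteins x channels. Column order must match
#'   `design$sample_id`.
#' @param records Tibble of protein metadata with columns `protein_id`
#'   (non-empty, unique) and optionally `gene_name` and the three logical
#'   flags; absent columns are filled with defaults.
#' @param design Channel design tibble with columns `sample_id`, `plex`,
#'   `channel`, `role` (`"experimental"` or `"pooled_reference"`), `sex`
#'   (`"M"`, `"F"` or `"none"`) and `treatment` (`"control"`, `"nicotine"` or
#'   `"none"`).
#' @param scale One of `"raw"`, `"normalized"`, `"log2"`.
#' @return A `tmt_matrix` tibble.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   sample_id = c("a", "b"), plex = "p1", channel = 0:1,
#'   role = "experimental", sex = c("M", "F"), treatment = "control"
#' )
#' tmt_matrix(matrix(1:4, 2, 2), tibble::tibble(protein_id = c("P1", "P2")), d)
tmt_matrix <- function(values, records, design, scale = "raw") {
  values <- as.matrix(values)
  records <- tibble::as_tibble(records)
  design <- check_design(design)
  if (!"gene_name" %in% names(records)) records$gene_name <- ""
  for (fl in c("is_reverse", "is_contaminant", "only_identified_by_site")) {
    if (!fl %in% names(records)) records[[fl]] <- FALSE
  }
  records <- records[, META_COLS]
  if (nrow(values) != nrow(records)) {
    design_error("values and records disagree on the number of proteins")
  }
  if (ncol(values) != nrow(design)) {
    design_error(sprintf(
      "values have %d channels but the design lists %d",
      ncol(values), nrow(design)
    ))
  }
  if (anyDuplicated(records$protein_id) || any(!nzchar(records$protein_id))) {
    format_error("protein_id must be non-empty and unique")
  }
  scale <- match.arg(scale, c("raw", "normalized", "log2"))
  if (scale != "log2" && any(values < 0, na.rm = TRUE)) {
    format_error("negative intensities are not allowed on the raw/normalized scale")
  }
  vals <- tibble::as_tibble(as.data.frame(values), .name_repair = "minimal")
  names(vals) <- design$sample_id
  out <- dplyr::bind_cols(records, vals)
  new_tmt_matrix(out, design = design, scale = scale)
}

new_tmt_matrix <- function(tbl, design, scale) {
  structure(
    tibble::as_tibble(tbl),
    design = design, scale = scale,
    class = c("tmt_matrix", "tbl_df", "tbl", "data.frame")
  )
}

check_design <- function(design) {
  design <- tibble::as_tibble(design)
  need <- c("sample_id", "plex", "channel", "role", "sex", "treatment")
  missing <- setdiff(need, names(design))
  if (length(missing)) {
    design_error(paste0("design is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(design$sample_id)) design_error("duplicate sample_id in design")
  bad_role <- setdiff(unique(design$role), c("experimental", "pooled_reference"))
  if (length(bad_role)) design_error(paste0("unknown channel role: ", bad_role[1]))
  pooled <- design$role == "pooled_reference"
  if (any(design$sex[pooled] != "none" | design$treatment[pooled] != "none")) {
    design_error("pooled_reference channels must have sex = 'none', treatment = 'none'")
  }
  if (any(design$sex[!pooled] == "none" | design$treatment[!pooled] == "none")) {
    design_error("experimental channels must carry both sex and treatment")
  }
  design
}

# rebuild a tmt_matrix after a bare-tibble manipulation
restore_tmt <- function(tbl, template, design = NULL, scale = NULL) {
  new_tmt_matrix(
    tbl,
    design = design %||% attr(template, "design"),
    scale = scale %||% attr(template, "scale")
  )
}

#' Accessors for `tmt_matrix` components
#'
#' @param x A [tmt_matrix()].
#' @return `tmt_design()` the channel design tibble; `tmt_scale()` the scale
#'   string; `intensity_values()` the proteins x channels numeric matrix with
#'   `protein_id` rownames; `protein_records()` the metadata tibble;
#'   `norm_factors()` the list of normalization factors recorded by the
#'   normalization stages (or `NULL`).
#' @export
tmt_design <- function(x) attr(x, "design")

#' @rdname tmt_design
#' @export
tmt_scale <- function(x) attr(x, "scale")

#' @rdname tmt_design
#' @export
intensity_values <- function(x) {
  m <- as.matrix(as.data.frame(x)[, tmt_design(x)$sample_id, drop = FALSE])
  rownames(m) <- x$protein_id
  m
}

#' @rdname tmt_design
#' @export
protein_records <- function(x) {
  tibble::as_tibble(as.data.frame(x)[, META_COLS])
}

#' @rdname tmt_design
#' @export
norm_factors <- function(x) attr(x, "norm_factors")

set_intensity_values <- function(x, values, scale = NULL) {
  stopifnot(nrow(values) == nrow(x))
  out <- tmt_matrix(values, protein_records(x), tmt_design(x),
    scale = scale %||% tmt_scale(x)
  )
  attr(out, "norm_factors") <- attr(x, "norm_factors")
  out
}

add_norm_factors <- function(x, ...) {
  nf <- c(attr(x, "norm_factors") %||% list(), list(...))
  attr(x, "norm_factors") <- nf
  x
}

#' Experimental-group label per channel
#'
#' Maps the channel design to the four sex-by-treatment groups used in the
#' study design: `MC`, `FC`, `MN`, `FN` (male/female x control/nicotine);
#' pooled reference channels are labelled `pool`.
#'
#' @param design A channel design tibble (see [tmt_matrix()]).
#' @return Character vector of group labels, one per design row.
#' @export
channel_groups <- function(design) {
  ifelse(
    design$role == "pooled_reference", "pool",
    paste0(design$sex, ifelse(design$treatment == "nicotine", "N", "C"))
  )
}

#' @export
print.tmt_matrix <- function(x, ...) {
  d <- tmt_design(x)
  cat(sprintf(
    "# tmt_matrix: %d proteins x %d channels (%d plex%s), scale = %s\n",
    nrow(x), nrow(d), length(unique(d$plex)),
    if (length(unique(d$plex)) > 1) "es" else "", tmt_scale(x)
  ))
  NextMethod()
}

#' Log2-transform a raw or normalized intensity table
#'
#' @param x A [tmt_matrix()] on the raw or normalized scale with strictly
#'   positive present values.
#' @return The same table on the log2 scale.
#' @export
log2_transform <- function(x) {
  if (tmt_scale(x) == "log2") return(x)
  v <- intensity_values(x)
  if (any(v <= 0, na.rm = TRUE)) {
    input_error("cannot log2-transform non-positive intensities")
  }
  set_intensity_values(x, log2(v), scale = "log2")
}
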
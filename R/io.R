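PG_META <- c(
  `Protein IDs` = "protein_id",
  `Gene names` = "gene_name",
  `Reverse` = "is_reverse",
  `Potential contaminant` = "is_contaminant",
  `Only identified by site` = "only_identified_by_site"
)

reporter_col <- function(design) {
  paste("Reporter intensity corrected", design$channel, design$plex)
}

#' Read a channel design table
#'
#' @param path TSV with columns `sample_id`, `plex`, `channel`, `role`,
#'   `sex`, `treatment`.
#' @return The validated design tibble.
#' @export
read_design <- function(path) {
  check_design(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname read_design
#' @param design Design tibble to write.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(check_design(design), path)
  invisible(path)
}

#' Read a MaxQuant-style protein-groups table
#'
#' Parses a tab-separated protein-groups export: one row per protein group,
#' per-channel `Reporter intensity corrected <channel> <plex>` columns, and the
#' `Reverse` / `Potential contaminant` / `Only identified by site` flag columns
#' (`"+"` means flagged). Reporter cells equal to 0 or blank are stored as
#' missing (`NA`): zero reporter intensity means "not measured", and treating
#' it as numeric zero would poison the later log2 transform. The gene name
#' kept is the first of the semicolon-separated `Gene names` entry; the rule is
#' recorded in the `gene_name_rule` attribute of the result.
#'
#' @param path Protein-groups TSV.
#' @param design Design tibble or path to a design TSV (see [read_design()]).
#' @return A raw-scale [tmt_matrix()].
#' @export
read_protein_groups <- function(path, design) {
  if (is.character(design)) design <- read_design(design)
  design <- check_design(design)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)

  missing_meta <- setdiff(names(PG_META), names(tbl))
  if (length(missing_meta)) {
    format_error(paste0("protein-groups table lacks required column: ", missing_meta[1]))
  }
  rep_cols <- reporter_col(design)
  missing_rep <- setdiff(rep_cols, names(tbl))
  if (length(missing_rep)) {
    design_error(paste0(
      "design channel has no matching reporter column: ", missing_rep[1]
    ))
  }

  records <- tibble::tibble(
    protein_id = as.character(tbl[["Protein IDs"]]),
    gene_name = first_gene(tbl[["Gene names"]]),
    is_reverse = parse_flag(tbl[["Reverse"]]),
    is_contaminant = parse_flag(tbl[["Potential contaminant"]]),
    only_identified_by_site = parse_flag(tbl[["Only identified by site"]])
  )
  values <- as.matrix(tbl[, rep_cols])
  mode(values) <- "numeric"
  values[!is.na(values) & values == 0] <- NA_real_
  colnames(values) <- design$sample_id

  out <- tmt_matrix(values, records, design, scale = "raw")
  attr(out, "gene_name_rule") <- "first entry of semicolon-separated 'Gene names'"
  out
}

parse_flag <- function(x) !is.na(x) & x == "+"

first_gene <- function(x) {
  x[is.na(x)] <- ""
  vapply(strsplit(x, ";", fixed = TRUE), function(g) {
    if (length(g)) g[[1]] else ""
  }, character(1))
}

#' Write a protein-groups table
#'
#' Inverse of [read_protein_groups()]: missing cells are written as 0 and flags
#' as `"+"`/blank, so a write/read round trip preserves values, flags and
#' channel order exactly.
#'
#' @param x A raw- or normalized-scale [tmt_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(x, path) {
  rec <- protein_records(x)
  v <- intensity_values(x)
  v[is.na(v)] <- 0
  vals <- tibble::as_tibble(as.data.frame(v), .name_repair = "minimal")
  names(vals) <- reporter_col(tmt_design(x))
  out <- dplyr::bind_cols(
    tibble::tibble(
      `Protein IDs` = rec$protein_id,
      `Gene names` = rec$gene_name,
      `Reverse` = ifelse(rec$is_reverse, "+", ""),
      `Potential contaminant` = ifelse(rec$is_contaminant, "+", ""),
      `Only identified by site` = ifelse(rec$only_identified_by_site, "+", "")
    ),
    vals
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Row-level filters applied before any statistics
#'
#' Removes protein groups flagged as reverse (decoy), potential contaminant or
#' only-identified-by-site, then removes every row with a missing value in any
#' channel. Surviving rows keep their order and values untouched; the operation
#' is idempotent. Counts of dropped rows per reason are stored in the
#' `filter_counts` attribute.
#'
#' @param x A [tmt_matrix()].
#' @return The filtered [tmt_matrix()].
#' @export
filter_rows <- function(x) {
  flagged <- x$is_reverse | x$is_contaminant | x$only_identified_by_site
  v <- intensity_values(x)
  incomplete <- !flagged & rowSums(is.na(v)) > 0
  keep <- !flagged & !incomplete
  out <- restore_tmt(as.data.frame(x)[keep, , drop = FALSE], x)
  attr(out, "norm_factors") <- attr(x, "norm_factors")
  attr(out, "filter_counts") <- c(
    flagged = sum(flagged), incomplete = sum(incomplete), retained = sum(keep)
  )
  if (!any(keep)) warning("filter_rows removed every row", call. = FALSE)
  out
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Gene symbols are case-normalized to upper case and duplicates
#' within a set are collapsed, so `Gfap` and `GFAP` are one member.
#'
#' @param path GMT file.
#' @return A `tmt_gene_sets` object: a named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(gene_set_collection(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    format_error(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  }
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)][nzchar(f[-(1:2)])])))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  gene_set_collection(sets, vapply(fields, `[[`, character(1), 2))
}

#' @rdname read_gmt
#' @param sets Named list of character vectors of gene symbols.
#' @param descriptions Optional per-set description strings.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  sets <- lapply(sets, function(s) unique(toupper(s)))
  if (any(lengths(sets) == 0) && length(sets)) {
    format_error("every gene set must be non-empty")
  }
  structure(sets,
    descriptions = descriptions %||% rep("", length(sets)),
    class = "tmt_gene_sets"
  )
}

#' @rdname read_gmt
#' @param collection A `tmt_gene_sets` object to write.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "descriptions")
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(names(collection)[i], desc[i], collection[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' Tab-separated `(node_a, node_b, combined_score)`; the first three columns
#' are used. STRING exports carry scores on a 0-1000 integer scale
#' (`score_scale = "string_0_1000"`), which are divided by 1000 on load.
#' Self-loops are dropped and duplicate undirected edges keep the maximum
#' score, so downstream graphs are simple.
#'
#' @param path Edge-list TSV with a header row.
#' @param score_scale `"unit"` (scores already in `[0, 1]`) or
#'   `"string_0_1000"`.
#' @return Tibble with columns `node_a`, `node_b`, `combined_score`.
#' @export
read_edge_table <- function(path, score_scale = c("unit", "string_0_1000")) {
  score_scale <- match.arg(score_scale)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tbl) < 3) format_error("edge table needs at least 3 columns")
  edges <- tibble::tibble(
    node_a = toupper(as.character(tbl[[1]])),
    node_b = toupper(as.character(tbl[[2]])),
    combined_score = as.numeric(tbl[[3]])
  )
  hi <- if (score_scale == "string_0_1000") 1000 else 1
  if (any(is.na(edges$combined_score)) ||
    any(edges$combined_score < 0 | edges$combined_score > hi)) {
    format_error(sprintf("combined_score outside declared range [0, %g]", hi))
  }
  if (score_scale == "string_0_1000") {
    edges$combined_score <- edges$combined_score / 1000
  }
  edges <- edges[edges$node_a != edges$node_b, , drop = FALSE]
  # canonical undirected key, keep max score among duplicates
  a <- pmin(edges$node_a, edges$node_b)
  b <- pmax(edges$node_a, edges$node_b)
  edges$node_a <- a
  edges$node_b <- b
  edges |>
    dplyr::group_by(.data$node_a, .data$node_b) |>
    dplyr::summarise(combined_score = max(.data$combined_score), .groups = "drop")
}
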
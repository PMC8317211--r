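# quick construction of small tmt_matrix fixtures

toy_design <- function(groups, plex = NULL, pools_per_plex = 0) {
  plex <- plex %||% rep("p1", length(groups))
  stopifnot(length(plex) == length(groups))
  rows <- list()
  for (p in unique(plex)) {
    g <- groups[plex == p]
    n_exp <- length(g)
    rows[[p]] <- tibble::tibble(
      sample_id = c(
        sprintf("%s_%s_%d", g, p, seq_len(n_exp)),
        if (pools_per_plex > 0) sprintf("pool%d_%s", seq_len(pools_per_plex), p)
      ),
      plex = p,
      channel = seq_len(n_exp + pools_per_plex) - 1L,
      role = c(rep("experimental", n_exp), rep("pooled_reference", pools_per_plex)),
      sex = c(substr(g, 1, 1), rep("none", pools_per_plex)),
      treatment = c(
        ifelse(substr(g, 2, 2) == "N", "nicotine", "control"),
        rep("none", pools_per_plex)
      )
    )
  }
  dplyr::bind_rows(rows)
}

toy_matrix <- function(values, groups, plex = NULL, pools_per_plex = 0,
                       scale = "raw", ids = NULL) {
  values <- as.matrix(values)
  d <- toy_design(groups, plex, pools_per_plex)
  ids <- ids %||% sprintf("P%03d", seq_len(nrow(values)))
  tmt_matrix(values, tibble::tibble(protein_id = ids), d, scale = scale)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
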
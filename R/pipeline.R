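#' Dataset plan mirroring the study layout
#'
#' Four datasets: two brain regions (VTA, NAc shell) under each of two
#' nicotine regimens. The chronic VTA dataset (the deepest one) is
#' batch-corrected by internal reference scaling with no ANOVA prefilter; the
#' three lower-coverage, higher-variability datasets use the linear-model
#' batch correction and the ANOVA prefilter.
#'
#' @return Tibble with columns `name`, `region`, `regimen`, `batch_method`,
#'   `anova_enabled`.
#' @export
default_dataset_plan <- function() {
  tibble::tibble(
    name = c("subchronic_vta", "subchronic_nac", "chronic_vta", "chronic_nac"),
    region = c("vta", "nac", "vta", "nac"),
    regimen = c("subchronic", "subchronic", "chronic", "chronic"),
    batch_method = c("linear_model", "linear_model", "irs", "linear_model"),
    anova_enabled = c(TRUE, TRUE, FALSE, TRUE)
  )
}

#' Pipeline configuration
#'
#' Collects every tunable of the full analysis in one object. All randomness
#' flows from `seed` through fixed per-dataset and per-stage offsets, so two
#' runs with the same configuration produce byte-identical numeric outputs.
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Root integer seed.
#' @param n_proteins Proteins per synthetic dataset.
#' @param datasets Dataset plan (see [default_dataset_plan()]).
#' @param synth Base [synthetic_design()] whose per-dataset copies get their
#'   own seeds (the `n_proteins` and `seed` fields are overridden).
#' @param test A [test_config()]; `anova_enabled` and `seed` are overridden
#'   per dataset according to the plan.
#' @param gmt Optional path to a GMT file; when `NULL`, synthetic gene sets
#'   over the quantified gene universe are used.
#' @param edges Optional path to an interaction edge TSV; when `NULL`, a
#'   synthetic edge table is used.
#' @param edge_score_scale Score scale of the edge file (see
#'   [read_edge_table()]).
#' @param min_score Interaction-score threshold for [build_network()].
#' @param mcode An [mcode_params()].
#' @param enrich_top_k,enrich_q Reporting cutoffs for [top_k_report()].
#' @return A `tmt_pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_proteins = 300,
                            datasets = default_dataset_plan(),
                            synth = synthetic_design(n_proteins = n_proteins),
                            test = test_config(seed = seed),
                            gmt = NULL, edges = NULL,
                            edge_score_scale = "unit",
                            min_score = 0.7, mcode = mcode_params(),
                            enrich_top_k = 5, enrich_q = 0.05) {
  structure(as.list(environment()), class = "tmt_pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose top-level keys match the arguments of
#'   `pipeline_config()` (nested keys `test`, `synth` and `mcode` are passed
#'   on to [test_config()], [synthetic_design()] and [mcode_params()]).
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$test)) args$test <- do.call(test_config, y$test)
  if (!is.null(y$mcode)) args$mcode <- do.call(mcode_params, y$mcode)
  if (!is.null(y$synth)) args$synth <- do.call(synthetic_design, y$synth)
  if (!is.null(y$datasets)) args$datasets <- dplyr::bind_rows(y$datasets)
  do.call(pipeline_config, args)
}

validate_pipeline_config <- function(config) {
  if (!inherits(config, "tmt_pipeline_config")) config_error("not a pipeline config")
  bad <- setdiff(config$datasets$batch_method, c("irs", "linear_model"))
  if (length(bad)) config_error(paste0("invalid batch_method: ", bad[1]))
  for (p in c("gmt", "edges")) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]])) {
      config_error(sprintf("%s path does not exist: %s", p, config[[p]]))
    }
  }
  invisible(config)
}

stage_guard <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(
      sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
      class = "tmtde_stage_error", parent = e, stage = stage
    )
  })
}

dataset_seed <- function(config, i) as.integer(config$seed) + 1000L * i

dataset_test_config <- function(config, i) {
  cfg <- config$test
  cfg$anova_enabled <- config$datasets$anova_enabled[i]
  cfg$seed <- dataset_seed(config, i) + 17L
  cfg
}

universe_of <- function(x) {
  sort(unique(toupper(ifelse(nzchar(x$gene_name), x$gene_name, x$protein_id))))
}

# normalized tables are persisted in the protein-groups dialect; values are
# log2 and strictly positive, so the zero-means-missing read rule is inert
read_normalized <- function(path, design) {
  m <- read_protein_groups(path, design)
  set_intensity_values(m, intensity_values(m), scale = "log2")
}

write_normalized <- function(x, path) write_protein_groups(x, path)

#' Run the full analysis
#'
#' Executes, per dataset: simulate (or load), filter, normalize, QC, the
#' three pairwise comparisons; then the cross-comparison overlap plan,
#' per-direction gene-set enrichment, and MCODE clustering of each
#' comparison's significant proteins on the score-filtered interaction
#' network. Every intermediate table is written as TSV under `out_dir`, and a
#' manifest records parameters, seeds and row counts at every filter.
#'
#' @param config A [pipeline_config()].
#' @return The manifest list, invisibly. Side effect: files under
#'   `config$out_dir`.
#' @export
run_all <- function(config) {
  validate_pipeline_config(config)
  out <- config$out_dir
  dir.create(file.path(out, "datasets"), showWarnings = FALSE, recursive = TRUE)

  plan <- config$datasets
  suites <- list()
  universes <- list()
  manifest_ds <- list()

  for (i in seq_len(nrow(plan))) {
    nm <- plan$name[i]
    ds <- stage_guard("simulate", {
      sd <- config$synth
      sd$n_proteins <- config$n_proteins
      sd$seed <- dataset_seed(config, i)
      dataset <- generate_dataset(sd)
      paths <- write_dataset(dataset, file.path(out, "datasets"), prefix = nm)
      # recompute from the persisted table so a later per-stage re-run over
      # the same files is byte-identical (text representation is the source
      # of truth for all downstream numbers)
      dataset$data <- read_protein_groups(paths[["protein_groups"]], paths[["design"]])
      dataset
    })
    filtered <- stage_guard("filter", filter_rows(ds$data))
    norm <- stage_guard("normalize", {
      n <- normalize_pipeline(filtered, plan$batch_method[i])
      path <- file.path(out, sprintf("normalized_%s.txt", nm))
      write_normalized(n, path)
      n2 <- read_normalized(path, tmt_design(n))
      attr(n2, "norm_factors") <- attr(n, "norm_factors")
      n2
    })
    stage_guard("qc", {
      qc <- qc_report(norm)
      readr::write_tsv(qc$channel_summary, file.path(out, sprintf("qc_%s_channels.tsv", nm)))
      readr::write_tsv(qc$cv, file.path(out, sprintf("qc_%s_cv.tsv", nm)))
      readr::write_tsv(qc$pca, file.path(out, sprintf("qc_%s_pca.tsv", nm)))
    })
    suite <- stage_guard("compare", {
      s <- run_pairwise_suite(norm, dataset_test_config(config, i))
      readr::write_tsv(tidy(s), file.path(out, sprintf("comparisons_%s.tsv", nm)))
      readr::write_tsv(glance(s), file.path(out, sprintf("counts_%s.tsv", nm)))
      s
    })
    suites[[nm]] <- suite
    universes[[nm]] <- universe_of(filtered)
    fc <- attr(filtered, "filter_counts")
    manifest_ds[[nm]] <- list(
      name = nm, batch_method = plan$batch_method[i],
      anova_enabled = plan$anova_enabled[i], seed = dataset_seed(config, i),
      rows_raw = nrow(ds$data),
      rows_dropped_flagged = unname(fc[["flagged"]]),
      rows_dropped_incomplete = unname(fc[["incomplete"]]),
      rows_retained = unname(fc[["retained"]]),
      irs_dropped = if (plan$batch_method[i] == "irs") {
        norm_factors(norm)$irs$n_dropped
      } else 0L,
      comparisons = as.list(stats::setNames(
        glance(suite)$n_significant, glance(suite)$comparison
      ))
    )
  }

  flat <- list()
  for (nm in names(suites)) {
    for (comp in names(suites[[nm]])) {
      flat[[paste(nm, comp, sep = ".")]] <- suites[[nm]][[comp]]
    }
  }

  stage_guard("overlap", {
    pairs <- overlap_plan(plan)
    ov <- overlap_matrix(flat, pairs)
    readr::write_tsv(overlap_report(ov), file.path(out, "overlap.tsv"))
  })

  all_genes <- sort(unique(unlist(universes)))
  collection <- stage_guard("enrich", {
    if (is.null(config$gmt)) {
      synthetic_gene_sets(all_genes, seed = as.integer(config$seed) + 7L)
    } else {
      read_gmt(config$gmt)
    }
  })
  stage_guard("enrich", {
    rows <- list()
    for (nm in names(suites)) {
      for (comp in names(suites[[nm]])) {
        for (dir in c("up", "down")) {
          query <- significant_proteins(suites[[nm]][[comp]], dir)$identifier
          if (!length(query)) next
          er <- top_k_report(
            enrich(query, universes[[nm]], collection),
            k = config$enrich_top_k, q_cutoff = config$enrich_q
          )
          if (!nrow(er)) next
          rows[[length(rows) + 1]] <- tidy(er) |>
            dplyr::mutate(dataset = nm, comparison = comp, direction = dir, .before = 1)
        }
      }
    }
    readr::write_tsv(
      dplyr::bind_rows(rows) %||% tibble::tibble(),
      file.path(out, "enrichment.tsv")
    )
  })

  stage_guard("cluster", {
    edges <- if (is.null(config$edges)) {
      synthetic_edge_table(all_genes, seed = as.integer(config$seed) + 11L)
    } else {
      read_edge_table(config$edges, config$edge_score_scale)
    }
    net <- build_network(edges, config$min_score)
    rows <- list()
    for (nm in names(suites)) {
      for (comp in names(suites[[nm]])) {
        sig <- significant_proteins(suites[[nm]][[comp]])$identifier
        present <- intersect(sig, igraph::V(net)$name)
        if (length(present) < 2) next
        cl <- mcode_find_clusters(
          igraph::induced_subgraph(net, present), config$mcode
        )
        if (!nrow(cl)) next
        rows[[length(rows) + 1]] <- tidy(cl) |>
          dplyr::mutate(dataset = nm, comparison = comp, .before = 1)
      }
    }
    readr::write_tsv(
      dplyr::bind_rows(rows) %||% tibble::tibble(),
      file.path(out, "clusters.tsv")
    )
  })

  manifest <- list(
    package = "tmtde",
    version = as.character(utils::packageVersion("tmtde")),
    seed = as.integer(config$seed),
    n_proteins = config$n_proteins,
    min_score = config$min_score,
    test = config$test[c("s0", "fdr", "n_permutations", "anova_fdr")],
    datasets = manifest_ds
  )
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(manifest)
}

overlap_plan <- function(plan) {
  pairs <- list()
  comps <- c("MC_vs_FC", "FN_vs_FC", "MN_vs_MC")
  for (region in unique(plan$region)) {
    nms <- plan$name[plan$region == region]
    if (length(nms) == 2) {
      for (comp in comps) {
        pairs[[length(pairs) + 1]] <- tibble::tibble(
          a = paste(nms[1], comp, sep = "."),
          b = paste(nms[2], comp, sep = "."),
          label = sprintf("%s %s across regimens", region, comp)
        )
      }
    }
  }
  for (nm in plan$name) {
    pairs[[length(pairs) + 1]] <- tibble::tibble(
      a = paste(nm, "FN_vs_FC", sep = "."),
      b = paste(nm, "MN_vs_MC", sep = "."),
      label = sprintf("%s nicotine effect across sexes", nm)
    )
  }
  dplyr::bind_rows(pairs)
}

#' Run one pipeline stage from on-disk inputs
#'
#' Re-runs a single stage against files written by [run_all()] (or compatible
#' inputs), producing the same outputs as the corresponding slice of the full
#' run.
#'
#' @param config A [pipeline_config()].
#' @param stage One of `"simulate"`, `"normalize"`, `"qc"`, `"compare"`,
#'   `"overlap"`, `"enrich"`, `"cluster"`.
#' @param name Dataset name (for the per-dataset stages); defaults to every
#'   dataset in the plan.
#' @param inputs Named list of explicit inputs for the cross-dataset stages:
#'   `a`/`b` (comparison TSV paths) plus `comparison_a`/`comparison_b`
#'   (contrast names, needed when a file stacks several) for `"overlap"`;
#'   `table` (comparison TSV path) and optionally `which` (contrast name)
#'   for `"enrich"` and `"cluster"`; `out` to override the output path.
#' @return Invisibly, the path(s) written.
#' @export
run_stage <- function(config, stage, name = NULL, inputs = list()) {
  validate_pipeline_config(config)
  stages <- c("simulate", "normalize", "qc", "compare", "overlap", "enrich", "cluster")
  if (!stage %in% stages) {
    tmt_abort(paste0("unknown stage: ", stage), "tmtde_usage_error")
  }
  out <- config$out_dir
  dir.create(file.path(out, "datasets"), showWarnings = FALSE, recursive = TRUE)
  plan <- config$datasets
  names_run <- name %||% plan$name

  ds_paths <- function(nm) {
    list(
      pg = file.path(out, "datasets", paste0(nm, "_proteinGroups.txt")),
      design = file.path(out, "datasets", paste0(nm, "_design.tsv")),
      norm = file.path(out, sprintf("normalized_%s.txt", nm))
    )
  }

  written <- character(0)
  for (nm in names_run) {
    i <- match(nm, plan$name)
    if (is.na(i) && stage %in% c("simulate", "normalize", "qc", "compare")) {
      tmt_abort(paste0("dataset not in plan: ", nm), "tmtde_usage_error")
    }
    p <- ds_paths(nm)
    if (stage == "simulate") {
      sd <- config$synth
      sd$n_proteins <- config$n_proteins
      sd$seed <- dataset_seed(config, i)
      write_dataset(generate_dataset(sd), file.path(out, "datasets"), prefix = nm)
      written <- c(written, p$pg)
    } else if (stage == "normalize") {
      m <- filter_rows(read_protein_groups(p$pg, p$design))
      n <- normalize_pipeline(m, plan$batch_method[i])
      write_normalized(n, p$norm)
      written <- c(written, p$norm)
    } else if (stage == "qc") {
      n <- read_normalized(p$norm, p$design)
      qc <- qc_report(n)
      f <- file.path(out, sprintf("qc_%s_cv.tsv", nm))
      readr::write_tsv(qc$channel_summary, file.path(out, sprintf("qc_%s_channels.tsv", nm)))
      readr::write_tsv(qc$cv, f)
      readr::write_tsv(qc$pca, file.path(out, sprintf("qc_%s_pca.tsv", nm)))
      written <- c(written, f)
    } else if (stage == "compare") {
      n <- read_normalized(p$norm, p$design)
      s <- run_pairwise_suite(n, dataset_test_config(config, i))
      f <- file.path(out, sprintf("comparisons_%s.tsv", nm))
      readr::write_tsv(tidy(s), f)
      readr::write_tsv(glance(s), file.path(out, sprintf("counts_%s.tsv", nm)))
      written <- c(written, f)
    }
    if (stage %in% c("overlap", "enrich", "cluster")) break
  }

  sig_list <- function(path, comp = NULL, dir = NULL) {
    tbl <- readr::read_tsv(path, show_col_types = FALSE)
    if ("comparison" %in% names(tbl)) {
      if (!is.null(comp)) {
        tbl <- tbl[tbl$comparison == comp, ]
      } else if (length(unique(tbl$comparison)) > 1) {
        input_error("file stacks several comparisons; name one via inputs$comparison_*")
      }
    }
    tbl <- tbl[tbl$significant, ]
    if (!is.null(dir)) tbl <- tbl[tbl$direction == dir, ]
    tibble::tibble(
      identifier = toupper(ifelse(nzchar(tbl$gene_name) & !is.na(tbl$gene_name),
        tbl$gene_name, tbl$protein_id
      )),
      direction = tbl$direction
    )
  }

  if (stage == "overlap") {
    s <- overlap_summary(
      sig_list(inputs$a, inputs$comparison_a),
      sig_list(inputs$b, inputs$comparison_b),
      label_a = basename(inputs$a), label_b = basename(inputs$b)
    )
    f <- inputs$out %||% file.path(out, "overlap_stage.tsv")
    readr::write_tsv(overlap_report(s), f)
    written <- c(written, f)
  } else if (stage == "enrich") {
    tbl <- readr::read_tsv(inputs$table, show_col_types = FALSE)
    universe <- sort(unique(toupper(
      ifelse(nzchar(tbl$gene_name) & !is.na(tbl$gene_name), tbl$gene_name, tbl$protein_id)
    )))
    collection <- if (is.null(config$gmt)) {
      synthetic_gene_sets(universe, seed = as.integer(config$seed) + 7L)
    } else {
      read_gmt(config$gmt)
    }
    rows <- list()
    for (dir in c("up", "down")) {
      query <- sig_list(inputs$table, inputs$which, dir)$identifier
      if (!length(query)) next
      er <- top_k_report(enrich(query, universe, collection),
        k = config$enrich_top_k, q_cutoff = config$enrich_q
      )
      if (nrow(er)) {
        rows[[length(rows) + 1]] <- dplyr::mutate(tidy(er), direction = dir, .before = 1)
      }
    }
    f <- inputs$out %||% file.path(out, "enrichment_stage.tsv")
    readr::write_tsv(dplyr::bind_rows(rows) %||% tibble::tibble(), f)
    written <- c(written, f)
  } else if (stage == "cluster") {
    edges <- if (is.null(config$edges)) {
      tbl <- readr::read_tsv(inputs$table, show_col_types = FALSE)
      genes <- sort(unique(toupper(tbl$gene_name[nzchar(tbl$gene_name) & !is.na(tbl$gene_name)])))
      synthetic_edge_table(genes, seed = as.integer(config$seed) + 11L)
    } else {
      read_edge_table(config$edges, config$edge_score_scale)
    }
    net <- build_network(edges, config$min_score)
    sig <- sig_list(inputs$table, inputs$which)$identifier
    present <- intersect(sig, igraph::V(net)$name)
    cl <- if (length(present) >= 2) {
      mcode_find_clusters(igraph::induced_subgraph(net, present), config$mcode)
    } else {
      mcode_find_clusters(build_network(tibble::tibble(
        node_a = character(), node_b = character(), combined_score = numeric()
      )), config$mcode)
    }
    f <- inputs$out %||% file.path(out, "clusters_stage.tsv")
    readr::write_tsv(tidy(cl), f)
    written <- c(written, f)
  }
  invisible(written)
}
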
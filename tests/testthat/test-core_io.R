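write_pg_fixture <- function(path, design, values, ids = NULL, genes = NULL,
                             reverse = NULL, contaminant = NULL, site = NULL) {
  n <- nrow(values)
  ids <- ids %||% sprintf("P%02d", seq_len(n))
  flags <- function(x) ifelse((x %||% rep(FALSE, n)), "+", "")
  header <- c(
    "Protein IDs", "Gene names", "Reverse", "Potential contaminant",
    "Only identified by site",
    paste("Reporter intensity corrected", design$channel, design$plex)
  )
  rows <- vapply(seq_len(n), function(i) {
    paste(c(
      ids[i], (genes %||% rep("", n))[i], flags(reverse)[i],
      flags(contaminant)[i], flags(site)[i],
      format(values[i, ], trim = TRUE, scientific = FALSE)
    ), collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  path
}

test_that("protein-group reading maps channels, zeros and flags correctly", {
  d <- toy_design(rep(c("MC", "FC", "MN", "FN"), 2),
    plex = rep(c("p1", "p2"), each = 4), pools_per_plex = 1
  )
  vals <- matrix(seq_len(3 * nrow(d)) * 10, nrow = 3)
  vals[1, 2] <- 0 # stored as missing, not numeric zero
  f <- withr::local_tempfile(fileext = ".txt")
  write_pg_fixture(f, d, vals,
    genes = c("Gfap", "Ppp1r1b;Alt", ""),
    reverse = c(FALSE, TRUE, FALSE)
  )
  m <- read_protein_groups(f, d)
  expect_s3_class(m, "tmt_matrix")
  expect_identical(dim(intensity_values(m)), c(3L, nrow(d)))
  expect_identical(tmt_scale(m), "raw")
  expect_true(is.na(intensity_values(m)[1, 2]))
  expect_identical(m$is_reverse, c(FALSE, TRUE, FALSE))
  # multi-entry gene names keep the first entry
  expect_identical(m$gene_name, c("Gfap", "Ppp1r1b", ""))
})

test_that("reading fails loudly on missing columns or design mismatch", {
  d <- toy_design(c("MC", "FC"))
  f <- withr::local_tempfile(fileext = ".txt")
  write_pg_fixture(f, d, matrix(1:4, 2))
  # a design channel with no matching reporter column
  d_bad <- toy_design(c("MC", "FC", "MN"))
  expect_error(read_protein_groups(f, d_bad), class = "tmtde_design_error")
  # a required metadata column removed
  lines <- readLines(f)
  lines[1] <- sub("Reverse\t", "Rev\t", lines[1])
  writeLines(lines, f)
  expect_error(read_protein_groups(f, d), class = "tmtde_format_error")
})

test_that("write/read round trip preserves values, flags and channel order", {
  d <- toy_design(rep(c("MC", "FC", "MN", "FN"), each = 2), pools_per_plex = 2)
  set.seed(4)
  vals <- matrix(round(stats::runif(5 * nrow(d)) * 1e6, 3), nrow = 5)
  vals[2, 3] <- NA
  m <- tmt_matrix(
    vals,
    tibble::tibble(
      protein_id = sprintf("Q%d", 1:5), gene_name = sprintf("g%d", 1:5),
      is_reverse = c(FALSE, FALSE, TRUE, FALSE, FALSE),
      is_contaminant = c(FALSE, TRUE, FALSE, FALSE, FALSE),
      only_identified_by_site = FALSE
    ),
    d
  )
  f <- withr::local_tempfile(fileext = ".txt")
  write_protein_groups(m, f)
  m2 <- read_protein_groups(f, d)
  expect_identical(intensity_values(m2), intensity_values(m))
  expect_identical(protein_records(m2), protein_records(m))
  expect_identical(tmt_design(m2)$sample_id, tmt_design(m)$sample_id)
})

test_that("filter_rows drops flagged and incomplete rows, keeps the rest intact", {
  d <- toy_design(c("MC", "MC", "FC", "FC"))
  vals <- matrix(1:20, nrow = 5)
  rec <- tibble::tibble(
    protein_id = sprintf("P%d", 1:5),
    is_reverse = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    is_contaminant = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    only_identified_by_site = c(FALSE, FALSE, TRUE, FALSE, FALSE)
  )
  m <- tmt_matrix(vals, rec, d)
  out <- filter_rows(m)
  expect_identical(out$protein_id, c("P4", "P5"))
  expect_identical(intensity_values(out), intensity_values(m)[4:5, ])

  # a single missing channel drops the whole row
  vals2 <- matrix(1, 2, 4)
  vals2[2, 3] <- NA
  m2 <- tmt_matrix(vals2, tibble::tibble(protein_id = c("A", "B")), d)
  expect_identical(filter_rows(m2)$protein_id, "A")

  # identity on clean input, and idempotence
  m3 <- tmt_matrix(matrix(1:8, 2), tibble::tibble(protein_id = c("A", "B")), d)
  once <- filter_rows(m3)
  expect_identical(intensity_values(once), intensity_values(m3))
  expect_identical(
    intensity_values(filter_rows(once)),
    intensity_values(once)
  )
  # empty survivor set warns rather than errors
  m4 <- tmt_matrix(matrix(NA_real_, 1, 4), tibble::tibble(protein_id = "A"), d)
  expect_warning(filter_rows(m4), "every row")
})

test_that("GMT parsing normalizes case and rejects malformed lines", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c(
    "pathA\tdesc\tGfap\tGFAP\tPpp1r1b",
    "pathB\tdesc\tTh\tDdc"
  ), f)
  gs <- read_gmt(f)
  expect_length(gs, 2)
  # case-normalization collapses Gfap/GFAP into one member
  expect_setequal(gs[["pathA"]], c("GFAP", "PPP1R1B"))
  expect_setequal(gs[["pathB"]], c("TH", "DDC"))

  writeLines(c("pathA\tdesc\tGFAP", "bad\tonlytwo"), f)
  expect_error(read_gmt(f), "line 2", class = "tmtde_format_error")

  writeLines(character(0), f)
  expect_length(read_gmt(f), 0)
})

test_that("edge tables are rescaled, de-duplicated and self-loop free", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "protein1\tprotein2\tcombined_score",
    "A\tB\t700",
    "A\tA\t900",
    "B\tA\t900"
  ), f)
  e <- read_edge_table(f, "string_0_1000")
  expect_identical(nrow(e), 1L)
  # duplicate undirected edge keeps the max, scores divided by 1000
  expect_equal(e$combined_score, 0.9)
  expect_identical(c(e$node_a, e$node_b), c("A", "B"))

  writeLines(c("a\tb\tscore", "A\tB\t1.2"), f)
  expect_error(read_edge_table(f, "unit"), class = "tmtde_format_error")
})
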
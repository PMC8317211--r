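test_that("d-statistic reduces to the classic pooled t at s0 = 0", {
  set.seed(14)
  for (r in 1:20) {
    a <- stats::rnorm(4 + r %% 3)
    b <- stats::rnorm(4, 0.5)
    ours <- d_statistic(a, b, s0 = 0)
    classic <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(ours$d, unname(classic$statistic), tolerance = 1e-12)
  }
})

test_that("d-statistic hand cases", {
  # zero variance: se = 0, d = diff / s0
  hand <- d_statistic(c(2, 2), c(1, 1), s0 = 0.5)
  expect_equal(hand$se, 0)
  expect_equal(hand$d, 2.0)
  # equal means give d = 0 regardless of s0
  expect_equal(d_statistic(c(1, 2), c(2, 1), s0 = 0.3)$d, 0)
  expect_equal(d_statistic(c(1, 2), c(2, 1), s0 = 0)$d, 0)
  # too few replicates
  expect_error(d_statistic(1, c(1, 2)), class = "tmtde_input_error")
})

test_that("increasing s0 never increases any |d|", {
  set.seed(15)
  Y <- matrix(stats::rnorm(50 * 8), 50, 8)
  m <- toy_matrix(Y, rep(c("MC", "FC"), each = 4), scale = "log2")
  cfg0 <- test_config(s0 = 0, anova_enabled = FALSE)
  d_prev <- abs(permutation_fdr(m, "MC", "FC", cfg0)$d)
  for (s0 in c(0.2, 0.5, 1, 2)) {
    cfg <- test_config(s0 = s0, anova_enabled = FALSE)
    d_cur <- abs(permutation_fdr(m, "MC", "FC", cfg)$d)
    expect_true(all(d_cur <= d_prev + 1e-12))
    d_prev <- d_cur
  }
})

test_that("ANOVA prefilter applies BH as in the hand example and drops degenerates", {
  # hand BH: p = {1e-4, .02, .03, .9}, m = 4 -> {4e-4, .04, .04, .9}
  expect_equal(
    stats::p.adjust(c(1e-4, 0.02, 0.03, 0.9), method = "BH"),
    c(4e-4, 0.04, 0.04, 0.9)
  )

  set.seed(16)
  n <- 60
  Y <- matrix(stats::rnorm(n * 8, 20, 0.2), n, 8)
  Y[1, ] <- 7 # constant across all samples -> dropped by convention
  Y[2, 1:2] <- Y[2, 1:2] + 10 * 0.2 # one group shifted by 10 sigma -> retained
  m <- toy_matrix(Y, c("MC", "MC", "FC", "FC", "MN", "MN", "FN", "FN"),
    scale = "log2"
  )
  out <- anova_prefilter(m, test_config())
  tab <- attr(out, "anova_table")
  expect_true(is.na(tab$p[1]))
  expect_false("P001" %in% out$protein_id)
  expect_true("P002" %in% out$protein_id)

  # the per-protein F agrees with stats::aov on a few proteins
  g <- factor(c("MC", "MC", "FC", "FC", "MN", "MN", "FN", "FN"))
  for (i in 3:6) {
    ref <- summary(stats::aov(Y[i, ] ~ g))[[1]]$`F value`[1]
    expect_equal(unname(tab$f[i]), ref, tolerance = 1e-10)
  }
})

test_that("permutation q-values are monotone in |d| and row-deterministic", {
  set.seed(17)
  Y <- matrix(stats::rnorm(40 * 8, 20, 0.3), 40, 8)
  Y[1:4, 1:4] <- Y[1:4, 1:4] + 2
  m <- toy_matrix(Y, rep(c("MC", "FC"), each = 4), scale = "log2")
  cfg <- test_config(anova_enabled = FALSE, seed = 2)
  res <- permutation_fdr(m, "MC", "FC", cfg)
  ord <- order(abs(res$d), decreasing = TRUE)
  expect_true(all(diff(res$q_value[ord]) >= -1e-12))
  expect_true(all(res$q_value[res$significant] < cfg$fdr))
  expect_identical(res$direction, ifelse(res$log2_fc >= 0, "up", "down"))

  # duplicated rows receive identical q-values
  m2 <- toy_matrix(Y[c(1, 1, 2, 2, 5:20), ], rep(c("MC", "FC"), each = 4),
    scale = "log2"
  )
  res2 <- permutation_fdr(m2, "MC", "FC", cfg)
  expect_equal(res2$q_value[1], res2$q_value[2])
  expect_equal(res2$q_value[3], res2$q_value[4])

  # a single 10-sigma protein among nulls attains the minimum q of the set
  Y3 <- matrix(stats::rnorm(100 * 8, 20, 0.25), 100, 8)
  Y3[7, 1:4] <- Y3[7, 1:4] + 2.5
  m3 <- toy_matrix(Y3, rep(c("MC", "FC"), each = 4), scale = "log2")
  res3 <- permutation_fdr(m3, "MC", "FC", cfg)
  expect_equal(res3$q_value[7], min(res3$q_value))
})

test_that("reversing the group order flips fold changes and directions, not q", {
  set.seed(18)
  Y <- matrix(stats::rnorm(30 * 8, 20, 0.3), 30, 8)
  m <- toy_matrix(Y, rep(c("MC", "FC"), each = 4), scale = "log2")
  cfg <- test_config(anova_enabled = FALSE, seed = 3)
  fwd <- permutation_fdr(m, "MC", "FC", cfg)
  rev <- permutation_fdr(m, "FC", "MC", cfg)
  expect_equal(rev$log2_fc, -fwd$log2_fc)
  expect_equal(rev$d, -fwd$d)
  expect_equal(rev$q_value, fwd$q_value)
  expect_identical(
    rev$direction,
    ifelse(fwd$direction == "up", "down", "up")
  )
})

test_that("the permutation engine enumerates exhaustively when feasible", {
  set.seed(19)
  Y <- matrix(stats::rnorm(20 * 8), 20, 8)
  m <- toy_matrix(Y, rep(c("MC", "FC"), each = 4), scale = "log2")
  res <- permutation_fdr(m, "MC", "FC", test_config(anova_enabled = FALSE))
  # choose(8,4) = 70 assignments minus the identity
  expect_identical(attr(res, "n_permutations_used"), 69L)
  expect_true(attr(res, "exhaustive"))

  # with a tiny permutation budget it samples distinct assignments instead
  res2 <- permutation_fdr(
    m, "MC", "FC",
    test_config(n_permutations = 20, anova_enabled = FALSE, seed = 4)
  )
  expect_identical(attr(res2, "n_permutations_used"), 20L)
  expect_false(attr(res2, "exhaustive"))
})

test_that("the pairwise suite uses the declared reference groups and the prefilter flag", {
  d <- synthetic_design(
    n_proteins = 150, frac_trt_de_f = 0, frac_trt_de_m = 0,
    frac_sex_de = 0.2, frac_missing = 0, seed = 23
  )
  ds <- generate_dataset(d)
  norm <- normalize_pipeline(filter_rows(ds$data), "irs")

  cfg <- test_config(anova_enabled = FALSE, seed = 23)
  s <- run_pairwise_suite(norm, cfg)
  expect_named(s, c("MC_vs_FC", "FN_vs_FC", "MN_vs_MC"))
  expect_identical(attr(s$MC_vs_FC, "ref_group"), "FC")
  expect_identical(attr(s$FN_vs_FC, "ref_group"), "FC")
  expect_identical(attr(s$MN_vs_MC, "ref_group"), "MC")

  # sex effects only: the sex contrast dominates the treatment contrasts
  g <- glance(s)
  expect_gt(
    g$n_significant[g$comparison == "MC_vs_FC"],
    2 * max(g$n_significant[g$comparison != "MC_vs_FC"])
  )

  # the prefilter shrinks the tested universe
  cfg_on <- test_config(anova_enabled = TRUE, seed = 23)
  s_on <- run_pairwise_suite(norm, cfg_on)
  expect_lt(nrow(s_on$MC_vs_FC), nrow(s$MC_vs_FC))
  expect_identical(nrow(s_on$MC_vs_FC), sum(attr(s_on, "anova_table")$retained))
})

test_that("mirrored female/male effects give approximately exchanged up/down counts", {
  # construct mirrored treatment effects directly: FN gains what MN loses
  set.seed(24)
  n <- 120
  base <- matrix(stats::rnorm(n * 16, 20, 0.25), n, 16)
  groups <- rep(c("MC", "FC", "MN", "FN"), each = 4)
  eff <- numeric(n)
  idx <- 1:24
  eff[idx] <- rep(c(1, -1), 12)
  base[, groups == "FN"] <- base[, groups == "FN"] + eff
  base[, groups == "MN"] <- base[, groups == "MN"] - eff
  m <- toy_matrix(base, groups, scale = "log2")
  s <- run_pairwise_suite(m, test_config(anova_enabled = FALSE, seed = 9))
  g <- glance(s)
  fn <- g[g$comparison == "FN_vs_FC", ]
  mn <- g[g$comparison == "MN_vs_MC", ]
  expect_equal(fn$n_up, mn$n_down, tolerance = 0.35)
  expect_equal(fn$n_down, mn$n_up, tolerance = 0.35)
})
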
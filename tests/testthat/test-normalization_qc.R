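test_that("sample loading equalizes channel totals with the expected factors", {
  # totals 100 and 300, mean 200 -> factors 2 and 2/3
  m <- toy_matrix(matrix(c(10, 90, 30, 270), nrow = 2), c("MC", "FC"))
  out <- sample_loading_normalize(m)
  f <- norm_factors(out)$sl$factor
  expect_equal(f, c(2, 2 / 3))
  expect_equal(unname(colSums(intensity_values(out))), c(200, 200))

  # identical channels: factors 1, matrix unchanged
  m2 <- toy_matrix(matrix(c(5, 7, 5, 7), nrow = 2), c("MC", "FC"))
  out2 <- sample_loading_normalize(m2)
  expect_equal(norm_factors(out2)$sl$factor, c(1, 1))
  expect_equal(intensity_values(out2), intensity_values(m2))

  # per-plex totals equal within tight relative tolerance on random data
  set.seed(2)
  m3 <- toy_matrix(
    matrix(stats::runif(30 * 8, 1, 100), 30),
    rep(c("MC", "FC", "MN", "FN"), 2),
    plex = rep(c("p1", "p2"), each = 4)
  )
  out3 <- sample_loading_normalize(m3)
  v <- intensity_values(out3)
  d <- tmt_design(out3)
  for (p in c("p1", "p2")) {
    tot <- colSums(v[, d$plex == p])
    expect_lt(max(abs(tot / mean(tot) - 1)), 1e-9)
  }

  # degenerate channel
  m4 <- toy_matrix(matrix(c(1, 1, 0, 0), 2), c("MC", "FC"))
  expect_error(sample_loading_normalize(m4), class = "tmtde_input_error")
})

test_that("TMM factors behave at the closed-form anchor points", {
  set.seed(7)
  base <- stats::rlnorm(200, log(1000), 1)
  # channel 2 identical to channel 1, channel 3 doubled uniformly
  m <- toy_matrix(cbind(base, base, 2 * base), c("MC", "FC", "MN"))
  f <- tmm_factors(m)
  ref_raw <- f$raw_factor
  # identical channel -> raw factor 1; doubled channel -> raw factor 2
  # (reference is one of the two identical channels)
  expect_equal(sort(ref_raw), c(1, 1, 2), tolerance = 1e-9)
  # anchored factors multiply to 1
  expect_equal(prod(f$factor), 1, tolerance = 1e-12)

  # trimming removes a 10% block of extreme ratios: factor stays 1
  x <- c(rep(100, 90), rep(100, 10))
  y <- c(rep(100, 90), rep(3200, 10)) # M = +5 for the outliers
  m2 <- toy_matrix(cbind(x, y), c("MC", "FC"))
  f2 <- tmm_factors(m2)
  expect_equal(f2$raw_factor, c(1, 1), tolerance = 1e-9)

  # insufficient data after trimming
  m3 <- toy_matrix(matrix(c(1, 2, 2, 4), 2), c("MC", "FC"))
  expect_error(tmm_factors(m3, min_kept = 10), class = "tmtde_input_error")
})

test_that("TMM agrees with the edgeR reference on equal-size libraries", {
  skip_if_not_installed("edgeR")
  set.seed(42)
  counts <- matrix(stats::rlnorm(500 * 4, log(500), 1.2), 500, 4)
  counts[, 2] <- counts[, 2] * 1.6
  m <- sample_loading_normalize(
    toy_matrix(counts, c("MC", "FC", "MN", "FN"))
  )
  ours <- tmm_factors(m)
  theirs <- edgeR::calcNormFactors(intensity_values(m), method = "TMM")
  expect_equal(ours$factor, unname(theirs), tolerance = 0.02)
})

test_that("IRS aligns pooled references across plexes and is idempotent", {
  # refs 100 (plex1) and 400 (plex2): target 200, factors 2 and 0.5
  v <- cbind(
    matrix(50, 1, 2), 100, 100, # plex1: 2 experimental + 2 pools
    matrix(80, 1, 2), 400, 400 # plex2
  )
  m <- toy_matrix(v, c("MC", "FC", "MC", "FC"),
    plex = rep(c("p1", "p2"), each = 2), pools_per_plex = 2
  )
  out <- irs_normalize(m)
  fac <- norm_factors(out)$irs$factors
  expect_equal(unname(fac[1, ]), c(2, 0.5))
  vv <- intensity_values(out)
  d <- tmt_design(out)
  pool_ref <- function(x, p) {
    exp(rowMeans(log(x[, d$plex == p & d$role == "pooled_reference", drop = FALSE])))
  }
  expect_equal(pool_ref(vv, "p1"), pool_ref(vv, "p2"))
  expect_equal(unname(pool_ref(vv, "p1")), 200)

  # idempotence
  twice <- irs_normalize(out)
  expect_equal(intensity_values(twice), intensity_values(out), tolerance = 1e-12)

  # equal refs -> identity; single plex -> identity
  m_eq <- toy_matrix(cbind(1, 2, 9, 9, 3, 4, 9, 9), c("MC", "FC", "MC", "FC"),
    plex = rep(c("p1", "p2"), each = 2), pools_per_plex = 2
  )
  expect_equal(
    intensity_values(irs_normalize(m_eq)),
    intensity_values(m_eq)
  )
  m_one <- toy_matrix(cbind(1, 2, 3, 4), c("MC", "FC"), pools_per_plex = 2)
  expect_equal(intensity_values(irs_normalize(m_one)), intensity_values(m_one))

  # proteins without usable pool values are dropped and counted
  v_bad <- rbind(v, c(1, 1, NA, 5, 1, 1, 4, 4))
  m_bad <- toy_matrix(v_bad, c("MC", "FC", "MC", "FC"),
    plex = rep(c("p1", "p2"), each = 2), pools_per_plex = 2
  )
  out_bad <- irs_normalize(m_bad)
  expect_identical(nrow(out_bad), 1L)
  expect_identical(norm_factors(out_bad)$irs$n_dropped, 1L)
})

test_that("linear batch correction removes a pure additive plex shift exactly", {
  set.seed(9)
  groups <- rep(c("MC", "FC", "MN", "FN"), 2)
  plex <- rep(c("p1", "p2"), each = 4)
  base <- matrix(stats::rnorm(20 * 4, 20, 1), 20, 4)
  v <- cbind(base, base + 1.0) # plex2 = plex1 + 1 uniformly
  m <- toy_matrix(v, groups, plex = plex, scale = "log2")
  out <- linear_batch_correct(m)
  vv <- intensity_values(out)
  # plex means equal after correction
  expect_equal(rowMeans(vv[, 1:4]), rowMeans(vv[, 5:8]), tolerance = 1e-10)
  # within-plex contrasts untouched
  expect_equal(vv[, 1] - vv[, 2], v[, 1] - v[, 2],
    tolerance = 1e-10, ignore_attr = TRUE
  )
  # group-mean differences preserved
  expect_equal(
    rowMeans(vv[, c(1, 5)]) - rowMeans(vv[, c(2, 6)]),
    rowMeans(v[, c(1, 5)]) - rowMeans(v[, c(2, 6)]),
    tolerance = 1e-10, ignore_attr = TRUE
  )

  # single plex is identity
  m1 <- toy_matrix(base, c("MC", "FC", "MN", "FN"), scale = "log2")
  expect_equal(intensity_values(linear_batch_correct(m1)), base,
    ignore_attr = TRUE
  )

  # confounded design errors out
  mc <- toy_matrix(v, c(rep("MC", 4), rep("FC", 4)), plex = plex, scale = "log2")
  expect_error(linear_batch_correct(mc), class = "tmtde_confounding_error")
})

test_that("linear batch correction matches the limma reference", {
  skip_if_not_installed("limma")
  set.seed(10)
  groups <- rep(c("MC", "FC", "MN", "FN"), 4)
  plex <- rep(c("p1", "p2"), each = 8)
  v <- matrix(stats::rnorm(50 * 16, 20, 1), 50, 16)
  v[, plex == "p2"] <- v[, plex == "p2"] + stats::rnorm(1, 0, 0.5)
  m <- toy_matrix(v, groups, plex = plex, scale = "log2")
  ours <- intensity_values(linear_batch_correct(m))
  theirs <- limma::removeBatchEffect(
    v,
    batch = plex, design = stats::model.matrix(~ 0 + groups)
  )
  dimnames(theirs) <- dimnames(ours)
  expect_equal(ours, theirs, tolerance = 1e-8)
})

test_that("the composed pipeline recovers injected factors and preserves ranks", {
  # loading and batch artifacts only, small noise: the closed-form regime
  d <- synthetic_design(
    n_proteins = 300, sigma_within = 0.02, sigma_pool = 0.01,
    frac_sex_de = 0, frac_trt_de_f = 0, frac_trt_de_m = 0,
    frac_decoy = 0, frac_contaminant = 0, frac_missing = 0, seed = 33
  )
  ds <- generate_dataset(d)
  raw <- intensity_values(ds$data)

  # estimated sample-loading factors recover the injected inverse loadings
  sl <- sample_loading_normalize(ds$data)
  est <- norm_factors(sl)$sl
  des <- tmt_design(ds$data)
  for (p in unique(des$plex)) {
    cols <- des$plex == p
    expect_gt(
      stats::cor(log(est$factor[cols]), -log(ds$loading[cols])), 0.99
    )
  }

  # IRS factors recover the injected per-protein batch shifts: the log2
  # factor for a plex should track (mean shift - own shift)
  norm <- normalize_pipeline(ds$data, "irs")
  irs <- norm_factors(norm)$irs$factors
  keep_t <- match(rownames(irs), ds$truth$protein_id)
  expected_shift <- rowMeans(ds$batch_log2[keep_t, ]) - ds$batch_log2[keep_t, 1]
  expect_gt(stats::cor(log2(irs[, 1]), expected_shift), 0.99)

  v <- intensity_values(norm)
  dn <- tmt_design(norm)
  p1 <- exp(rowMeans(v[, dn$plex == "plex1" & dn$role == "pooled_reference"]))
  p2 <- exp(rowMeans(v[, dn$plex == "plex2" & dn$role == "pooled_reference"]))
  expect_equal(p1, p2, tolerance = 1e-9)

  # per-channel stages (SL, TMM) preserve within-channel ranks; the
  # per-protein stage (IRS) preserves each protein's cross-channel order
  # within a plex
  st <- tmm_normalize(sample_loading_normalize(ds$data))
  vst <- intensity_values(st)
  for (j in seq_len(ncol(vst))) {
    expect_identical(order(vst[, j]), order(raw[, j]))
  }
  dn <- tmt_design(norm)
  keep <- match(norm$protein_id, ds$data$protein_id)
  for (p in unique(dn$plex)) {
    cols <- which(dn$plex == p)
    pre <- log2(intensity_values(st))[keep, cols, drop = FALSE]
    post <- v[, cols, drop = FALSE]
    for (i in seq_len(nrow(post))) {
      expect_identical(order(post[i, ]), order(pre[i, ]))
    }
  }

  # no-artifact data: output equals log2 input up to per-channel constants
  d0 <- synthetic_design(
    n_proteins = 100, sigma_within = 0.02, sigma_pool = 0,
    loading_sd_log2 = 0, batch_sd_log2 = 0,
    frac_decoy = 0, frac_contaminant = 0, frac_missing = 0, seed = 34
  )
  ds0 <- generate_dataset(d0)
  n0 <- normalize_pipeline(ds0$data, "irs")
  delta <- intensity_values(n0) - log2(intensity_values(ds0$data))
  expect_lt(max(apply(delta, 2, stats::sd)), 0.02)

  # both batch paths produce finite log2 matrices
  n_lin <- normalize_pipeline(ds0$data, "linear_model")
  expect_true(all(is.finite(intensity_values(n_lin))))
  expect_identical(tmt_scale(n_lin), "log2")
})

test_that("QC metrics match hand computations and degenerate cases", {
  # identical replicates: CV 0, Pearson 1
  v <- matrix(rep(c(10, 11, 12, 13), 4), 4, 4)
  m <- toy_matrix(v, c("MC", "MC", "FC", "FC"), scale = "log2")
  q <- qc_report(m)
  expect_equal(q$cv$mean_cv, c(0, 0))
  expect_true(all(abs(q$correlation - 1) < 1e-12))

  # group values {90, 110}: CV = 14.142% with sample sd
  v2 <- log2(matrix(c(90, 110, 90, 110), 1))
  m2 <- toy_matrix(v2, c("MC", "MC", "FC", "FC"), scale = "log2")
  q2 <- qc_report(m2)
  expect_equal(q2$cv$mean_cv, c(14.142, 14.142), tolerance = 1e-4)

  # duplicated sample column: identical PCA scores
  set.seed(3)
  v3 <- matrix(stats::rnorm(30 * 4, 20, 1), 30, 4)
  v3[, 2] <- v3[, 1]
  m3 <- toy_matrix(v3, c("MC", "MC", "FC", "FC"), scale = "log2")
  q3 <- qc_report(m3)
  expect_equal(
    unlist(q3$pca[1, c("PC1", "PC2")]),
    unlist(q3$pca[2, c("PC1", "PC2")])
  )
  # variance fractions are a valid non-increasing partition
  expect_true(all(diff(q3$var_explained) <= 1e-12))
  expect_lte(sum(q3$var_explained), 1 + 1e-9)

  # single-replicate group warns and is skipped
  m4 <- toy_matrix(v3[, 1:3], c("MC", "MC", "FC"), scale = "log2")
  expect_warning(q4 <- qc_report(m4), "single replicate")
  expect_identical(q4$cv$group, "MC")
})
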
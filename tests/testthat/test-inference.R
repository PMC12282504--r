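# Inference: Procrustes alignment, permutation test, bootstrap, CV.

test_that("procrustes_align undoes sign flips and column swaps", {
  set.seed(80)
  M <- qr.Q(qr(matrix(rnorm(36), 6, 6)))[, 1:3]
  flipped <- M %*% diag(c(-1, 1, -1))
  expect_equal(procrustes_align(M, flipped), M, tolerance = 1e-10,
               ignore_attr = TRUE)
  swapped <- M[, c(2, 1, 3)]
  expect_equal(procrustes_align(M, swapped), M, tolerance = 1e-10,
               ignore_attr = TRUE)

  # alignment never increases Frobenius distance; rotation stays orthogonal
  for (rep in 1:20) {
    A <- qr.Q(qr(matrix(rnorm(36), 6, 6)))[, 1:3]
    B <- qr.Q(qr(matrix(rnorm(36), 6, 6)))[, 1:3]
    al <- procrustes_align(A, B)
    Q <- attr(al, "rotation")
    expect_equal(crossprod(Q), diag(3), tolerance = 1e-10, ignore_attr = TRUE)
    expect_lte(norm(A - al, "F"), norm(A - B, "F") + 1e-12)
  }
  expect_error(procrustes_align(M, M[1:4, ]), "identical shapes")
})

test_that("permutation test is exact for strong signal and never returns 0", {
  ds <- ed_subset(generate_dataset(small_spec(seed = 4, effect_brain = 3,
                                              effect_behavior = 3,
                                              noise_sd = 0.3)))
  cfg <- analysis_config(n_permutations = 99, seed = 6)
  pt <- permutation_test(ds, cfg)
  expect_equal(pt$pvalues[1], 1 / 100)
  expect_true(all(pt$pvalues > 0))
  expect_equal(dim(pt$perm_s), c(99L, 8L))

  # identical config => identical result (one seeded RNG stream)
  pt2 <- permutation_test(ds, cfg)
  expect_identical(pt$perm_s, pt2$perm_s)

  # the Procrustes-rotated variant runs and also finds the planted LV
  pt3 <- permutation_test(ds, cfg, align = "procrustes")
  expect_equal(pt3$pvalues[1], 1 / 100)
})

test_that("permutation p-values are near-uniform under the null", {
  # scaled-down calibration (the full 200-replicate version runs in the
  # acceptance suite): 60 null replicates, 99 permutations each
  pvals <- sapply(1:60, function(s) {
    ds <- ed_subset(generate_null_dataset(small_spec(seed = 900 + s)))
    permutation_test(ds, analysis_config(n_permutations = 99, seed = s))$pvalues[1]
  })
  expect_gte(mean(pvals < 0.05), 0.0)
  expect_lte(mean(pvals < 0.05), 0.15)
  expect_gt(mean(pvals), 0.35)  # mean of U(0,1) is 0.5; wide MC margin
})

test_that("bootstrap ratios equal weight / two-pass SE over stored draws", {
  ds <- ed_subset(generate_dataset(small_spec(seed = 12, effect_brain = 1.5,
                                              effect_behavior = 1.5)))
  dec <- decompose_ds(ds)
  cfg <- tiny_config(seed = 3)
  bt <- bootstrap_analysis(ds, dec, cfg, store_draws = TRUE)
  # independent two-pass variance oracle on the stored aligned draws
  se_oracle <- apply(bt$draws$u, c(2, 3), sd)
  expect_equal(unname(bt$bootstrap_se_brain), se_oracle, tolerance = 1e-10)
  expect_equal(unname(bt$bootstrap_ratios_brain),
               unname(dec$u) / se_oracle, tolerance = 1e-10)
  # determinism
  bt2 <- bootstrap_analysis(ds, dec, cfg)
  expect_identical(bt$bootstrap_ratios_brain, bt2$bootstrap_ratios_brain)
})

test_that("bootstrap flags planted features and clears pure-noise loadings", {
  # near-noiseless planted signal: SEs collapse, planted |BSR| clears 1.96
  ds <- generate_dataset(synthetic_spec(n_edr = 30, n_edbp = 15, n_hc = 5,
                                        p = 6, q = 5, sparsity = 1,
                                        effect_brain = 2, effect_behavior = 2,
                                        noise_sd = 0.05, seed = 21))
  ed <- ed_subset(ds)
  dec <- decompose_ds(ed)
  bt <- bootstrap_analysis(ed, dec, tiny_config(seed = 4))
  expect_lt(max(bt$bootstrap_se_brain[, 1]), 0.05)
  expect_true(all(abs(bt$bootstrap_ratios_brain[, 1]) > 1.96))

  # null behavior columns: loading CI crosses zero most of the time
  # (scaled-down: 8 replicates x off-support columns; spec states >= 80%)
  cross <- unlist(lapply(1:8, function(s) {
    ds <- generate_dataset(small_spec(seed = 40 + s, effect_brain = 1.5,
                                      effect_behavior = 1.5))
    ed <- ed_subset(ds)
    dec <- decompose_ds(ed)
    bt <- bootstrap_analysis(ed, dec, tiny_config(seed = s), ci_lvs = 1)
    off <- setdiff(seq_len(ncol(ed$behavior)),
                   attr(ds, "ground_truth")$support_behavior[[1]])
    ci <- bt$loading_ci$LV1
    beh <- ci[ci$block == "behavior", ]
    !beh$reliable[off]
  }))
  expect_gte(mean(cross), 0.8)
})

test_that("cross-validation is perfect on noiseless rank-1 data", {
  ds <- ed_subset(generate_dataset(noiseless_spec(seed = 2)))
  cfg <- analysis_config(n_cv_splits = 10, n_cv_null = 0, seed = 5,
                         age_correct = FALSE)
  cv <- cross_validate(ds, cfg, 1)
  expect_true(all(cv$split_rs > 1 - 1e-8))
  expect_equal(cv$mean_r, 1, tolerance = 1e-8)
  expect_length(cv$split_rs, 10)
  # determinism
  cv2 <- cross_validate(ds, cfg, 1)
  expect_identical(cv$split_rs, cv2$split_rs)
})

test_that("out-of-sample r shrinks relative to in-sample r on noisy data", {
  shrunk <- sapply(1:6, function(s) {
    ds <- ed_subset(generate_dataset(small_spec(seed = 60 + s,
                                                effect_brain = 1.5,
                                                effect_behavior = 1.5)))
    dec <- decompose_ds(ds)
    r_in <- score_correlation(dec$brain_scores[, 1], dec$behavior_scores[, 1])$r
    cv <- cross_validate(ds, analysis_config(n_cv_splits = 25, n_cv_null = 0,
                                             seed = s))
    cv$mean_r <= r_in
  })
  expect_true(all(shrunk))
})

test_that("the CV permutation p-value detects signal and respects add-one", {
  ds <- ed_subset(generate_dataset(small_spec(seed = 13, effect_brain = 2.5,
                                              effect_behavior = 2.5,
                                              noise_sd = 0.5)))
  cfg <- analysis_config(n_cv_splits = 8, n_cv_null = 19, seed = 7)
  cv <- cross_validate(ds, cfg, 1)
  expect_equal(cv$pvalue, 1 / 20)
  expect_gt(cv$mean_r, 0.8)
})

test_that("cross_validate rejects too-small test splits", {
  ds <- ed_subset(generate_dataset(small_spec(seed = 1)))
  small <- subset_subjects(ds, 1:6)
  expect_error(cross_validate(small, analysis_config(n_cv_splits = 2,
                                                     train_fraction = 0.75,
                                                     n_cv_null = 0, seed = 1)),
               "at least 3")
})
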
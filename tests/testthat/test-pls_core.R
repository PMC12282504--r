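# Core decomposition: SVD of the cross-correlation, covariance explained,
# score projection, loadings.

test_that("pls_decompose handles exact low-rank structure", {
  # orthogonal z-scored columns give R = I2: equal singular values
  Zx <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1)) /
    apply(cbind(c(1, 1, -1, -1), c(1, -1, 1, -1)), 2, sd)
  cc <- cross_correlation(Zx, Zx)
  dec <- pls_decompose(cc, Zx, Zx)
  expect_equal(dec$s, c(1, 1), tolerance = 1e-12)
  expect_equal(dec$covexp, c(0.5, 0.5), tolerance = 1e-12)

  # planted exact rank-1 R = s * u v^T
  set.seed(50)
  u <- rnorm(6); u <- u / sqrt(sum(u^2))
  v <- rnorm(4); v <- v / sqrt(sum(v^2))
  R1 <- 3 * u %*% t(v)
  dec1 <- pls_decompose(R1, matrix(rnorm(60), 10, 6), matrix(rnorm(40), 10, 4))
  expect_equal(dec1$s[1], 3, tolerance = 1e-10)
  expect_equal(dec1$covexp[1], 1, tolerance = 1e-10)
  expect_equal(abs(sum(dec1$u[, 1] * u)), 1, tolerance = 1e-10)
  expect_equal(abs(sum(dec1$v[, 1] * v)), 1, tolerance = 1e-10)

  expect_error(pls_decompose(matrix(0, 3, 2), matrix(rnorm(15), 5, 3),
                             matrix(rnorm(10), 5, 2)), "no covariance")
})

test_that("pls_decompose matches the eigen-decomposition oracle", {
  set.seed(60)
  for (rep in 1:5) {
    Zx <- zscore_columns(matrix(rnorm(120), 20, 6))$Z
    Zy <- zscore_columns(matrix(rnorm(80), 20, 4))$Z
    cc <- cross_correlation(Zx, Zy)
    dec <- pls_decompose(cc, Zx, Zy)
    # oracle: eigen-decomposition of R^T R gives v and s^2
    ev <- eigen(crossprod(cc$R), symmetric = TRUE)
    expect_equal(dec$s, sqrt(pmax(ev$values, 0)), tolerance = 1e-10)
    for (k in 1:4)
      expect_equal(abs(sum(dec$v[, k] * ev$vectors[, k])), 1, tolerance = 1e-8)
    # reconstruction invariant
    recon <- dec$u %*% (dec$s * t(dec$v))
    expect_lt(norm(recon - cc$R, "F"), 1e-10)
    # sign convention: dominant behavior loading positive
    for (k in 1:4) {
      ld <- dec$behavior_loadings[, k]
      expect_gt(ld[which.max(abs(ld))], 0)
    }
    # loadings equal an explicit per-column correlation loop
    for (k in 1:2) for (j in 1:6)
      expect_equal(dec$brain_loadings[j, k],
                   cor(Zx[, j], dec$brain_scores[, k]), tolerance = 1e-12)
  }
})

test_that("covariance_explained follows s^2 / sum(s^2)", {
  expect_equal(covariance_explained(c(2, 1, 1)), c(4, 1, 1) / 6)
  expect_equal(covariance_explained(c(5, 0, 0)), c(1, 0, 0))
  expect_error(covariance_explained(c(0, 0)), "zero")
  expect_error(covariance_explained(c(-1, 2)), "non-negative")
})

test_that("planted-signal covariance explained decays with noise", {
  cov1 <- sapply(c(0.3, 1, 3), function(sig) {
    ds <- generate_dataset(small_spec(seed = 77, noise_sd = sig,
                                      effect_brain = 1.5, effect_behavior = 1.5))
    decompose_ds(ed_subset(ds))$covexp[1]
  })
  expect_true(all(diff(cov1) < 0))
})

test_that("project_scores reproduces training scores and hand dot products", {
  ds <- ed_subset(generate_dataset(small_spec(seed = 8)))
  model <- fit_preprocess(ds)
  Z <- apply_preprocess(model, ds)
  dec <- pls_decompose(cross_correlation(Z$Zx, Z$Zy), Z$Zx, Z$Zy)
  pr <- project_scores(Z$Zx, Z$Zy, dec, 2)
  expect_equal(pr$brain_scores, unname(dec$brain_scores[, 2]))
  expect_equal(pr$behavior_scores, unname(dec$behavior_scores[, 2]))

  one <- project_scores(Z$Zx[3, , drop = FALSE], Z$Zy[3, , drop = FALSE], dec, 1)
  expect_equal(one$brain_scores, sum(Z$Zx[3, ] * dec$u[, 1]), tolerance = 1e-12)
  expect_equal(one$behavior_scores, sum(Z$Zy[3, ] * dec$v[, 1]), tolerance = 1e-12)

  expect_error(project_scores(Z$Zx[, 1:3], Z$Zy, dec, 1), "column counts")
  expect_error(project_scores(Z$Zx, Z$Zy, dec, 99), "out of range")
})

test_that("score_correlation matches the textbook formula", {
  x <- rnorm(10)
  expect_equal(score_correlation(x, x)$r, 1)
  expect_equal(score_correlation(x, -x)$r, -1)
  set.seed(70)
  y <- rnorm(10)
  sc <- score_correlation(x, y)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(sc$r, r_manual, tolerance = 1e-12)
  t_manual <- r_manual * sqrt(8 / (1 - r_manual^2))
  expect_equal(sc$p, 2 * pt(-abs(t_manual), 8), tolerance = 1e-12)
  expect_error(score_correlation(rep(1, 5), rnorm(5)), "zero variance")
})
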
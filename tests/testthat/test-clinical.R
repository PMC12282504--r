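# Clinical statistics: Welch t, chi-square, subtype contrasts, prospective
# partial correlations, descriptive tables.

test_that("welch_t reproduces published summary statistics and the oracle", {
  # harm avoidance row of the cohort descriptives table
  w <- welch_t(25.04, 6.29, 91, 14.04, 7.55, 48)
  expect_equal(round(w$t, 2), 8.64)

  expect_equal(welch_t(5, 2, 10, 5, 2, 10)$t, 0)
  expect_error(welch_t(1, 0, 5, 2, 0, 5), "both group variances")
  expect_error(welch_t(1, 1, 1, 2, 1, 5), "n >= 2")

  set.seed(90)
  x <- rnorm(8); y <- rnorm(8, 1)
  res <- welch_test(x, y)
  oracle <- t.test(x, y, var.equal = FALSE)
  expect_equal(res$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$df, unname(oracle$parameter), tolerance = 1e-12)
  expect_equal(res$p, oracle$p.value, tolerance = 1e-12)
  # antisymmetry under group swap
  expect_equal(res$t, -welch_test(y, x)$t, tolerance = 1e-12)
})

test_that("chi_square_independence matches the expected-counts oracle", {
  expect_equal(chi_square_independence(matrix(10, 2, 2))$chisq, 0)

  eth <- as.matrix(read.csv(system.file("extdata", "cohort_ethnicity_counts.csv",
                                        package = "bbpls"), row.names = 1))
  expect_equal(round(chi_square_independence(eth)$chisq, 2), 0.68)

  set.seed(91)
  tab <- matrix(rpois(9, 12), 3, 3)
  res <- chi_square_independence(tab)
  oracle <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(res$chisq, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$p, oracle$p.value, tolerance = 1e-12)
  # invariance under row/column permutation
  expect_equal(chi_square_independence(tab[c(2, 1, 3), c(3, 1, 2)])$chisq,
               res$chisq, tolerance = 1e-12)
  expect_error(chi_square_independence(matrix(c(0, 0, 3, 4), 2, 2)), "zero row")
  expect_error(chi_square_independence(matrix(c(1.5, 2, 3, 4), 2, 2)),
               "non-negative integers")
})

test_that("compare_subtypes reports both score types and is null-calibrated", {
  ds <- ed_subset(generate_dataset(small_spec(seed = 14)))
  dec <- decompose_ds(ds)
  tab <- compare_subtypes(ds, dec, 1)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$score_type, c("brain", "behavior"))
  expect_equal(tab$n_EDr + tab$n_EDbp, rep(sum(ds$group == "ED"), 2))
  # two LVs -> four tests
  expect_equal(nrow(rbind(compare_subtypes(ds, dec, 1),
                          compare_subtypes(ds, dec, 2))), 4)

  # delta = 0: behavior-score subtype test is a null test
  # (scaled-down: 20 replicates; spec states p > 0.05 in >= 90% of 50)
  null_p <- sapply(1:20, function(s) {
    ds <- ed_subset(generate_dataset(small_spec(seed = 300 + s,
                                                subtype_shift = 0,
                                                effect_brain = 1.5,
                                                effect_behavior = 1.5)))
    compare_subtypes(ds, decompose_ds(ds), 1)$p[2]
  })
  expect_gte(mean(null_p > 0.05), 0.8)

  # delta = 1 SD on the latent: detected most of the time
  # (scaled-down: 15 replicates; spec states >= 80% of 50)
  pow_p <- sapply(1:15, function(s) {
    ds <- ed_subset(generate_dataset(small_spec(seed = 500 + s,
                                                subtype_shift = 1,
                                                effect_brain = 1.5,
                                                effect_behavior = 1.5)))
    compare_subtypes(ds, decompose_ds(ds), 1)$p[2]
  })
  expect_gte(mean(pow_p < 0.05), 0.6)

  hc <- subset_subjects(generate_dataset(small_spec(seed = 14)),
                        rep(c(FALSE, TRUE), c(50, 10)))
  expect_error(compare_subtypes(hc, dec, 1), "per subtype")
})

test_that("partial correlation matches the residual oracle", {
  # covariate orthogonal (by construction) to both variables: partial = simple
  set.seed(92)
  n <- 40
  z <- rnorm(n)
  x <- rnorm(n); y <- rnorm(n)
  x <- lm(x ~ z)$residuals  # exactly orthogonal to z
  y <- lm(y ~ z)$residuals
  pc <- bbpls:::partial_cor(x, y, z)
  expect_equal(pc$r, cor(x, y), tolerance = 1e-10)

  # 6-subject worked example vs explicit two-regression oracle
  x6 <- c(1.2, 0.4, -0.8, 2.1, -1.3, 0.6)
  y6 <- c(0.3, 1.1, -0.2, 1.9, -0.7, 0.2)
  z6 <- c(0.5, -0.3, 0.8, 1.2, -1.1, 0.1)
  rx <- residuals(lm(x6 ~ z6)); ry <- residuals(lm(y6 ~ z6))
  pc6 <- bbpls:::partial_cor(x6, y6, z6)
  expect_equal(pc6$r, cor(rx, ry), tolerance = 1e-12)
  # cross-check against the first-order partial correlation formula
  r_xy <- cor(x6, y6); r_xz <- cor(x6, z6); r_yz <- cor(y6, z6)
  expect_equal(pc6$r, (r_xy - r_xz * r_yz) /
                 sqrt((1 - r_xz^2) * (1 - r_yz^2)), tolerance = 1e-12)
})

test_that("prospective_association is null when follow-up ignores the latent", {
  # gamma = 0: follow-up = rho * baseline + noise only
  rs <- sapply(1:50, function(s) {
    ds <- ed_subset(generate_dataset(small_spec(seed = 700 + s,
                                                followup_coupling = 0)))
    prospective_association(ds, decompose_ds(ds), 1, "brain")$r
  })
  expect_lt(abs(mean(rs)), 0.05)

  ds <- ed_subset(generate_dataset(small_spec(seed = 15)))
  ds$followup_severity[-(1:5)] <- NA
  expect_error(prospective_association(ds, decompose_ds(ds), 1), ">= 10")
})

test_that("group_descriptives builds a per-variable table with Welch tests", {
  ds <- generate_dataset(small_spec(seed = 16))
  vars <- c("age", ds$behavior_names[1:4])
  tab <- group_descriptives(ds, vars)
  expect_equal(nrow(tab), length(vars))
  expect_true(all(tab$test == "welch_t"))
  # spot-check one row against welch_test on the raw columns
  v <- ds$behavior_names[2]
  ref <- welch_test(ds$behavior[ds$group == "ED", v],
                    ds$behavior[ds$group == "HC", v])
  expect_equal(tab$statistic[tab$variable == v], ref$t, tolerance = 1e-12)

  # variable observed only in ED: flagged, untested
  ds$behavior[ds$group == "HC", 1] <- NA
  tab2 <- group_descriptives(ds, ds$behavior_names[1])
  expect_true(is.na(tab2$statistic))
  expect_match(tab2$note, "one group")
  expect_error(group_descriptives(ds, "nonexistent"), "unknown variable")
})
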
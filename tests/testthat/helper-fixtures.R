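# Fixtures are built in code at test time; nothing binary is shipped.

# A small cohort with planted signal, subtypes and follow-up: fast enough to
# regenerate freely inside tests.
small_spec <- function(seed = 1L, ...) {
  synthetic_spec(n_edr = 40L, n_edbp = 20L, n_hc = 10L, p = 10L, q = 8L,
                 seed = seed, ...)
}

# Noise-free, full-support, rank-1 world: every preprocessing and projection
# step is exactly deterministic, so identifiability claims can be asserted
# to numerical precision. (Sparse supports would leave zero-variance noise
# columns at sigma = 0.) No age effect is planted and analyses of this world
# disable age correction: the train-fitted slope on a finite sample picks up
# the chance z-age correlation, which would pollute exact rank-1 structure
# in held-out projections.
noiseless_spec <- function(seed = 1L, noise_sd = 0, ...) {
  synthetic_spec(n_edr = 20L, n_edbp = 10L, n_hc = 5L, p = 6L, q = 5L,
                 noise_sd = noise_sd, sparsity = 1, effect_brain = 2,
                 effect_behavior = 2, age_slope = 0, seed = seed, ...)
}

# Tiny analysis config for tests that only need the machinery to run.
tiny_config <- function(seed = 1L, ...) {
  analysis_config(n_permutations = 99L, n_bootstraps = 60L, n_cv_splits = 10L,
                  n_cv_null = 0L, seed = seed, ...)
}

# Decompose a dataset the way the pipeline does (fit preprocessing on the
# given subjects, full-sample decomposition).
decompose_ds <- function(ds) {
  Z <- apply_preprocess(fit_preprocess(ds), ds)
  pls_decompose(cross_correlation(Z$Zx, Z$Zy), Z$Zx, Z$Zy)
}

ed_subset <- function(ds) subset_subjects(ds, ds$group == "ED")
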
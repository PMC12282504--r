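# Synthetic cohort generator with a planted low-rank cross-block covariance.
#
# The generated world mirrors the cohort the analysis targets: 91 adolescents
# with an eating disorder (61 restricting, 30 binge-purge), 48 healthy
# controls, 65 brain columns (35 white-matter tracts + 30 subcortical
# regions), 38 behavior measures across 5 domains, ages uniform on
# 13.1-18.2 years, and one-year follow-up severity for 72 of the 91 ED
# subjects. Per subject i and planted latent l:
#   z_il ~ Normal(delta * 1[EDbp], 1)
#   brain_i    = sum_l a_l z_il u_l + age_i * slope + E_i,  E ~ N(0, sigma^2)
#   behavior_i = sum_l b_l z_il v_l + F_i,                  F ~ N(0, sigma^2)
# with u_l, v_l fixed unit-norm sparse direction vectors (saved as ground
# truth). Baseline severity loads on the first latent; follow-up severity is
# rho * baseline + gamma * z_1 + noise.

ROI_NAMES_65 <- c(sprintf("tract_%02d", 1:35), sprintf("subcort_%02d", 1:30))

BEHAVIOR_MEASURES_38 <- data.frame(
  domain = c(rep("cognition", 6), rep("temperament", 14),
             rep("interoception", 8), rep("emotion", 2), rep("ed_symptoms", 8)),
  measure = c(
    "cognitive_flexibility", "cognitive_inhibition", "similarities",
    "matrix_reasoning", "vocabulary", "block_design",
    "self_transcendence", "cooperativeness", "self_directedness",
    "persistence", "reward_dependence", "harm_avoidance", "novelty_seeking",
    "inhibitory_control", "attentional_control", "activation_control",
    "effortful_control", "motivational_bias", "behavioral_inhibition",
    "reward_responsiveness",
    "trust", "body_listening", "self_regulation", "emotional_awareness",
    "attention_regulation", "not_worrying", "not_distracting", "noticing",
    "emotion_dysregulation", "alexithymia",
    "weight_concern", "shape_concern", "eating_concern", "restraint",
    "excessive_exercise", "restricting", "purging", "binge_eating"))

#' Specify a synthetic cohort
#'
#' Defaults encode the emulated study cohort (91 ED = 61 EDr + 30 EDbp,
#' 48 HC, 65 brain columns, 38 behavior measures, follow-up for 72/91) with
#' one planted latent variable whose effect scale gives an in-sample score
#' correlation near 0.5 at the default noise level.
#'
#' @param n_edr,n_edbp,n_hc group sizes (restricting / binge-purge / control).
#' @param p,q numbers of brain and behavior columns.
#' @param n_latent number of planted latent variables.
#' @param effect_brain,effect_behavior latent-to-block effect scales `a_l`,
#'   `b_l` (length `n_latent`, recycled).
#' @param noise_sd residual SD `sigma` for both blocks.
#' @param subtype_shift latent mean shift `delta` for EDbp subjects (SD units
#'   of the latent).
#' @param age_slope slope of every brain column on age (units per year).
#' @param followup_coupling coupling `gamma` of follow-up severity to the
#'   first latent.
#' @param baseline_autocorr autoregression `rho` of follow-up on baseline
#'   severity.
#' @param followup_fraction fraction of ED subjects with follow-up.
#' @param sparsity fraction of columns in each planted direction's support.
#' @param seed RNG seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_edr = 61L, n_edbp = 30L, n_hc = 48L,
                           p = 65L, q = 38L, n_latent = 1L,
                           effect_brain = 1, effect_behavior = 1,
                           noise_sd = 1, subtype_shift = 0.5,
                           age_slope = 0.05, followup_coupling = 0.3,
                           baseline_autocorr = 0.5,
                           followup_fraction = 72 / 91,
                           sparsity = 0.2, seed = 1L) {
  for (nm in c("n_edr", "n_edbp", "n_hc", "p", "q", "n_latent"))
    if (!is_count(get(nm))) stop_bbpls("%s must be a positive count", nm)
  if (noise_sd < 0) stop_bbpls("noise_sd must be >= 0")
  if (!(followup_fraction > 0 && followup_fraction <= 1))
    stop_bbpls("followup_fraction must lie in (0, 1]")
  if (n_latent * ceiling(sparsity * min(p, q)) > min(p, q))
    stop_bbpls("p or q too small for %d disjoint sparse supports", n_latent)
  structure(list(
    n_edr = as.integer(n_edr), n_edbp = as.integer(n_edbp),
    n_hc = as.integer(n_hc), p = as.integer(p), q = as.integer(q),
    n_latent = as.integer(n_latent),
    effect_brain = rep_len(effect_brain, n_latent),
    effect_behavior = rep_len(effect_behavior, n_latent),
    noise_sd = noise_sd, subtype_shift = subtype_shift,
    age_slope = age_slope, followup_coupling = followup_coupling,
    baseline_autocorr = baseline_autocorr,
    followup_fraction = followup_fraction, sparsity = sparsity,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# Disjoint sparse unit-norm direction vectors: equal-magnitude positive
# entries on a randomly chosen support of ceiling(sparsity * d) columns.
sparse_directions <- function(d, n_latent, sparsity) {
  m <- ceiling(sparsity * d)
  pool <- sample.int(d)
  D <- matrix(0, d, n_latent)
  for (l in seq_len(n_latent))
    D[pool[(l - 1) * m + seq_len(m)], l] <- 1 / sqrt(m)
  D
}

#' Generate a synthetic study dataset
#'
#' See the module comment above for the generative model. The ground truth
#' (direction vectors, supports, latent scores, spec) is attached as
#' attribute `"ground_truth"` for recovery tests.
#'
#' @param spec a [synthetic_spec()].
#' @return a `study_dataset` with attribute `ground_truth`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  set.seed(substream_seed(spec$seed, "synthesis"))
  n_ed <- spec$n_edr + spec$n_edbp
  n <- n_ed + spec$n_hc
  group <- c(rep("ED", n_ed), rep("HC", spec$n_hc))
  subtype <- c(rep("EDr", spec$n_edr), rep("EDbp", spec$n_edbp),
               rep(NA_character_, spec$n_hc))
  ids <- sprintf("S%04d", seq_len(n))

  U <- sparse_directions(spec$p, spec$n_latent, spec$sparsity)
  V <- sparse_directions(spec$q, spec$n_latent, spec$sparsity)
  z <- matrix(rnorm(n * spec$n_latent), n, spec$n_latent)
  z[subtype %in% "EDbp", ] <- z[subtype %in% "EDbp", , drop = FALSE] +
    spec$subtype_shift

  age <- runif(n, 13.1, 18.2)
  X <- z %*% (spec$effect_brain * t(U)) + outer(age, rep(spec$age_slope, spec$p)) +
    matrix(rnorm(n * spec$p, sd = spec$noise_sd), n, spec$p)
  Y <- z %*% (spec$effect_behavior * t(V)) +
    matrix(rnorm(n * spec$q, sd = spec$noise_sd), n, spec$q)

  colnames(X) <- if (spec$p == 65L) ROI_NAMES_65 else sprintf("roi_%02d", seq_len(spec$p))
  if (spec$q == 38L) {
    colnames(Y) <- BEHAVIOR_MEASURES_38$measure
    domains <- BEHAVIOR_MEASURES_38$domain
  } else {
    colnames(Y) <- sprintf("beh_%02d", seq_len(spec$q))
    domains <- rep(BEHAVIOR_DOMAINS, length.out = spec$q)
  }

  # Severity on the published scale: ED baseline centered at 2.94 (SD ~1.37)
  # loading on the first latent; HC near-zero severity; follow-up for a
  # random ED subset of size round(followup_fraction * n_ed).
  baseline <- numeric(n)
  ed_idx <- which(group == "ED")
  baseline[ed_idx] <- 2.94 + 0.8 * z[ed_idx, 1] + rnorm(n_ed, sd = 1.1)
  baseline[-ed_idx] <- abs(rnorm(spec$n_hc, 0.07, 0.085))
  followup <- rep(NA_real_, n)
  fu_idx <- sort(sample(ed_idx, round(spec$followup_fraction * n_ed)))
  followup[fu_idx] <- 1.54 - spec$baseline_autocorr * 2.94 +
    spec$baseline_autocorr * baseline[fu_idx] +
    spec$followup_coupling * z[fu_idx, 1] +
    rnorm(length(fu_idx), sd = 0.9)

  ds <- study_dataset(ids, X, Y, age, group, subtype, baseline, followup,
                      domains)
  attr(ds, "ground_truth") <- list(
    u = U, v = V,
    effect_brain = spec$effect_brain, effect_behavior = spec$effect_behavior,
    support_brain = apply(U != 0, 2L, which, simplify = FALSE),
    support_behavior = apply(V != 0, 2L, which, simplify = FALSE),
    latent = z, spec = spec)
  ds
}

#' Generate a null dataset (independent blocks)
#'
#' Same marginal structure as [generate_dataset()] but with all effect
#' scales set to zero, so the brain and behavior blocks are independent.
#'
#' @param spec a [synthetic_spec()].
#' @return a `study_dataset` with attribute `ground_truth`.
#' @export
generate_null_dataset <- function(spec = synthetic_spec()) {
  spec$effect_brain[] <- 0
  spec$effect_behavior[] <- 0
  generate_dataset(spec)
}

#' Recovery metrics against the planted ground truth
#'
#' Absolute cosine similarity between planted and estimated direction
#' vectors, the estimated covariance-explained fractions, and (when a
#' bootstrap result is supplied) true/false-positive rates of the
#' `|bootstrap ratio| > threshold` flags against the planted brain support.
#' On null data (zero effect scales) the rates are `NA`.
#'
#' @param truth the `ground_truth` attribute of a generated dataset.
#' @param dec a `pls_decomposition` estimated from that dataset.
#' @param inference optional `bbpls_bootstrap` for the same decomposition.
#' @return data.frame with one row per planted latent variable.
#' @export
recovery_report <- function(truth, dec, inference = NULL) {
  L <- ncol(truth$u)
  if (L > length(dec$s))
    stop_bbpls("decomposition has fewer components (%d) than planted (%d)",
               length(dec$s), L)
  cosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  rows <- lapply(seq_len(L), function(l) {
    null_lv <- truth$effect_brain[l] == 0 || truth$effect_behavior[l] == 0
    tpr <- fpr <- NA_real_
    if (!is.null(inference) && !null_lv) {
      flags <- abs(inference$bootstrap_ratios_brain[, l]) > inference$bsr_threshold
      on <- truth$support_brain[[l]]
      tpr <- mean(flags[on])
      fpr <- if (length(on) < length(flags)) mean(flags[-on]) else NA_real_
    }
    data.frame(lv = l,
               cosine_u = if (null_lv) NA_real_ else cosine(truth$u[, l], dec$u[, l]),
               cosine_v = if (null_lv) NA_real_ else cosine(truth$v[, l], dec$v[, l]),
               covexp = dec$covexp[l], tpr_brain = tpr, fpr_brain = fpr)
  })
  do.call(rbind, rows)
}
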
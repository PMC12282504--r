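# Clinical applications of the LV scores, plus cohort descriptive statistics
# (two-group tests of the kind reported in a demographic "Table 1").

#' Welch's unequal-variance t-test from summary statistics
#'
#' `t = (mean1 - mean2) / sqrt(sd1^2/n1 + sd2^2/n2)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value. Use
#' [welch_test()] for raw vectors.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (sd1 < 0 || sd2 < 0) stop_bbpls("standard deviations must be >= 0")
  if (sd1 == 0 && sd2 == 0) stop_bbpls("both group variances are zero")
  if (n1 < 2 || n2 < 2) stop_bbpls("need n >= 2 per group")
  se1 <- sd1^2 / n1; se2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(se1 + se2)
  df <- (se1 + se2)^2 / (se1^2 / (n1 - 1) + se2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Welch's t-test on two raw vectors
#'
#' @param x,y numeric vectors (NA removed).
#' @return list with `t`, `df`, `p`, group means and SDs.
#' @export
welch_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  res <- welch_t(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
  c(res, list(mean1 = mean(x), sd1 = sd(x), n1 = length(x),
              mean2 = mean(y), sd2 = sd(y), n2 = length(y)))
}

#' Pearson chi-square test of independence
#'
#' Without continuity correction; `df = (r - 1)(c - 1)`. Expected counts are
#' returned for inspection.
#'
#' @param tab r x c matrix of non-negative counts.
#' @return list with `chisq`, `df`, `p`, `expected`.
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != floor(tab)))
    stop_bbpls("counts must be non-negative integers")
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop_bbpls("need at least a 2 x 2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_bbpls("zero row or column sum")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chisq <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE),
       expected = expected)
}

#' Compare LV scores between diagnostic subtypes
#'
#' Welch t-tests of the restricting (EDr) vs binge-purge (EDbp) subtypes on
#' the brain and behavior scores of one latent variable (difference taken as
#' EDr minus EDbp, so higher EDbp scores give negative t), plus the
#' within-subtype brain-behavior score correlations.
#'
#' @param ds the ED `study_dataset` the decomposition was fit on.
#' @param dec the fitted `pls_decomposition` (score rows aligned with `ds`).
#' @param lv latent-variable index.
#' @return data.frame with one row per score type (brain, behavior).
#' @export
compare_subtypes <- function(ds, dec, lv = 1L) {
  is_r <- !is.na(ds$subtype) & ds$subtype == "EDr"
  is_bp <- !is.na(ds$subtype) & ds$subtype == "EDbp"
  if (sum(is_r) < 3L || sum(is_bp) < 3L)
    stop_bbpls("need at least 3 subjects per subtype (EDr %d, EDbp %d)",
               sum(is_r), sum(is_bp))
  one <- function(score_type) {
    sc <- if (score_type == "brain") dec$brain_scores[, lv] else dec$behavior_scores[, lv]
    tt <- welch_test(sc[is_r], sc[is_bp])
    within <- function(ix) score_correlation(dec$brain_scores[ix, lv],
                                             dec$behavior_scores[ix, lv])
    wr <- within(is_r); wbp <- within(is_bp)
    data.frame(lv = lv, score_type = score_type,
               mean_EDr = tt$mean1, sd_EDr = tt$sd1, n_EDr = tt$n1,
               mean_EDbp = tt$mean2, sd_EDbp = tt$sd2, n_EDbp = tt$n2,
               t = tt$t, df = tt$df, p = tt$p,
               r_within_EDr = wr$r, p_within_EDr = wr$p,
               r_within_EDbp = wbp$r, p_within_EDbp = wbp$p)
  }
  out <- rbind(one("brain"), one("behavior"))
  class(out) <- c("subtype_comparison", class(out))
  out
}

# Partial correlation of x and y controlling for z, by double
# residualization; identical to the first-order partial correlation formula.
partial_cor <- function(x, y, z) {
  rx <- lm(x ~ z)$residuals
  ry <- lm(y ~ z)$residuals
  r <- cor(rx, ry)
  n <- length(x)
  tstat <- r * sqrt((n - 3) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), n - 3), n = n)
}

#' Prospective association of baseline LV scores with follow-up severity
#'
#' Partial Pearson correlation between a baseline latent-variable score and
#' the follow-up severity score, controlling for baseline severity
#' (residual-on-residual method; p from the t distribution with n - 3 df).
#' Only subjects with non-missing baseline and follow-up severity enter.
#'
#' @param ds the ED `study_dataset`.
#' @param dec the fitted `pls_decomposition`.
#' @param lv latent-variable index.
#' @param score_type `"brain"` or `"behavior"`.
#' @return list with `r`, `p`, `n`.
#' @export
prospective_association <- function(ds, dec, lv = 1L,
                                    score_type = c("brain", "behavior")) {
  score_type <- match.arg(score_type)
  keep <- !is.na(ds$baseline_severity) & !is.na(ds$followup_severity)
  if (sum(keep) < 10L)
    stop_bbpls("only %d subjects have baseline and follow-up severity; need >= 10",
               sum(keep))
  sc <- if (score_type == "brain") dec$brain_scores[keep, lv] else
    dec$behavior_scores[keep, lv]
  partial_cor(sc, ds$followup_severity[keep], ds$baseline_severity[keep])
}

#' Cohort descriptive statistics with two-group tests
#'
#' Builds a demographics-style table: for numeric variables (behavior columns
#' or `"age"`) an ED vs HC Welch t-test with per-group mean (SD); for factor
#' metadata variables (`"subtype"` is not meaningful here, but e.g. custom
#' factors) a chi-square test of independence. Variables observed in only one
#' group are flagged and left untested.
#'
#' @param ds a `study_dataset` containing both groups.
#' @param variables character vector of behavior column names and/or `"age"`.
#' @return data.frame of class `group_stats_table`, one row per variable.
#' @export
group_descriptives <- function(ds, variables) {
  ed <- ds$group == "ED"; hc <- ds$group == "HC"
  rows <- lapply(variables, function(v) {
    x <- if (identical(v, "age")) ds$age else {
      if (!v %in% ds$behavior_names) stop_bbpls("unknown variable '%s'", v)
      ds$behavior[, v]
    }
    xe <- x[ed & !is.na(x)]; xh <- x[hc & !is.na(x)]
    base <- data.frame(variable = v,
                       mean_ED = mean(xe), sd_ED = sd(xe), n_ED = length(xe),
                       mean_HC = if (length(xh)) mean(xh) else NA_real_,
                       sd_HC = if (length(xh) > 1) sd(xh) else NA_real_,
                       n_HC = length(xh))
    if (length(xe) >= 2 && length(xh) >= 2) {
      tt <- welch_t(mean(xe), sd(xe), length(xe), mean(xh), sd(xh), length(xh))
      cbind(base, data.frame(test = "welch_t", statistic = tt$t, df = tt$df,
                             p = tt$p, note = ""))
    } else {
      cbind(base, data.frame(test = NA_character_, statistic = NA_real_,
                             df = NA_real_, p = NA_real_,
                             note = "observed in one group only; no test"))
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("group_stats_table", class(out))
  out
}
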
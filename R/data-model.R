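# Shared data model: study dataset container, analysis configuration, and
# delimited-text input/output. The fixed dialect is comma-separated, decimal
# point, UTF-8; subject_id is always the first column.

BEHAVIOR_DOMAINS <- c("cognition", "temperament", "interoception",
                      "emotion", "ed_symptoms")

#' Construct a study dataset
#'
#' Bundles an aligned brain matrix (subjects x ROIs), behavior matrix
#' (subjects x measures), and subject metadata. All components share the same
#' subject ordering. Construction runs [validate_dataset()] and fails on any
#' hard invariant violation.
#'
#' @param subject_id character vector of unique subject identifiers.
#' @param brain numeric matrix, one column per region of interest
#'   (e.g. restricted normalized directional diffusion, unitless).
#' @param behavior numeric matrix, one column per behavioral measure
#'   (instrument units).
#' @param age numeric vector, years.
#' @param group factor or character, levels `ED` / `HC`.
#' @param subtype factor or character, levels `EDr` / `EDbp`; `NA` for HC.
#' @param baseline_severity,followup_severity EDE global scores (0-6 scale);
#'   `followup_severity` may be `NA` for subjects without follow-up.
#' @param behavior_domains optional character vector assigning each behavior
#'   column to one of `r toString(BEHAVIOR_DOMAINS)`.
#' @return an object of class `study_dataset`.
#' @export
study_dataset <- function(subject_id, brain, behavior, age, group,
                          subtype = NULL, baseline_severity = NULL,
                          followup_severity = NULL, behavior_domains = NULL) {
  ds <- new_study_dataset(subject_id, brain, behavior, age, group, subtype,
                          baseline_severity, followup_severity,
                          behavior_domains)
  v <- validate_dataset(ds)
  if (length(v$failures))
    stop_bbpls("invalid study_dataset: %s", paste(v$failures, collapse = "; "))
  ds
}

# Low-level constructor without validation (used by tests that corrupt fields).
new_study_dataset <- function(subject_id, brain, behavior, age, group,
                              subtype = NULL, baseline_severity = NULL,
                              followup_severity = NULL,
                              behavior_domains = NULL) {
  n <- length(subject_id)
  brain <- as.matrix(brain)
  behavior <- as.matrix(behavior)
  if (is.null(colnames(brain)))
    colnames(brain) <- paste0("roi_", seq_len(ncol(brain)))
  if (is.null(colnames(behavior)))
    colnames(behavior) <- paste0("beh_", seq_len(ncol(behavior)))
  structure(list(
    subject_id = as.character(subject_id),
    brain = brain,
    behavior = behavior,
    age = as.numeric(age),
    group = factor(as.character(group), levels = c("ED", "HC")),
    subtype = factor(as.character(subtype %||% rep(NA_character_, n)),
                     levels = c("EDr", "EDbp")),
    baseline_severity = as.numeric(baseline_severity %||% rep(NA_real_, n)),
    followup_severity = as.numeric(followup_severity %||% rep(NA_real_, n)),
    roi_names = colnames(brain),
    behavior_names = colnames(behavior),
    behavior_domains = as.character(behavior_domains %||%
                                      rep(NA_character_, ncol(behavior)))
  ), class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("study_dataset: %d subjects (%d ED / %d HC), %d ROIs, %d behavior measures\n",
              length(x$subject_id), sum(x$group == "ED", na.rm = TRUE),
              sum(x$group == "HC", na.rm = TRUE),
              ncol(x$brain), ncol(x$behavior)))
  n_fu <- sum(!is.na(x$followup_severity))
  if (n_fu) cat(sprintf("  follow-up severity available for %d subjects\n", n_fu))
  invisible(x)
}

#' @export
dim.study_dataset <- function(x) {
  c(n = length(x$subject_id), p = ncol(x$brain), q = ncol(x$behavior))
}

#' Subset a study dataset by subjects
#'
#' @param ds a `study_dataset`.
#' @param i logical or integer subject index.
#' @return a `study_dataset` restricted to the selected subjects.
#' @export
subset_subjects <- function(ds, i) {
  new_study_dataset(ds$subject_id[i], ds$brain[i, , drop = FALSE],
                    ds$behavior[i, , drop = FALSE], ds$age[i], ds$group[i],
                    ds$subtype[i], ds$baseline_severity[i],
                    ds$followup_severity[i], ds$behavior_domains)
}

#' Validate a study dataset
#'
#' Pure screening function: returns hard invariant violations (`failures`)
#' and data-quality `warnings` (zero-variance columns, per-column missingness,
#' high skewness) without mutating anything.
#'
#' @param ds a `study_dataset` (possibly malformed).
#' @return list with character vectors `failures` and `warnings`.
#' @export
validate_dataset <- function(ds) {
  failures <- character()
  warnings <- character()
  n <- length(ds$subject_id)
  if (nrow(ds$brain) != n || nrow(ds$behavior) != n ||
      length(ds$age) != n || length(ds$group) != n ||
      length(ds$subtype) != n)
    failures <- c(failures, "subject alignment violated: components differ in n")
  if (ncol(ds$brain) < 2L)
    failures <- c(failures, "brain block needs p >= 2 columns")
  if (ncol(ds$behavior) < 2L)
    failures <- c(failures, "behavior block needs q >= 2 columns")
  dup <- unique(ds$subject_id[duplicated(ds$subject_id)])
  if (length(dup))
    failures <- c(failures, paste0("duplicated subject_id: ",
                                   paste(dup, collapse = ", ")))
  if (any(!is.finite(ds$age)) || any(ds$age <= 0, na.rm = TRUE))
    failures <- c(failures, "age must be finite and > 0 for all subjects")
  bad_sub <- !is.na(ds$subtype) & !is.na(ds$group) & ds$group != "ED"
  if (any(bad_sub))
    failures <- c(failures, "subtype labels present outside the ED group")

  for (blk in c("brain", "behavior")) {
    X <- ds[[blk]]
    if (nrow(X) != n) next
    nmiss <- colSums(is.na(X))
    for (j in which(nmiss > 0))
      warnings <- c(warnings, sprintf("missing values in %s column %s (%d)",
                                      blk, colnames(X)[j], nmiss[j]))
    ok <- nmiss == 0L
    sds <- rep(NA_real_, ncol(X))
    sds[ok] <- apply(X[, ok, drop = FALSE], 2L, sd)
    for (j in which(!is.na(sds) & sds == 0))
      warnings <- c(warnings, sprintf("zero-variance column %s", colnames(X)[j]))
    if (nrow(X) >= 3) {
      sk <- rep(0, ncol(X)); sk[ok] <- col_skew(X[, ok, drop = FALSE])
      for (j in which(abs(sk) > 2))
        warnings <- c(warnings, sprintf("high skewness (|skew| = %.2f) in %s column %s",
                                        abs(sk[j]), blk, colnames(X)[j]))
    }
  }
  list(failures = failures, warnings = warnings)
}

#' Analysis configuration
#'
#' Collects the tunable parameters of the inference stages. Defaults follow
#' the published analysis where it states them (100 cross-validation splits
#' of 75% train / 25% test; bootstrap-ratio reliability threshold 1.96) and
#' conventional behavioral-PLS practice elsewhere (10,000 permutations,
#' 5,000 bootstrap resamples).
#'
#' @param n_permutations permutation count for singular-value significance.
#' @param n_bootstraps bootstrap resample count.
#' @param n_cv_splits number of random train/test splits.
#' @param train_fraction fraction of subjects in each training split.
#' @param alpha two-sided significance level.
#' @param bsr_threshold reliability threshold on |bootstrap ratio|.
#' @param seed master RNG seed; each stochastic stage uses an independent
#'   sub-stream derived from it.
#' @param n_cv_null permutation repetitions for the cross-validation p-value
#'   (0 skips that p-value).
#' @param stratify_cv stratify splits by subtype/group labels when present.
#' @param age_correct residualize the brain block on age during
#'   preprocessing (disable when inputs are already age-corrected upstream).
#' @param imaging_modality_label free-text label for the brain block.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(n_permutations = 10000L, n_bootstraps = 5000L,
                            n_cv_splits = 100L, train_fraction = 0.75,
                            alpha = 0.05, bsr_threshold = 1.96, seed = 1L,
                            n_cv_null = 500L, stratify_cv = TRUE,
                            age_correct = TRUE,
                            imaging_modality_label = "RND") {
  if (!is_count(n_permutations) || !is_count(n_bootstraps) || !is_count(n_cv_splits))
    stop_bbpls("n_permutations, n_bootstraps and n_cv_splits must be counts >= 1")
  if (!(train_fraction > 0 && train_fraction < 1))
    stop_bbpls("train_fraction must lie in (0, 1)")
  if (!(alpha > 0 && alpha < 1))
    stop_bbpls("alpha must lie in (0, 1)")
  structure(list(
    n_permutations = as.integer(n_permutations),
    n_bootstraps = as.integer(n_bootstraps),
    n_cv_splits = as.integer(n_cv_splits),
    train_fraction = train_fraction,
    alpha = alpha,
    bsr_threshold = bsr_threshold,
    seed = as.integer(seed),
    n_cv_null = as.integer(n_cv_null),
    stratify_cv = isTRUE(stratify_cv),
    age_correct = isTRUE(age_correct),
    imaging_modality_label = imaging_modality_label
  ), class = "analysis_config")
}

#' Read an analysis configuration from a JSON file
#'
#' The config file is JSON (a strict subset of YAML 1.2); unknown keys are an
#' error, absent keys take the [analysis_config()] defaults.
#'
#' @param path file path.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop_bbpls("unknown config keys: %s", paste(unknown, collapse = ", "))
  do.call(analysis_config, vals)
}

# ---- reading -----------------------------------------------------------------

read_numeric_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character",
                 fileEncoding = "UTF-8")
  if (ncol(df) < 2L || names(df)[1] != "subject_id")
    stop_bbpls("%s: first column must be 'subject_id'", path)
  ids <- df[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_bbpls("%s: duplicated subject_id: %s", path, paste(dup, collapse = ", "))
  M <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
              dimnames = list(ids, names(df)[-1]))
  for (j in seq_len(ncol(M))) {
    raw <- df[[j + 1L]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !(is.na(raw) | raw %in% c("", "NA")))
    if (length(bad))
      stop_bbpls("%s: non-numeric value '%s' at row %d, column '%s'",
                 path, raw[bad[1]], bad[1], colnames(M)[j])
    M[, j] <- val
  }
  M
}

#' Read a study dataset from three CSV files
#'
#' All files are comma-separated with a header row and a leading `subject_id`
#' column. The metadata file must provide columns `age`, `group` (ED/HC),
#' `subtype` (EDr/EDbp, blank for HC), `ede_baseline` and `ede_followup`.
#' The three files must describe the same subject set; rows are aligned in
#' sorted subject_id order. Behavior domains may be encoded as a
#' `domain__measure` column-name prefix. Subjects with missing brain or
#' behavior cells, or missing age/group, are dropped (complete-case) with a
#' message.
#'
#' @param brain_path,behavior_path,meta_path CSV file paths.
#' @return a `study_dataset`.
#' @export
read_dataset <- function(brain_path, behavior_path, meta_path) {
  brain <- read_numeric_table(brain_path)
  behavior <- read_numeric_table(behavior_path)
  meta <- read.csv(meta_path, check.names = FALSE, colClasses = "character",
                   fileEncoding = "UTF-8")
  if (!"subject_id" %in% names(meta))
    stop_bbpls("%s: missing 'subject_id' column", meta_path)
  dup <- unique(meta$subject_id[duplicated(meta$subject_id)])
  if (length(dup))
    stop_bbpls("%s: duplicated subject_id: %s", meta_path,
               paste(dup, collapse = ", "))
  need <- c("age", "group", "subtype", "ede_baseline", "ede_followup")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop_bbpls("%s: missing metadata columns: %s", meta_path,
               paste(miss, collapse = ", "))

  sets <- list(brain = rownames(brain), behavior = rownames(behavior),
               metadata = meta$subject_id)
  common <- Reduce(intersect, sets)
  for (nm in names(sets)) {
    extra <- setdiff(sets[[nm]], common)
    if (length(extra))
      stop_bbpls("subject_id %s present in the %s file but absent elsewhere",
                 paste(extra, collapse = ", "), nm)
  }
  ids <- sort(common)
  brain <- brain[ids, , drop = FALSE]
  behavior <- behavior[ids, , drop = FALSE]
  meta <- meta[match(ids, meta$subject_id), ]

  num <- function(x) suppressWarnings(as.numeric(x))
  age <- num(meta$age)
  subtype <- meta$subtype
  subtype[subtype %in% c("", "NA")] <- NA_character_

  keep <- rowSums(is.na(brain)) == 0L & rowSums(is.na(behavior)) == 0L &
    is.finite(age) & meta$group %in% c("ED", "HC")
  if (any(!keep))
    message(sprintf("read_dataset: dropping %d incomplete subject(s): %s",
                    sum(!keep), paste(ids[!keep], collapse = ", ")))

  domains <- rep(NA_character_, ncol(behavior))
  pref <- regmatches(colnames(behavior),
                     regexpr("^[a-z_]+(?=__)", colnames(behavior), perl = TRUE))
  if (length(pref) == ncol(behavior) && all(pref %in% BEHAVIOR_DOMAINS))
    domains <- pref

  study_dataset(ids[keep], brain[keep, , drop = FALSE],
                behavior[keep, , drop = FALSE], age[keep], meta$group[keep],
                subtype[keep], num(meta$ede_baseline)[keep],
                num(meta$ede_followup)[keep], domains)
}

#' Write a study dataset to the three-file CSV layout
#'
#' Numeric cells are written with 15 significant digits so that
#' `read_dataset()` round-trips the dataset to within text-representation
#' error.
#'
#' @param ds a `study_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(M) {
    df <- data.frame(subject_id = ds$subject_id, check.names = FALSE)
    for (j in seq_len(ncol(M))) df[[colnames(M)[j]]] <- format(M[, j], digits = 15)
    df
  }
  paths <- file.path(dir, c("brain.csv", "behavior.csv", "meta.csv"))
  write.csv(fmt(ds$brain), paths[1], row.names = FALSE, quote = FALSE)
  B <- ds$behavior
  if (all(ds$behavior_domains %in% BEHAVIOR_DOMAINS) &&
      !any(grepl("__", colnames(B))))
    colnames(B) <- paste0(ds$behavior_domains, "__", colnames(B))
  write.csv(fmt(B), paths[2], row.names = FALSE, quote = FALSE)
  meta <- data.frame(
    subject_id = ds$subject_id, age = format(ds$age, digits = 15),
    group = as.character(ds$group),
    subtype = ifelse(is.na(ds$subtype), "", as.character(ds$subtype)),
    ede_baseline = ifelse(is.na(ds$baseline_severity), "NA",
                          format(ds$baseline_severity, digits = 15)),
    ede_followup = ifelse(is.na(ds$followup_severity), "NA",
                          format(ds$followup_severity, digits = 15)))
  write.csv(meta, paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

# ---- writing results ---------------------------------------------------------

write_num_csv <- function(df, path) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- format(df[[j]], digits = 15, trim = TRUE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Write analysis results to delimited-text tables
#'
#' Emits CSV tables (loadings, weights, bootstrap ratios, subject scores,
#' permutation and cross-validation summaries, group statistics when present)
#' plus a key-value `run_summary.txt` echoing the configuration, seed and
#' package version. Re-running with the same seed and config produces
#' byte-identical tables.
#'
#' @param results list with elements `decomposition` (a `pls_decomposition`),
#'   and optionally `permutation`, `bootstrap`, `cv` (list per LV),
#'   `group_stats`, `config`.
#' @param out_dir output directory.
#' @return character vector of written file paths (the manifest).
#' @export
write_results <- function(results, out_dir) {
  dec <- results$decomposition
  if (is.null(dec)) stop_bbpls("results$decomposition is required")
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_bbpls("cannot create output directory %s", out_dir)
  files <- character()
  lvs <- paste0("LV", seq_along(dec$s))

  loadings <- data.frame(block = c(rep("brain", nrow(dec$brain_loadings)),
                                   rep("behavior", nrow(dec$behavior_loadings))),
                         variable = c(rownames(dec$brain_loadings),
                                      rownames(dec$behavior_loadings)))
  loadings <- cbind(loadings, rbind(dec$brain_loadings, dec$behavior_loadings))
  names(loadings)[-(1:2)] <- lvs
  files <- c(files, write_num_csv(loadings, file.path(out_dir, "loadings.csv")))

  weights <- data.frame(block = loadings$block, variable = loadings$variable)
  weights <- cbind(weights, rbind(dec$u, dec$v))
  names(weights)[-(1:2)] <- lvs
  files <- c(files, write_num_csv(weights, file.path(out_dir, "weights.csv")))

  sc <- data.frame(subject_id = rownames(dec$brain_scores) %||%
                     seq_len(nrow(dec$brain_scores)))
  for (k in seq_along(dec$s)) {
    sc[[paste0("brain_", lvs[k])]] <- dec$brain_scores[, k]
    sc[[paste0("behavior_", lvs[k])]] <- dec$behavior_scores[, k]
  }
  files <- c(files, write_num_csv(sc, file.path(out_dir, "subject_scores.csv")))

  cov <- data.frame(lv = lvs, singular_value = dec$s,
                    covariance_explained_pct = 100 * dec$covexp)
  if (!is.null(results$permutation))
    cov$perm_pvalue <- results$permutation$pvalues
  files <- c(files, write_num_csv(cov, file.path(out_dir, "permutation_summary.csv")))

  if (!is.null(results$bootstrap)) {
    bt <- results$bootstrap
    br <- data.frame(block = c(rep("brain", nrow(bt$bootstrap_ratios_brain)),
                               rep("behavior", nrow(bt$bootstrap_ratios_behavior))),
                     variable = c(rownames(bt$bootstrap_ratios_brain),
                                  rownames(bt$bootstrap_ratios_behavior)))
    br <- cbind(br, rbind(bt$bootstrap_ratios_brain, bt$bootstrap_ratios_behavior))
    names(br)[-(1:2)] <- lvs
    files <- c(files, write_num_csv(br, file.path(out_dir, "bootstrap_ratios.csv")))

    ci <- do.call(rbind, lapply(names(bt$loading_ci), function(lv) {
      x <- bt$loading_ci[[lv]]
      data.frame(lv = lv, block = x$block, variable = x$variable,
                 loading = x$loading, lower = x$lower, upper = x$upper,
                 reliable = x$reliable)
    }))
    files <- c(files, write_num_csv(ci, file.path(out_dir, "loading_ci.csv")))
  }

  if (!is.null(results$cv)) {
    cvtab <- do.call(rbind, lapply(results$cv, function(cv)
      data.frame(lv = paste0("LV", cv$lv), mean_out_of_sample_r = cv$mean_r,
                 sd_split_r = sd(cv$split_rs), n_splits = cv$n_splits,
                 pvalue = cv$pvalue %||% NA_real_)))
    files <- c(files, write_num_csv(cvtab, file.path(out_dir, "cv_summary.csv")))
  }

  if (!is.null(results$group_stats))
    files <- c(files, write_num_csv(as.data.frame(results$group_stats),
                                    file.path(out_dir, "group_stats.csv")))
  if (!is.null(results$subtypes))
    files <- c(files, write_num_csv(as.data.frame(results$subtypes),
                                    file.path(out_dir, "subtype_comparison.csv")))
  if (!is.null(results$prospective))
    files <- c(files, write_num_csv(as.data.frame(results$prospective),
                                    file.path(out_dir, "prospective.csv")))

  cfg <- results$config
  summ <- c(sprintf("package_version=%s", as.character(packageVersion("bbpls"))),
            sprintf("n_latent_variables=%d", length(dec$s)),
            if (!is.null(cfg)) sprintf("%s=%s", names(unclass(cfg)),
                                       vapply(unclass(cfg), format, "")))
  sfile <- file.path(out_dir, "run_summary.txt")
  writeLines(summ, sfile)
  files <- c(files, sfile)
  files
}
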
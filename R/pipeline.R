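# End-to-end orchestration: preprocess -> decompose -> inference -> clinical,
# from a dataset (or the three CSV inputs) and an analysis configuration,
# writing all result tables plus a run manifest.

#' Run the full PLS pipeline
#'
#' Stages: (1) subset to the analysis group and fit preprocessing (age
#' residualization of the brain block, column z-scoring of both blocks);
#' (2) cross-correlate and decompose into latent variables; (3) permutation
#' test, bootstrap reliability, and out-of-sample validation of every LV
#' with permutation p below `alpha` (at least LV-1); (4) clinical stage:
#' subtype contrasts and prospective follow-up associations for the
#' validated LVs, and an ED-vs-HC descriptives table when both groups are
#' present. All tables are written to `out_dir`.
#'
#' @param ds a `study_dataset`, or `NULL` to read from the three paths.
#' @param brain_path,behavior_path,meta_path CSV inputs (used when `ds` is
#'   `NULL`).
#' @param config an [analysis_config()] or path to a JSON config file.
#' @param out_dir output directory.
#' @param analysis_group `"ED"` (primary), `"HC"` (control-only re-run), or
#'   `"all"`.
#' @return object of class `run_manifest`: config echo, seed, input hashes,
#'   per-stage timings (seconds), output files, package version, and the
#'   in-memory `results` list.
#' @export
run_pipeline <- function(ds = NULL, brain_path = NULL, behavior_path = NULL,
                         meta_path = NULL, config = analysis_config(),
                         out_dir = "bbpls_results",
                         analysis_group = c("ED", "HC", "all")) {
  analysis_group <- match.arg(analysis_group)
  if (is.character(config)) config <- read_config(config)
  hashes <- NULL
  if (is.null(ds)) {
    paths <- c(brain = brain_path, behavior = behavior_path, meta = meta_path)
    hashes <- tools::md5sum(paths)
    ds <- read_dataset(brain_path, behavior_path, meta_path)
  }
  timings <- numeric()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop_bbpls("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
    timings[stage] <<- proc.time()[["elapsed"]] - t0
    out
  }

  full_ds <- ds
  if (analysis_group != "all") ds <- subset_subjects(ds, ds$group == analysis_group)

  Z <- tick("preprocess", {
    model <- fit_preprocess(ds, age_correct = config$age_correct)
    apply_preprocess(model, ds)
  })
  dec <- tick("decompose", {
    d <- pls_decompose(cross_correlation(Z$Zx, Z$Zy), Z$Zx, Z$Zy)
    rownames(d$brain_scores) <- rownames(d$behavior_scores) <- ds$subject_id
    d
  })
  perm <- tick("permutation", permutation_test(ds, config))
  sig_lvs <- which(perm$pvalues < config$alpha)
  report_lvs <- if (length(sig_lvs)) sig_lvs else 1L
  boot <- tick("bootstrap",
               bootstrap_analysis(ds, dec, config, ci_lvs = report_lvs))
  cv <- tick("cross_validation",
             lapply(report_lvs, function(l) cross_validate(ds, config, lv = l)))

  clinical <- tick("clinical", {
    out <- list()
    has_subtypes <- sum(ds$subtype == "EDr", na.rm = TRUE) >= 3 &&
      sum(ds$subtype == "EDbp", na.rm = TRUE) >= 3
    if (has_subtypes)
      out$subtypes <- do.call(rbind, lapply(report_lvs, function(l)
        compare_subtypes(ds, dec, l)))
    n_fu <- sum(!is.na(ds$baseline_severity) & !is.na(ds$followup_severity))
    if (n_fu >= 10)
      out$prospective <- do.call(rbind, lapply(report_lvs, function(l)
        do.call(rbind, lapply(c("brain", "behavior"), function(st) {
          pa <- prospective_association(ds, dec, l, st)
          data.frame(lv = l, score_type = st, partial_r = pa$r, p = pa$p,
                     n = pa$n)
        }))))
    if (all(c("ED", "HC") %in% full_ds$group))
      out$group_stats <- group_descriptives(full_ds,
                                            c("age", full_ds$behavior_names))
    out
  })

  results <- c(list(decomposition = dec, permutation = perm, bootstrap = boot,
                    cv = cv, config = config, significant_lvs = sig_lvs),
               clinical)
  files <- tick("write", write_results(results, out_dir))

  manifest <- structure(list(
    config = config, seed = config$seed, analysis_group = analysis_group,
    input_hashes = hashes, timings = timings, files = files,
    package_version = as.character(packageVersion("bbpls")),
    results = results
  ), class = "run_manifest")
  saveRDS_free_manifest(manifest, file.path(out_dir, "manifest.txt"))
  manifest
}

# Plain-text manifest (key = value lines); no binary artifacts are written.
saveRDS_free_manifest <- function(manifest, path) {
  lines <- c(
    sprintf("package_version = %s", manifest$package_version),
    sprintf("seed = %d", manifest$seed),
    sprintf("analysis_group = %s", manifest$analysis_group),
    if (!is.null(manifest$input_hashes))
      sprintf("input_md5_%s = %s", names(manifest$input_hashes),
              manifest$input_hashes),
    sprintf("timing_%s_sec = %.3f", names(manifest$timings), manifest$timings),
    sprintf("output_file = %s", manifest$files))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("bbpls run (group %s, seed %d): %d LVs, significant: %s\n",
              x$analysis_group, x$seed,
              length(x$results$decomposition$s),
              if (length(x$results$significant_lvs))
                paste(x$results$significant_lvs, collapse = ", ") else "none"))
  cat(sprintf("  %d output files in %s\n", length(x$files),
              dirname(x$files[1])))
  invisible(x)
}

#' Render a human-readable report from written results
#'
#' Reads the CSV tables written by [write_results()] and emits a markdown
#' report: covariance explained and permutation p per LV, loadings sorted by
#' absolute value with reliability flags (confidence interval crossing zero
#' means non-reliable), bootstrap ratios sorted by magnitude and flagged at
#' the configured threshold, and the cross-validation summary. If inference
#' tables are absent the report contains the decomposition only, with a
#' warning line.
#'
#' @param results_dir directory written by [run_pipeline()]/[write_results()].
#' @param bsr_threshold reliability threshold used for flagging.
#' @param top how many variables to list per table.
#' @return path of the written `report.md`, invisibly.
#' @export
render_report <- function(results_dir, bsr_threshold = 1.96, top = 15L) {
  need <- file.path(results_dir, c("loadings.csv", "permutation_summary.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop_bbpls("missing result tables: %s", paste(basename(missing), collapse = ", "))
  perm <- read.csv(file.path(results_dir, "permutation_summary.csv"))
  lines <- c("# PLS run report", "", "## Latent variables", "",
             "| LV | singular value | covariance explained | permutation p |",
             "|----|---------------:|---------------------:|--------------:|")
  for (i in seq_len(nrow(perm)))
    lines <- c(lines, sprintf("| %s | %.4f | %.1f%% | %s |", perm$lv[i],
                              perm$singular_value[i],
                              perm$covariance_explained_pct[i],
                              if ("perm_pvalue" %in% names(perm))
                                format(perm$perm_pvalue[i], digits = 3) else "-"))

  ci_path <- file.path(results_dir, "loading_ci.csv")
  if (file.exists(ci_path)) {
    ci <- read.csv(ci_path)
    for (lv in unique(ci$lv)) {
      sub <- ci[ci$lv == lv, ]
      sub <- sub[order(-abs(sub$loading)), ]
      sub <- head(sub, top)
      lines <- c(lines, "", sprintf("## %s loadings (top %d by |loading|)", lv, top),
                 "", "| block | variable | loading | 95% CI | reliable |",
                 "|-------|----------|--------:|--------|----------|")
      for (i in seq_len(nrow(sub)))
        lines <- c(lines, sprintf("| %s | %s | %.3f | [%.3f, %.3f] | %s |",
                                  sub$block[i], sub$variable[i], sub$loading[i],
                                  sub$lower[i], sub$upper[i],
                                  ifelse(sub$reliable[i], "yes", "no")))
    }
  }

  bsr_path <- file.path(results_dir, "bootstrap_ratios.csv")
  if (file.exists(bsr_path)) {
    bsr <- read.csv(bsr_path)
    lv_cols <- grep("^LV", names(bsr), value = TRUE)
    for (lv in head(lv_cols, 2L)) {
      sub <- bsr[order(-abs(bsr[[lv]])), c("block", "variable", lv)]
      sub <- head(sub, top)
      lines <- c(lines, "", sprintf("## %s bootstrap ratios (top %d, threshold %.2f)",
                                    lv, top, bsr_threshold),
                 "", "| block | variable | bootstrap ratio | reliable |",
                 "|-------|----------|----------------:|----------|")
      for (i in seq_len(nrow(sub)))
        lines <- c(lines, sprintf("| %s | %s | %.2f | %s |",
                                  sub$block[i], sub$variable[i], sub[[lv]][i],
                                  ifelse(abs(sub[[lv]][i]) > bsr_threshold,
                                         "yes", "no")))
    }
  } else {
    lines <- c(lines, "", "WARNING: no inference tables found; decomposition only.")
  }

  cv_path <- file.path(results_dir, "cv_summary.csv")
  if (file.exists(cv_path)) {
    cv <- read.csv(cv_path)
    lines <- c(lines, "", "## Out-of-sample validation", "",
               "| LV | mean out-of-sample r | SD across splits | splits | p |",
               "|----|---------------------:|-----------------:|-------:|---:|")
    for (i in seq_len(nrow(cv)))
      lines <- c(lines, sprintf("| %s | %.3f | %.3f | %d | %s |", cv$lv[i],
                                cv$mean_out_of_sample_r[i], cv$sd_split_r[i],
                                cv$n_splits[i],
                                ifelse(is.na(cv$pvalue[i]), "-",
                                       format(cv$pvalue[i], digits = 3))))
  }

  out <- file.path(results_dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}
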
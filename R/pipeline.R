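#' Pipeline run configuration
#'
#' Bundles the cross-validation scheme, the classifier list, the
#' covariate-handling regime, the multiple-comparison setting and the seed
#' for one end-to-end analysis.
#'
#' @param cv_scheme one of `"site_stratified_fixed"`, `"loso"`,
#'   `"site_stratified_matched"`, `"single_site_repeated"`.
#' @param n_folds folds for the stratified schemes (default 10; used as k
#'   for the repeated scheme, where 5 is conventional).
#' @param n_repeats repeats for `"single_site_repeated"` (default 10).
#' @param model_specs list of [model_spec()]s (default: the random forest).
#' @param feature_regime one of `"brain_plus_covariates"`, `"brain_only"`,
#'   `"covariates_only"`, `"residualized_brain"`.
#' @param subgroup_contrast optional `contrast_spec` (see
#'   [build_contrasts()]); `NULL` runs case vs control.
#' @param alpha family-wise level (default 0.05).
#' @param n_comparisons Bonferroni divisor (default 30: 3 CV designs x 10
#'   classifiers).
#' @param missing_threshold global missingness-exclusion threshold.
#' @param seed integer; mandatory.
#' @return an object of class `run_config`.
#' @export
run_config <- function(cv_scheme = "site_stratified_fixed",
                       n_folds = 10L, n_repeats = 10L,
                       model_specs = NULL,
                       feature_regime = "brain_plus_covariates",
                       subgroup_contrast = NULL,
                       alpha = 0.05, n_comparisons = 30L,
                       missing_threshold = 0.10,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory")
  cv_scheme <- match.arg(cv_scheme,
                         c("site_stratified_fixed", "loso",
                           "site_stratified_matched",
                           "single_site_repeated"))
  feature_regime <- match.arg(feature_regime,
                              c("brain_plus_covariates", "brain_only",
                                "covariates_only", "residualized_brain"))
  if (n_folds < 2L) stop("n_folds must be at least 2")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  if (is.null(model_specs))
    model_specs <- list(rfc = model_spec("rfc", seed = seed))
  if (inherits(model_specs, "model_spec")) model_specs <- list(model_specs)
  ids <- vapply(model_specs, `[[`, "", "id")
  names(model_specs) <- ids
  structure(list(cv_scheme = cv_scheme, n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 model_specs = model_specs,
                 feature_regime = feature_regime,
                 subgroup_contrast = subgroup_contrast,
                 alpha = alpha, n_comparisons = as.integer(n_comparisons),
                 missing_threshold = missing_threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

.build_plans <- function(config, table) {
  switch(config$cv_scheme,
         site_stratified_fixed = list(
           site_stratified_folds(table, config$n_folds,
                                 derive_seed(config$seed, "folds"))),
         loso = list(loso_folds(table)),
         site_stratified_matched = list(
           matched_size_folds(table, loso_folds(table),
                              derive_seed(config$seed, "folds"))),
         single_site_repeated =
           repeated_kfold(table, config$n_folds, config$n_repeats,
                          derive_seed(config$seed, "folds")))
}

# train/test design matrices for one fold under one regime
.fold_design <- function(train_tab, test_tab, regime) {
  state <- fit_preprocess(train_tab)
  br_tr <- apply_preprocess(state, train_tab)
  br_te <- apply_preprocess(state, test_tab)
  cov_tr <- encode_covariates(state, train_tab)
  cov_te <- encode_covariates(state, test_tab)
  res_tr <- res_te <- NULL
  if (regime == "residualized_brain") {
    rz <- fit_residualizer(br_tr, train_tab$meta)
    res_tr <- apply_residualizer(rz, br_tr, train_tab$meta)
    res_te <- apply_residualizer(rz, br_te, test_tab$meta)
  }
  list(X_train = assemble_features(br_tr, cov_tr, regime, res_tr),
       X_test = assemble_features(br_te, cov_te, regime, res_te),
       imputed_train = sum(train_tab$mask),
       imputed_test = sum(test_tab$mask))
}

#' Run the classification pipeline
#'
#' Executes one configuration end to end: optional subgroup contrast,
#' global high-missingness exclusion, fold-plan construction, in-fold
#' preprocessing and (where requested) confound residualization, model
#' fitting with nested tuning, fold-wise and pooled evaluation with
#' Mann-Whitney inference, and Bonferroni flagging.  All randomness derives
#' from `config$seed`; identical inputs give bit-identical reports.
#'
#' @param config a [run_config()].
#' @param table a [subject_table()].
#' @return named list of `analysis_report`s, one per model spec.  Each
#'   carries a `log` with fold sizes, exclusions, imputation counts, tuning
#'   choices and the count of skipped single-class folds.
#' @export
run_pipeline <- function(config, table) {
  stopifnot(inherits(config, "run_config"))
  validate_subject_table(table)
  contrast_name <- "case_vs_control"
  if (!is.null(config$subgroup_contrast)) {
    table <- apply_contrast(table, config$subgroup_contrast)
    contrast_name <- config$subgroup_contrast$name
  }
  excl <- exclude_high_missingness(table, config$missing_threshold)
  table <- excl$table
  if (!any(table$meta$diagnosis == 1) || !any(table$meta$diagnosis == 0))
    stop("empty subgroup: contrast '", contrast_name,
         "' leaves a single class after filtering")
  plans <- .build_plans(config, table)
  lapply(plans, validate_fold_plan, table = table)
  reports <- lapply(config$model_specs, function(spec)
    .evaluate_spec(spec, config, table, plans, contrast_name,
                   excluded = excl$excluded))
  names(reports) <- names(config$model_specs)
  reports
}

.evaluate_spec <- function(spec, config, table, plans, contrast_name,
                           excluded) {
  ids <- table$meta$subject_id
  y_all <- stats::setNames(table$meta$diagnosis, ids)
  per_fold <- list()
  score_sum <- stats::setNames(numeric(length(ids)), ids)
  score_cnt <- stats::setNames(integer(length(ids)), ids)
  tuning <- list()
  n_skipped <- 0L
  imputed <- 0L
  for (r in seq_along(plans)) {
    plan <- plans[[r]]
    for (f in seq_along(plan$folds)) {
      fold <- plan$folds[[f]]
      tr <- subset_table(table, match(fold$train, ids))
      te <- subset_table(table, match(fold$test, ids))
      des <- .fold_design(tr, te, config$feature_regime)
      imputed <- imputed + des$imputed_train + des$imputed_test
      fspec <- spec
      fspec$seed <- derive_seed(spec$seed, sprintf("model/%d/%d", r, f))
      fit <- fit_model(fspec, des$X_train, tr$meta$diagnosis)
      s <- predict_scores(fit, des$X_test)
      if (!is.null(fit$chosen)) tuning[[sprintf("r%d_f%d", r, f)]] <- fit$chosen
      y_te <- te$meta$diagnosis
      single <- length(unique(y_te)) < 2L
      if (single) n_skipped <- n_skipped + 1L
      sm <- if (single) list(balanced_accuracy = NA_real_,
                             sensitivity = NA_real_,
                             specificity = NA_real_)
            else secondary_metrics(s, y_te, fit$threshold)
      per_fold[[length(per_fold) + 1L]] <- data.frame(
        repeat_index = r, fold = f, n_test = length(y_te),
        auc = if (single) NA_real_ else auc_rank(s, y_te),
        balanced_accuracy = sm$balanced_accuracy,
        sensitivity = sm$sensitivity, specificity = sm$specificity,
        skipped_single_class = single)
      score_sum[fold$test] <- score_sum[fold$test] + s
      score_cnt[fold$test] <- score_cnt[fold$test] + 1L
    }
  }
  per_fold <- do.call(rbind, per_fold)
  seen <- score_cnt > 0L
  pooled <- mwu_auc_inference(score_sum[seen] / score_cnt[seen],
                              y_all[seen], config$alpha)
  analysis_report(
    model_id = spec$id, scheme = config$cv_scheme,
    contrast = contrast_name, regime = config$feature_regime,
    per_fold = per_fold,
    fold_auc_mean = mean(per_fold$auc, na.rm = TRUE),
    fold_auc_sd = stats::sd(per_fold$auc[!is.na(per_fold$auc)]),
    pooled_auc = pooled$auc, U = pooled$U, p = pooled$p,
    ci_low = pooled$ci[1], ci_high = pooled$ci[2],
    significant = unname(bonferroni(pooled$p, config$alpha,
                                    config$n_comparisons)),
    alpha = config$alpha, n_comparisons = config$n_comparisons,
    n_skipped_single_class = n_skipped, seed = config$seed,
    log = list(n_subjects = length(ids),
               fold_sizes = vapply(plans[[1]]$folds,
                                   function(f) length(f$test), 1L),
               n_excluded = nrow(excluded),
               excluded_ids = excluded$subject_id,
               imputed_cells = imputed,
               tuning_choices = tuning))
}

#' Per-analysis result record
#'
#' Holds per-fold metrics, their mean and dispersion, the pooled AUC over
#' per-subject test scores with its Mann-Whitney U, two-sided p, 95%
#' Hanley-McNeil interval and Bonferroni-corrected significance flag, plus
#' a structured run log.
#'
#' @param ... named fields (see [run_pipeline()], which constructs these).
#' @return an object of class `analysis_report`.
#' @export
analysis_report <- function(...) {
  structure(list(...), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf(
    "analysis_report: %s | %s | %s | %s\n  pooled AUC %.3f (95%% CI %.3f-%.3f), p = %.3g%s; fold AUC %.3f +/- %.3f\n",
    x$model_id, x$scheme, x$regime, x$contrast, x$pooled_auc, x$ci_low,
    x$ci_high, x$p, if (x$significant) " *" else "", x$fold_auc_mean,
    x$fold_auc_sd))
  invisible(x)
}

#' One-row summary of an analysis report
#' @param x an `analysis_report`.
#' @param row.names,optional,... passed over from the generic; unused.
#' @return data.frame mirroring a supplementary-table row (AUC, CI, p,
#'   corrected flag, fold SD).
#' @export
as.data.frame.analysis_report <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(model = x$model_id, scheme = x$scheme, regime = x$regime,
             contrast = x$contrast, pooled_auc = x$pooled_auc,
             ci_low = x$ci_low, ci_high = x$ci_high, U = x$U, p = x$p,
             significant = x$significant,
             fold_auc_mean = x$fold_auc_mean, fold_auc_sd = x$fold_auc_sd,
             n_skipped_single_class = x$n_skipped_single_class,
             stringsAsFactors = FALSE)
}

#' Serialise reports
#'
#' Reports are written both machine-readable (JSON, lossless: reading the
#' file back reproduces the report) and tabular (TSV, one row per report)
#' for human review and downstream aggregation.
#'
#' @param report an `analysis_report`. @param path file path.
#' @return the path, invisibly (`report_from_json()` returns the report).
#' @export
report_to_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = I(17), na = "null", null = "null",
                       dataframe = "columns")
  invisible(path)
}

#' @rdname report_to_json
#' @export
report_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$per_fold <- as.data.frame(x$per_fold)
  x$per_fold$repeat_index <- as.integer(x$per_fold$repeat_index)
  x$per_fold$fold <- as.integer(x$per_fold$fold)
  x$per_fold$n_test <- as.integer(x$per_fold$n_test)
  for (cn in c("auc", "balanced_accuracy", "sensitivity", "specificity"))
    x$per_fold[[cn]] <- as.numeric(x$per_fold[[cn]])
  for (cn in c("n_comparisons", "n_skipped_single_class", "seed"))
    x[[cn]] <- as.integer(x[[cn]])
  x$log$fold_sizes <- as.integer(x$log$fold_sizes)
  x$log$n_subjects <- as.integer(x$log$n_subjects)
  x$log$n_excluded <- as.integer(x$log$n_excluded)
  x$log$excluded_ids <- as.character(x$log$excluded_ids)
  x$log$imputed_cells <- as.integer(x$log$imputed_cells)
  x$log$tuning_choices <- lapply(x$log$tuning_choices, as.data.frame)
  do.call(analysis_report, x)
}

#' Write a set of reports as one TSV table
#'
#' @param reports list of `analysis_report`s. @param path file path.
#' @return the path, invisibly.
#' @export
reports_to_tsv <- function(reports, path) {
  if (inherits(reports, "analysis_report")) reports <- list(reports)
  tab <- do.call(rbind, lapply(reports, as.data.frame))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
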
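#' Permutation-null feature importance for the random forest
#'
#' Observed importance is the impurity-based importance of a forest grown on
#' the true labels.  The null distribution comes from `B` refits on
#' label-permuted responses (response permutation, the same seed-derived
#' permutation sequence for all features), giving per-feature p-values
#' `p = (1 + #{null >= observed}) / (B + 1)`; the attainable floor is
#' exactly `1/(B+1)` and no p-value can be zero.
#'
#' @param X numeric training matrix (brain features only — covariate
#'   columns must not enter importance analysis).
#' @param y 0/1 labels.
#' @param spec a [model_spec()] with `family = "rfc"`.
#' @param B number of permutations; at least 50 (p-value resolution below
#'   the usual FDR entry point).
#' @param seed integer seed.
#' @return data.frame with `feature`, `importance`, `p`.
#' @export
permutation_importance <- function(X, y, spec = model_spec("rfc"),
                                   B = 200L, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family != "rfc")
    stop("permutation importance is defined for the rfc family only")
  if (B < 50L)
    stop("B must be at least 50: p-value resolution 1/(B+1) would be too ",
         "coarse for FDR at 0.05")
  X <- .check_X(X)
  y <- as.integer(y)
  rf_imp <- function(yy, s)
    ranger::ranger(x = X, y = factor(yy, levels = c(0L, 1L)),
                   num.trees = spec$n_trees,
                   mtry = max(1L, floor(sqrt(ncol(X)))),
                   importance = "impurity", num.threads = 1L,
                   seed = s)$variable.importance
  obs <- rf_imp(y, derive_seed(seed, "imp/obs"))
  exceed <- integer(ncol(X))
  perms <- with_seed(seed, "imp/perms",
                     lapply(seq_len(B), function(b) sample(length(y))))
  for (b in seq_len(B)) {
    null_b <- rf_imp(y[perms[[b]]], derive_seed(seed, paste0("imp/", b)))
    exceed <- exceed + (null_b >= obs)
  }
  data.frame(feature = colnames(X), importance = unname(obs),
             p = unname((1 + exceed) / (B + 1)),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up selection
#'
#' @param p p-values in `(0, 1]`.
#' @param q target false-discovery rate (default 0.05).
#' @return list with `adjusted` (monotone BH-adjusted values) and
#'   `selected` (`adjusted <= q`).
#' @export
fdr_bh <- function(p, q = 0.05) {
  stopifnot(all(p > 0), all(p <= 1))
  adjusted <- stats::p.adjust(p, method = "BH")
  list(adjusted = adjusted, selected = adjusted <= q)
}

#' Across-fold consistency filter
#'
#' A feature is consistent when it was selected in strictly more than half
#' of the evaluated folds.
#'
#' @param selections logical matrix, folds in rows, features in columns
#'   (or a list of per-fold logical vectors).
#' @param n_folds number of evaluated folds (defaults to `nrow`).
#' @return data.frame with `feature`, `n_selected`, `consistent`.
#' @export
consistency_filter <- function(selections, n_folds = NULL) {
  if (is.list(selections) && !is.matrix(selections))
    selections <- do.call(rbind, selections)
  if (nrow(selections) < 2L)
    stop("consistency requires selections from at least 2 folds")
  if (is.null(n_folds)) n_folds <- nrow(selections)
  cnt <- colSums(selections)
  data.frame(feature = colnames(selections) %||%
               paste0("x", seq_along(cnt)),
             n_selected = as.integer(cnt),
             consistent = cnt > n_folds / 2,
             stringsAsFactors = FALSE)
}

#' Fold-wise permutation-importance analysis
#'
#' Runs [permutation_importance()] on the training side of every fold of a
#' plan, applies per-fold Benjamini-Hochberg selection, and summarises the
#' across-fold consistency (selected in more than half the folds).  Inputs
#' are the residualized brain features — covariates are regressed out and
#' never enter the forest — matching the convention of interpreting
#' importance on confound-corrected imaging data only.
#'
#' @param table a [subject_table()] (already contrast-filtered if needed).
#' @param plan a `fold_plan`.
#' @param spec [model_spec()] with family `"rfc"`.
#' @param B permutations per fold. @param q FDR level.
#' @param seed integer seed.
#' @return an `importance_table`: list with `per_fold` (feature,
#'   importance, p, q_value, selected per fold) and `summary`
#'   (per-feature selected-fold count and consistency flag).
#' @export
importance_analysis <- function(table, plan, spec = model_spec("rfc"),
                                B = 200L, q = 0.05, seed = 1L) {
  ids <- table$meta$subject_id
  per_fold <- list()
  sel <- list()
  for (f in seq_along(plan$folds)) {
    tr <- subset_table(table, match(plan$folds[[f]]$train, ids))
    state <- fit_preprocess(tr)
    br <- apply_preprocess(state, tr)
    rz <- fit_residualizer(br, tr$meta)
    Xr <- apply_residualizer(rz, br, tr$meta)
    imp <- permutation_importance(Xr, tr$meta$diagnosis, spec, B,
                                  derive_seed(seed, paste0("fold/", f)))
    bh <- fdr_bh(imp$p, q)
    imp$q_value <- bh$adjusted
    imp$selected <- bh$selected
    imp$fold <- f
    per_fold[[f]] <- imp
    sel[[f]] <- stats::setNames(bh$selected, imp$feature)
  }
  summary <- consistency_filter(do.call(rbind, sel), length(plan$folds))
  structure(list(per_fold = do.call(rbind, per_fold), summary = summary,
                 q = q, B = B, n_folds = length(plan$folds)),
            class = "importance_table")
}

#' Write an importance table as TSV
#' @param x an `importance_table`. @param path_per_fold,path_summary paths.
#' @return invisibly, the summary path.
#' @export
importance_to_tsv <- function(x, path_per_fold, path_summary) {
  utils::write.table(x$per_fold, path_per_fold, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$summary, path_summary, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path_summary)
}
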
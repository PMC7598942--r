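#' Exclude subjects with excessive missingness
#'
#' Removes every subject with strictly more than `threshold` of their
#' feature cells masked.  This is a global, one-off filter applied before
#' any cross-validation split; the remaining missing cells are handled
#' in-fold by train-median imputation.
#'
#' @param table a [subject_table()].
#' @param threshold proportion in `(0,1)`; default 0.10.
#' @return list with `table` (retained rows, order preserved) and
#'   `excluded`, a data.frame of `subject_id`, `missing_fraction`, `reason`.
#' @export
exclude_high_missingness <- function(table, threshold = 0.10) {
  stopifnot(threshold > 0, threshold < 1)
  frac <- rowMeans(table$mask)
  drop <- frac > threshold
  if (all(drop))
    stop("all subjects exceed the missingness threshold; empty table")
  excluded <- data.frame(subject_id = table$meta$subject_id[drop],
                         missing_fraction = frac[drop],
                         reason = rep(sprintf("missingness > %d%%",
                                              round(100 * threshold)),
                                      sum(drop)),
                         stringsAsFactors = FALSE)
  list(table = subset_table(table, !drop), excluded = excluded)
}

#' Fit in-fold preprocessing on training rows
#'
#' Learns, from training rows only: per-feature medians and interquartile
#' ranges over observed (unmasked) cells — quartiles by linear interpolation
#' between order statistics — and the categorical covariate level inventory
#' (sex, site).  Degenerate features with IQR 0 get scale divisor 1 so they
#' stay median-centred.
#'
#' @param train a [subject_table()] of training rows.
#' @return an object of class `preprocess_state`.
#' @export
fit_preprocess <- function(train) {
  if (n_subjects(train) == 0L) stop("empty training table")
  X <- train$features
  obs_count <- colSums(!train$mask)
  if (any(obs_count == 0L))
    stop("feature(s) fully missing in training data: ",
         paste(colnames(X)[obs_count == 0L], collapse = ", "))
  med <- apply(X, 2, stats::median, na.rm = TRUE)
  q <- apply(X, 2, stats::quantile, probs = c(0.25, 0.75), na.rm = TRUE,
             type = 7, names = FALSE)
  iqr <- q[2, ] - q[1, ]
  structure(list(medians = med, iqrs = iqr,
                 scale = ifelse(iqr > 0, iqr, 1),
                 feature_names = colnames(X),
                 sex_levels = if ("sex" %in% names(train$meta))
                   sort(unique(stats::na.omit(train$meta$sex))) else character(0),
                 site_levels = sort(unique(train$meta$site_id))),
            class = "preprocess_state")
}

#' Impute and robust-scale a table against a fitted state
#'
#' Masked cells are replaced by the training medians, then every feature is
#' centred on its training median and divided by its training IQR (divisor 1
#' where the training IQR was 0).  Rows outside the argument table are never
#' touched, so applying a train-fitted state to test rows cannot leak.
#'
#' @param state a `preprocess_state` from [fit_preprocess()].
#' @param table a [subject_table()] with the same feature schema.
#' @return numeric matrix of scaled brain features (no covariates).
#' @export
apply_preprocess <- function(state, table) {
  stopifnot(inherits(state, "preprocess_state"))
  if (!identical(state$feature_names, colnames(table$features))) {
    diff <- c(setdiff(state$feature_names, colnames(table$features)),
              setdiff(colnames(table$features), state$feature_names))
    stop("feature schema mismatch: ", paste(unique(diff), collapse = ", "))
  }
  X <- table$features
  for (j in seq_along(state$medians)) {
    m <- table$mask[, j]
    if (any(m)) X[m, j] <- state$medians[j]
  }
  sweep(sweep(X, 2, state$medians, "-"), 2, state$scale, "/")
}

# one-hot encode against a fixed level inventory; unseen levels -> zero row
.onehot <- function(v, levels, prefix) {
  M <- matrix(0, length(v), length(levels),
              dimnames = list(NULL, paste0(prefix, levels)))
  hit <- match(v, levels)
  ok <- !is.na(hit)
  M[cbind(which(ok), hit[ok])] <- 1
  M
}

#' Encode covariates against a fitted level inventory
#'
#' Builds the covariate block `[age | one-hot sex | one-hot site]` with the
#' full (no reference drop) encoding used when covariates enter tree or
#' kernel models as features.  Levels unseen during fitting encode as
#' all-zero indicator rows.
#'
#' @param state a `preprocess_state`.
#' @param table a [subject_table()].
#' @return numeric matrix with one row per subject.
#' @export
encode_covariates <- function(state, table) {
  m <- table$meta
  age <- if ("age" %in% names(m)) m$age else rep(0, nrow(m))
  cbind(age = age,
        .onehot(m$sex, state$sex_levels, "sex_"),
        .onehot(m$site_id, state$site_levels, "site_"))
}

#' Assemble the model input matrix for a feature regime
#'
#' @param brain scaled brain-feature matrix from [apply_preprocess()].
#' @param covariates covariate block from [encode_covariates()].
#' @param regime one of `"brain_plus_covariates"`, `"brain_only"`,
#'   `"covariates_only"`, `"residualized_brain"`.
#' @param residualized for `"residualized_brain"`, the output of
#'   [apply_residualizer()]; requesting that regime without it is an error.
#' @return numeric model input matrix.
#' @export
assemble_features <- function(brain, covariates, regime,
                              residualized = NULL) {
  regime <- match.arg(regime, c("brain_plus_covariates", "brain_only",
                                "covariates_only", "residualized_brain"))
  switch(regime,
         brain_plus_covariates = cbind(brain, covariates),
         brain_only = brain,
         covariates_only = covariates,
         residualized_brain = {
           if (is.null(residualized))
             stop("residualized_brain regime requires a fitted residualizer")
           residualized
         })
}
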
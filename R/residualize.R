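#' Train-fitted confound residualization
#'
#' Removes the linear effect of the covariates age, sex and site from every
#' brain feature by per-feature ordinary least squares.  Coefficients are
#' estimated on training rows only and then applied unchanged to test rows,
#' preserving train/test independence.  The regression design is an
#' intercept, age, and sex/site indicator columns with the first (reference)
#' level dropped so the design stays full rank; a site level unseen at fit
#' time (e.g. the held-out site under LOSO) contributes zero to every
#' indicator and is thereby treated as the reference level.
#'
#' @param features numeric matrix of (scaled) brain features, training rows.
#' @param covariates data.frame with columns `age`, `sex`, `site_id`
#'   aligned with the feature rows.
#' @return an object of class `residualizer` holding the per-feature
#'   coefficient matrix and the fitted level inventories.
#' @export
fit_residualizer <- function(features, covariates) {
  features <- as.matrix(features)
  sex_levels <- sort(unique(as.character(covariates$sex)))
  site_levels <- sort(unique(as.character(covariates$site_id)))
  X <- .resid_design(covariates, sex_levels, site_levels)
  if (nrow(X) < ncol(X) + 1L)
    stop("too few training rows (", nrow(X), ") for ", ncol(X),
         " design columns")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient covariate design; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  B <- qr.coef(qrX, features)
  structure(list(coefficients = B, sex_levels = sex_levels,
                 site_levels = site_levels, n_train = nrow(X),
                 design_columns = colnames(X)),
            class = "residualizer")
}

.resid_design <- function(cov, sex_levels, site_levels) {
  n <- nrow(cov)
  parts <- list("(Intercept)" = rep(1, n), age = as.numeric(cov$age))
  for (lv in sex_levels[-1])
    parts[[paste0("sex_", lv)]] <- as.numeric(cov$sex == lv)
  for (lv in site_levels[-1])
    parts[[paste0("site_", lv)]] <- as.numeric(cov$site_id == lv)
  X <- do.call(cbind, parts)
  colnames(X) <- names(parts)
  X
}

#' Apply a fitted residualizer
#'
#' Returns `features - design %*% coefficients` using the design built from
#' the stored level inventories.  Applied to its own training rows this
#' reproduces the OLS residuals exactly; unseen site levels fall back to the
#' reference-level prediction.
#'
#' @param res a `residualizer` from [fit_residualizer()].
#' @param features numeric matrix with the same feature columns as at fit.
#' @param covariates data.frame with `age`, `sex`, `site_id`.
#' @return matrix of residualized features.
#' @export
apply_residualizer <- function(res, features, covariates) {
  stopifnot(inherits(res, "residualizer"))
  features <- as.matrix(features)
  B <- res$coefficients
  if (ncol(features) != ncol(B))
    stop("feature schema mismatch: ", ncol(features), " columns vs ",
         ncol(B), " fitted")
  X <- .resid_design(covariates, res$sex_levels, res$site_levels)
  features - X %*% res$coefficients
}

#' Export residualizer coefficients for audit
#'
#' @param res a `residualizer`.
#' @return data.frame, one row per feature, one column per design term.
#' @export
residualizer_coefficients <- function(res) {
  B <- t(res$coefficients)
  data.frame(feature = rownames(B), as.data.frame(B, check.names = FALSE),
             row.names = NULL, check.names = FALSE)
}
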
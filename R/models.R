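#' Classifier specification
#'
#' One entry of the classifier zoo: a model family, an optional PCA
#' reduction (valid for SVM and logistic-regression families), a tuning
#' grid consumed by nested cross-validation, and a seed.  Tuning is enabled
#' for the SVM kernels, logistic regression and XGBoost; the random forest
#' and the Gaussian-process classifier run with fixed recommended settings
#' (500 trees with sqrt(p) candidate features; linear kernel at default
#' scale).  The neural network is a fully connected net with three hidden
#' layers of 60, 40 and 20 units.
#'
#' @param family one of `"svm_linear"`, `"svm_rbf"`, `"logreg_l1"`,
#'   `"logreg_l2"`, `"gpc_linear"`, `"rfc"`, `"xgb"`, `"nn"`.
#' @param pca if `TRUE`, precede the classifier by a train-fit PCA keeping
#'   the minimal number of components explaining 90% of the variance.
#' @param tuning_grid data.frame of candidate hyper-parameter rows, or
#'   `NULL` for the family default (see [default_tuning_grid()]).
#' @param inner_cv_folds inner stratified CV folds for tuning (default 5).
#' @param n_trees forest size for `"rfc"` (default 500).
#' @param seed integer seed for every stochastic component.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(family, pca = FALSE, tuning_grid = NULL,
                       inner_cv_folds = 5L, n_trees = 500L, seed = 1L) {
  family <- match.arg(family, c("svm_linear", "svm_rbf", "logreg_l1",
                                "logreg_l2", "gpc_linear", "rfc", "xgb",
                                "nn"))
  if (pca && !family %in% c("svm_linear", "svm_rbf", "logreg_l1",
                            "logreg_l2"))
    stop("PCA is only combined with SVM and logistic-regression families")
  if (is.null(tuning_grid)) tuning_grid <- default_tuning_grid(family)
  structure(list(family = family, pca = pca, tuning_grid = tuning_grid,
                 inner_cv_folds = as.integer(inner_cv_folds),
                 n_trees = as.integer(n_trees), seed = as.integer(seed),
                 id = paste0(if (pca) "pca_" else "", family)),
            class = "model_spec")
}

#' Default tuning grids
#'
#' Conventional log-spaced grids: SVM cost in {0.01, 0.1, 1, 10}; RBF gamma
#' as the `1/(p Var(X))` scale heuristic times {0.1, 1, 10}; logistic
#' regression penalty lambda in {0.01, 0.1, 1, 10}; XGBoost depth {2, 4, 6}
#' x learning rate {0.05, 0.1, 0.3} at 200 trees.  Untuned families return
#' `NULL`.
#'
#' @param family a model family name.
#' @return data.frame of grid rows, or `NULL`.
#' @export
default_tuning_grid <- function(family) {
  switch(family,
         svm_linear = data.frame(cost = c(0.01, 0.1, 1, 10)),
         svm_rbf = expand.grid(cost = c(0.01, 0.1, 1, 10),
                               gamma_mult = c(0.1, 1, 10)),
         logreg_l1 = ,
         logreg_l2 = data.frame(lambda = c(0.01, 0.1, 1, 10)),
         xgb = expand.grid(max_depth = c(2L, 4L, 6L),
                           eta = c(0.05, 0.1, 0.3), nrounds = 200L),
         NULL)
}

#' The canonical ten-plus-one classifier zoo
#'
#' SVM (linear, RBF) with and without PCA, L1 and L2 logistic regression,
#' PCA + logistic regression, a linear-kernel Gaussian-process classifier,
#' a random forest, XGBoost, and the fully connected neural network.
#'
#' @param seed integer seed shared by all specs.
#' @return named list of [model_spec()]s.
#' @export
canonical_model_specs <- function(seed = 1L) {
  specs <- list(
    model_spec("svm_linear", seed = seed),
    model_spec("svm_linear", pca = TRUE, seed = seed),
    model_spec("svm_rbf", seed = seed),
    model_spec("svm_rbf", pca = TRUE, seed = seed),
    model_spec("logreg_l1", seed = seed),
    model_spec("logreg_l2", seed = seed),
    model_spec("logreg_l2", pca = TRUE, seed = seed),
    model_spec("gpc_linear", seed = seed),
    model_spec("rfc", seed = seed),
    model_spec("xgb", seed = seed),
    model_spec("nn", seed = seed))
  stats::setNames(specs, vapply(specs, `[[`, "", "id"))
}

.check_X <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  bad <- !apply(is.finite(X), 2, all)
  if (any(bad))
    stop("non-finite values in column(s): ",
         paste(colnames(X)[bad], collapse = ", "))
  X
}

# number of leading principal components explaining >= `target` of variance
.pca_ncomp <- function(sdev, target = 0.90) {
  cum <- cumsum(sdev^2) / sum(sdev^2)
  which(cum >= target - 1e-12)[1L]
}

#' Fit a classifier to a model input matrix
#'
#' Applies the spec's optional train-fit PCA (minimal number of components
#' explaining 90% of the variance), runs nested stratified cross-validation
#' over the tuning grid where the family is tuned (selection metric: mean
#' inner AUC; ties go to the earlier grid row), and refits on all training
#' rows.  Every stochastic component draws from seeds derived from
#' `spec$seed`.
#'
#' @param spec a [model_spec()].
#' @param X numeric matrix, finite entries only.
#' @param y 0/1 labels with both classes present.
#' @return an object of class `siteclass_model`.
#' @export
fit_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"))
  X <- .check_X(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  pca <- NULL
  if (spec$pca) {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    k <- .pca_ncomp(pc$sdev)
    pca <- list(rotation = pc$rotation[, seq_len(k), drop = FALSE],
                center = pc$center, ncomp = k)
    X <- scale(X, center = pc$center, scale = FALSE) %*% pca$rotation
  }
  chosen <- NULL
  if (!is.null(spec$tuning_grid) && nrow(spec$tuning_grid) > 1L) {
    chosen <- .tune_inner(spec, X, y)
  } else if (!is.null(spec$tuning_grid)) {
    chosen <- spec$tuning_grid[1L, , drop = FALSE]
  }
  if (!is.null(chosen)) rownames(chosen) <- NULL
  fit <- .fit_base(spec, X, y, chosen, derive_seed(spec$seed, "fit"))
  structure(list(spec = spec, pca = pca, fit = fit, chosen = chosen,
                 n_features = ncol(X),
                 threshold = .threshold_for(spec$family)),
            class = "siteclass_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.threshold_for <- function(family) {
  # probability-type scores cut at 0.5, margin-type scores at 0
  if (family %in% c("rfc", "xgb", "gpc_linear", "nn")) 0.5 else 0
}

.tune_inner <- function(spec, X, y) {
  grid <- spec$tuning_grid
  k <- min(spec$inner_cv_folds, sum(y == 1L), sum(y == 0L))
  if (k < 2L) return(grid[1L, , drop = FALSE])
  fold_of <- with_seed(spec$seed, "tune/folds", {
    cells <- split(seq_along(y), y)
    .stratified_assign(cells, k)
  })
  score <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    aucs <- numeric(k)
    for (f in seq_len(k)) {
      tr <- fold_of != f
      fit <- .fit_base(spec, X[tr, , drop = FALSE], y[tr],
                       grid[g, , drop = FALSE],
                       derive_seed(spec$seed, sprintf("tune/%d/%d", g, f)))
      s <- .predict_base(spec$family, fit, X[!tr, , drop = FALSE])
      aucs[f] <- if (length(unique(y[!tr])) < 2L) NA_real_
                 else auc_rank(s, y[!tr])
    }
    score[g] <- mean(aucs, na.rm = TRUE)
  }
  grid[which.max(score), , drop = FALSE]
}

.fit_base <- function(spec, X, y, params, seed) {
  family <- spec$family
  yf <- factor(y, levels = c(0L, 1L))
  switch(family,
         svm_linear = e1071::svm(x = X, y = yf, kernel = "linear",
                                 cost = params$cost %||% 1, scale = FALSE),
         svm_rbf = {
           vx <- stats::var(as.vector(X))
           g0 <- if (vx > 0) 1 / (ncol(X) * vx) else 1 / ncol(X)
           e1071::svm(x = X, y = yf, kernel = "radial",
                      cost = params$cost %||% 1,
                      gamma = g0 * (params$gamma_mult %||% 1), scale = FALSE)
         },
         logreg_l1 = glmnet::glmnet(X, yf, family = "binomial", alpha = 1,
                                    lambda = params$lambda %||% 0.1,
                                    standardize = FALSE),
         logreg_l2 = glmnet::glmnet(X, yf, family = "binomial", alpha = 0,
                                    lambda = params$lambda %||% 0.1,
                                    standardize = FALSE),
         gpc_linear = with_seed(seed, "gpc",
           kernlab::gausspr(x = X, y = yf, kernel = "vanilladot",
                            kpar = list())),
         rfc = ranger::ranger(x = X, y = yf, num.trees = spec$n_trees,
                              mtry = max(1L, floor(sqrt(ncol(X)))),
                              probability = TRUE, num.threads = 1L,
                              seed = seed),
         xgb = xgboost::xgb.train(
           params = list(objective = "binary:logistic",
                         max_depth = params$max_depth %||% 4L,
                         eta = params$eta %||% 0.1,
                         nthread = 1L, seed = seed),
           data = xgboost::xgb.DMatrix(X, label = y, nthread = 1L),
           nrounds = params$nrounds %||% 200L, verbose = 0),
         nn = .fit_mlp(X, y, seed = seed))
}

.svm_scores <- function(fit, X) {
  p <- stats::predict(fit, X, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  # e1071 reports the margin for the class named first in the column label
  if (startsWith(colnames(dv)[1L], "1")) as.numeric(dv) else -as.numeric(dv)
}

.predict_base <- function(family, fit, X) {
  switch(family,
         svm_linear = ,
         svm_rbf = .svm_scores(fit, X),
         logreg_l1 = ,
         logreg_l2 = as.numeric(stats::predict(fit, X, type = "link")),
         gpc_linear = {
           pr <- kernlab::predict(fit, X, type = "probabilities")
           as.numeric(pr[, "1"])
         },
         rfc = as.numeric(stats::predict(fit, data = X,
                                         num.threads = 1L)$predictions[, "1"]),
         xgb = as.numeric(stats::predict(
           fit, xgboost::xgb.DMatrix(X, nthread = 1L))),
         nn = .predict_mlp(fit, X))
}

#' Decision scores from a fitted classifier
#'
#' One real-valued score per row, higher meaning more case-like, on the
#' score scale native to the family (class probability for the forest,
#' boosted trees, Gaussian process and neural network; margin for the SVMs
#' and logistic regression).  Deterministic given the fitted model.
#'
#' @param model a `siteclass_model` from [fit_model()].
#' @param X matrix with the same columns as at training.
#' @return numeric score vector.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "siteclass_model"))
  X <- .check_X(X)
  expected <- if (is.null(model$pca)) model$n_features
              else length(model$pca$center)
  if (ncol(X) != expected)
    stop("input width ", ncol(X), " does not match training width ",
         expected)
  if (!is.null(model$pca))
    X <- scale(X, center = model$pca$center, scale = FALSE) %*%
      model$pca$rotation
  .predict_base(model$spec$family, model$fit, X)
}

# --- minimal fully connected network ---------------------------------------
# 3 hidden layers (60, 40, 20), ReLU, sigmoid output, class-weighted
# cross-entropy, full-batch Adam, early stopping on a 10% stratified
# validation split with a fixed epoch cap.
.fit_mlp <- function(X, y, hidden = c(60L, 40L, 20L), seed = 1L,
                     lr = 0.01, max_epochs = 200L, patience = 15L) {
  with_seed(seed, "mlp", {
    n <- nrow(X)
    val <- unlist(lapply(split(seq_len(n), y), function(i)
      sample(i, max(1L, round(0.1 * length(i))))))
    tr <- setdiff(seq_len(n), val)
    dims <- c(ncol(X), hidden, 1L)
    L <- length(dims) - 1L
    W <- lapply(seq_len(L), function(l)
      matrix(stats::rnorm(dims[l] * dims[l + 1L], 0, sqrt(2 / dims[l])),
             dims[l], dims[l + 1L]))
    b <- lapply(seq_len(L), function(l) numeric(dims[l + 1L]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    w1 <- n / (2 * sum(y == 1L)); w0 <- n / (2 * sum(y == 0L))
    forward <- function(X) {
      A <- list(X)
      for (l in seq_len(L)) {
        Z <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+")
        A[[l + 1L]] <- if (l < L) pmax(Z, 0) else 1 / (1 + exp(-Z))
      }
      A
    }
    val_loss <- function() {
      p <- forward(X[val, , drop = FALSE])[[L + 1L]]
      p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
      wt <- ifelse(y[val] == 1L, w1, w0)
      -mean(wt * (y[val] * log(p) + (1 - y[val]) * log(1 - p)))
    }
    best <- list(W = W, b = b, loss = Inf); wait <- 0L
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    wtr <- ifelse(ytr == 1L, w1, w0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    for (epoch in seq_len(max_epochs)) {
      A <- forward(Xtr)
      p <- pmin(pmax(A[[L + 1L]], 1e-9), 1 - 1e-9)
      delta <- matrix(wtr * (p - ytr) / length(ytr), ncol = 1L)
      for (l in rev(seq_len(L))) {
        gW <- crossprod(A[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L)
          delta <- (delta %*% t(W[[l]])) * (A[[l]] > 0)
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        cor1 <- 1 - beta1^epoch; cor2 <- 1 - beta2^epoch
        W[[l]] <- W[[l]] - lr * (mW[[l]] / cor1) / (sqrt(vW[[l]] / cor2) + eps)
        b[[l]] <- b[[l]] - lr * (mb[[l]] / cor1) / (sqrt(vb[[l]] / cor2) + eps)
      }
      vl <- val_loss()
      if (vl < best$loss - 1e-6) {
        best <- list(W = W, b = b, loss = vl); wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    structure(list(W = best$W, b = best$b, hidden = hidden,
                   dims = dims), class = "siteclass_mlp")
  })
}

.predict_mlp <- function(fit, X) {
  A <- X
  L <- length(fit$W)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% fit$W[[l]], 2, fit$b[[l]], "+")
    A <- if (l < L) pmax(Z, 0) else 1 / (1 + exp(-Z))
  }
  as.numeric(A)
}
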
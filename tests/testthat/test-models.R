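.toy_xy <- function(n = 80, p = 10, seed = 1, signal = 1.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- rep_len(c(0L, 1L), n)
  X[y == 1, 1] <- X[y == 1, 1] + signal
  list(X = X, y = y)
}

test_that("PCA keeps the minimal component count reaching 90% variance", {
  # eigenvalue spectrum built so 11 components explain 89.1% and 12 explain
  # 90.3%: the rule must keep 12
  ev <- c(rep(0.891 / 11, 11), 0.012, rep(0.097 / 10, 10))
  expect_equal(siteclass:::.pca_ncomp(sqrt(ev)), 12L)
  expect_equal(siteclass:::.pca_ncomp(sqrt(c(9, 1) / 10)), 1L)  # exactly 90%
  d <- .toy_xy(n = 100, p = 12)
  m <- fit_model(model_spec("svm_linear", pca = TRUE, seed = 2), d$X, d$y)
  pc <- prcomp(d$X, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  expect_identical(m$pca$ncomp, which(cum >= 0.9)[1])
  expect_length(predict_scores(m, d$X), 100L)
})

test_that("PCA is invalid outside SVM and logistic families", {
  expect_error(model_spec("rfc", pca = TRUE), "only combined")
})

test_that("the network has three hidden layers of 60, 40 and 20 units", {
  d <- .toy_xy(n = 60, p = 5)
  m <- fit_model(model_spec("nn", seed = 3), d$X, d$y)
  expect_identical(m$fit$hidden, c(60L, 40L, 20L))
  expect_identical(m$fit$dims, c(5L, 60L, 40L, 20L, 1L))
  expect_identical(vapply(m$fit$W, nrow, 1L), c(5L, 60L, 40L, 20L))
})

test_that("a separable problem is fit perfectly by the linear SVM", {
  X <- cbind(a = c(1, 2, 3, 11, 12, 13), b = c(0, 1, 0, 1, 0, 1))
  y <- c(0, 0, 0, 1, 1, 1)
  m <- fit_model(model_spec("svm_linear", seed = 1), X, y)
  s <- predict_scores(m, X)
  expect_equal(auc_rank(s, y), 1.0)
  expect_true(min(s[y == 1]) > max(s[y == 0]))
})

test_that("scores are deterministic, row-order invariant and duplicable", {
  d <- .toy_xy(n = 60, p = 8, seed = 4)
  for (fam in c("svm_rbf", "logreg_l1", "rfc", "xgb", "nn")) {
    spec <- model_spec(fam, n_trees = 100, seed = 9)
    m <- fit_model(spec, d$X, d$y)
    s <- predict_scores(m, d$X)
    perm <- sample(nrow(d$X))
    expect_equal(predict_scores(m, d$X[perm, ])[order(perm)], s,
                 tolerance = 1e-12, info = fam)
    dup <- predict_scores(m, d$X[c(1, 1), , drop = FALSE])
    expect_identical(dup[1], dup[2])
    m2 <- fit_model(spec, d$X, d$y)
    expect_identical(predict_scores(m2, d$X), s)
  }
})

test_that("nested tuning picks a grid row and is seed-deterministic", {
  d <- .toy_xy(n = 90, p = 6, seed = 5)
  spec <- model_spec("svm_linear", seed = 7)
  m <- fit_model(spec, d$X, d$y)
  expect_true(m$chosen$cost %in% spec$tuning_grid$cost)
  m2 <- fit_model(spec, d$X, d$y)
  expect_identical(m$chosen, m2$chosen)
  # tuning sees only the training rows passed in: any other data is
  # irrelevant to the selected hyperparameter
  m3 <- fit_model(spec, d$X + 0, d$y)
  expect_identical(m$chosen, m3$chosen)
})

test_that("input contracts are enforced", {
  d <- .toy_xy()
  expect_error(fit_model(model_spec("rfc"), d$X, rep(1, nrow(d$X))),
               "single class")
  bad <- d$X; bad[3, 2] <- Inf
  expect_error(fit_model(model_spec("rfc"), bad, d$y), "non-finite.*f2")
  m <- fit_model(model_spec("rfc", n_trees = 50, seed = 1), d$X, d$y)
  expect_error(predict_scores(m, d$X[, 1:5]), "width")
})

test_that("the canonical zoo contains the eleven named configurations", {
  zoo <- canonical_model_specs(seed = 2)
  expect_identical(names(zoo),
                   c("svm_linear", "pca_svm_linear", "svm_rbf",
                     "pca_svm_rbf", "logreg_l1", "logreg_l2",
                     "pca_logreg_l2", "gpc_linear", "rfc", "xgb", "nn"))
  tuned <- vapply(zoo, function(s) !is.null(s$tuning_grid), logical(1))
  expect_identical(unname(tuned[c("rfc", "gpc_linear", "nn")]),
                   rep(FALSE, 3))
  expect_true(all(tuned[c("svm_linear", "svm_rbf", "logreg_l1",
                          "logreg_l2", "xgb")]))
})
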
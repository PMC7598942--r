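test_that("missingness exclusion applies the >10% rule exactly", {
  n_feat <- 157
  feats <- matrix(rnorm(3 * n_feat), 3, n_feat,
                  dimnames = list(NULL, paste0("f", seq_len(n_feat))))
  feats[1, 1:16] <- NA   # 16/157 = 10.19% -> out
  feats[2, 1:15] <- NA   # 15/157 =  9.55% -> in
  tab <- make_table(rep("s1", 3), c(1, 0, 1), features = feats)
  res <- exclude_high_missingness(tab, 0.10)
  expect_identical(res$excluded$subject_id, "s001")
  expect_identical(res$table$meta$subject_id, c("s002", "s003"))
  clean <- make_table(rep("s1", 3), c(1, 0, 1))
  res2 <- exclude_high_missingness(clean)
  expect_identical(res2$table$meta, clean$meta)
  expect_identical(nrow(res2$excluded), 0L)
})

test_that("median and IQR match hand computation under linear interpolation", {
  feats <- cbind(a = c(1, 2, 3, 4, 5), b = c(5, 5, 5, 5, 5),
                 c = c(1, 2, 3, 4, 100))
  tab <- make_table(rep("s1", 5), c(1, 0, 1, 0, 1), features = feats)
  st <- fit_preprocess(tab)
  expect_equal(unname(st$medians["a"]), 3)
  expect_equal(unname(st$iqrs["a"]), 2)       # Q1 = 2, Q3 = 4
  expect_equal(unname(st$iqrs["b"]), 0)
  expect_equal(unname(st$scale["b"]), 1)      # degenerate spread -> divisor 1
  out <- apply_preprocess(st, tab)
  expect_equal(unname(out[3, "a"]), 0)        # median maps to zero
  expect_equal(unname(out[5, "a"]), 1)        # (5 - 3) / 2
  expect_equal(unname(out[, "b"]), rep(0, 5))
})

test_that("masked cells impute to the train median and statistics skip them", {
  feats <- cbind(a = c(1, 2, 3, 4, 5, NA))
  tab <- make_table(rep("s1", 6), c(1, 0, 1, 0, 1, 0), features = feats)
  st <- fit_preprocess(tab)
  expect_equal(unname(st$medians["a"]), 3)    # computed on observed cells
  out <- apply_preprocess(st, tab)
  expect_equal(unname(out[6, "a"]), 0)        # imputed to 3, scaled to 0
  feats2 <- cbind(a = rep(NA_real_, 3))
  tab2 <- make_table(rep("s1", 3), c(1, 0, 1), features = feats2)
  expect_error(fit_preprocess(tab2), "fully missing.*a")
})

test_that("fitting never touches rows outside the training table", {
  co <- small_cohort(seed = 6, n_sites = 3, size = c(10, 15))
  idx <- seq_len(n_subjects(co$table))
  train <- subset_table(co$table, idx[1:20])
  st1 <- fit_preprocess(train)
  perturbed <- co$table
  perturbed$features[21, ] <- perturbed$features[21, ] + 100
  st2 <- fit_preprocess(subset_table(perturbed, idx[1:20]))
  expect_identical(st1$medians, st2$medians)
  expect_identical(st1$iqrs, st2$iqrs)
})

test_that("scaling inverts exactly for observed cells", {
  co <- small_cohort(seed = 6, n_sites = 3, size = c(10, 15),
                     missing_rate = 0, heavy_missing_fraction = 0)
  st <- fit_preprocess(co$table)
  out <- apply_preprocess(st, co$table)
  back <- sweep(sweep(out, 2, st$scale, "*"), 2, st$medians, "+")
  expect_equal(back, co$table$features, tolerance = 1e-12)
})

test_that("one-hot covariate blocks behave and regimes have the right width", {
  site <- rep(paste0("st", 1:5), each = 4)
  tab <- make_table(site, rep_len(c(0, 1), 20), n_features = 157)
  st <- fit_preprocess(tab)
  brain <- apply_preprocess(st, tab)
  cov <- encode_covariates(st, tab)
  expect_identical(ncol(assemble_features(brain, cov,
                                          "brain_plus_covariates")), 165L)
  expect_identical(ncol(assemble_features(brain, cov, "covariates_only")), 8L)
  expect_identical(ncol(assemble_features(brain, cov, "brain_only")), 157L)
  # seen levels row-sum to 1 per block; unseen levels to 0
  sex_block <- cov[, grepl("^sex_", colnames(cov)), drop = FALSE]
  site_block <- cov[, grepl("^site_", colnames(cov)), drop = FALSE]
  expect_true(all(rowSums(sex_block) == 1))
  expect_true(all(rowSums(site_block) == 1))
  new_tab <- make_table(rep("stX", 4), c(0, 1, 0, 1), n_features = 157)
  cov_new <- encode_covariates(st, new_tab)
  expect_true(all(rowSums(cov_new[, grepl("^site_", colnames(cov_new))]) == 0))
  expect_error(assemble_features(brain, cov, "residualized_brain"),
               "requires a fitted residualizer")
})
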
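test_that("the generator is deterministic under its seed", {
  a <- small_cohort(seed = 7)
  b <- small_cohort(seed = 7)
  expect_identical(a$table$features, b$table$features)
  expect_identical(a$table$meta, b$table$meta)
  expect_identical(a$truth$diagnosis_idx, b$truth$diagnosis_idx)
  c <- small_cohort(seed = 8)
  expect_false(identical(a$table$features, c$table$features))
})

test_that("injected diagnosis effects are recovered from group moments", {
  co <- generate_cohort(cohort_config(
    n_sites = 10, site_size_range = c(180, 220), case_fraction = 0.5,
    diagnosis_effect = c(20, 1.0), medication_effect = c(40, 0),
    site_offset_sd = 0, site_scale_sd = 0, missing_rate = 0,
    heavy_missing_fraction = 0, seed = 21))
  expect_gte(n_subjects(co$table), 1900)
  X <- co$truth$complete_features
  dx <- co$table$meta$diagnosis
  smd <- vapply(co$truth$diagnosis_idx, function(j) {
    s <- sqrt((stats::var(X[dx == 1, j]) + stats::var(X[dx == 0, j])) / 2)
    (mean(X[dx == 1, j]) - mean(X[dx == 0, j])) / s
  }, numeric(1))
  expect_true(all(abs(smd - 1.0) < 0.15))
  # unaffected features carry no systematic group difference
  off <- setdiff(seq_len(ncol(X)), co$truth$diagnosis_idx)[1:20]
  smd0 <- vapply(off, function(j)
    mean(X[dx == 1, j]) - mean(X[dx == 0, j]), numeric(1))
  expect_true(all(abs(smd0) < 0.2))
})

test_that("a null configuration has calibrated univariate tests", {
  co <- generate_cohort(cohort_config(
    n_sites = 6, site_size_range = c(100, 100), case_fraction = 0.5,
    diagnosis_effect = c(20, 0), medication_effect = c(40, 0),
    site_offset_sd = 0, site_scale_sd = 0,
    covariate_feature_slopes = list(age_sd = 0, sex_sd = 0),
    missing_rate = 0, heavy_missing_fraction = 0, seed = 31))
  X <- co$table$features
  dx <- co$table$meta$diagnosis
  pv <- apply(X, 2, function(x) stats::t.test(x[dx == 1], x[dx == 0])$p.value)
  expect_gt(mean(pv < 0.05), 0.005)
  expect_lt(mean(pv < 0.05), 0.11)
})

test_that("full site-medication purity makes the flag constant per site", {
  co <- generate_cohort(cohort_config(
    n_sites = 8, site_size_range = c(20, 40), site_medication_purity = 1.0,
    seed = 5))
  m <- co$table$meta
  by_site <- tapply(m$medicated[m$diagnosis == 1],
                    m$site_id[m$diagnosis == 1],
                    function(v) stats::var(v))
  expect_true(all(by_site[!is.na(by_site)] == 0))
})

test_that("medication-duration correlation hits its target in large cohorts", {
  co <- generate_cohort(cohort_config(
    n_sites = 20, site_size_range = c(100, 150), seed = 13))
  m <- co$table$meta[co$table$meta$diagnosis == 1, ]
  expect_gte(nrow(m), 1000)
  r <- stats::cor(m$medicated, m$illness_duration)
  expect_lt(abs(r - (-0.094)), 0.05)
})

test_that("an infeasible correlation target errors explicitly", {
  expect_error(generate_cohort(cohort_config(
    n_sites = 4, site_size_range = c(20, 30), medicated_fraction = 0,
    seed = 2)), "infeasible correlation target")
})

test_that("missingness injection matches its configuration", {
  co <- small_cohort(seed = 3, n_sites = 5, size = c(40, 60),
                     missing_rate = 0, heavy_missing_fraction = 0)
  expect_false(any(co$table$mask))
  n <- n_subjects(co$table)
  t2 <- inject_missingness(co$table, 0.01, 0.05, seed = 9)
  heavy <- mean(rowMeans(t2$mask) > 0.10)
  expect_gt(heavy, qbinom(0.0005, n, 0.05) / n)
  expect_lt(heavy, qbinom(0.9995, n, 0.05) / n)
  t3 <- inject_missingness(co$table, 0.01, 0.05, seed = 9)
  expect_identical(t2$mask, t3$mask)
  expect_false(identical(t2$mask,
                         inject_missingness(co$table, 0.01, 0.05, 10)$mask))
})

test_that("the canonical feature layout has 157 FreeSurfer-style names", {
  nm <- freesurfer_feature_names(157)
  expect_length(nm, 157)
  expect_false(anyDuplicated(nm) > 0)
  expect_true("lh_superiorfrontal_thickavg" %in% nm)
  expect_true("rh_hippocampus_vol" %in% nm)
  expect_true("icv" %in% nm)
  expect_identical(sum(grepl("_thickavg$", nm)), 70L)  # 2x34 + 2 hemisphere
  expect_identical(sum(grepl("_surfavg$", nm)), 70L)
  expect_identical(sum(grepl("_vol$", nm)), 16L)       # 2x7 + 2 ventricles
})
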
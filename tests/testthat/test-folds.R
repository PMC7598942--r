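test_that("site-stratified folds balance sizes globally and per cell", {
  tab <- make_table(rep(c("A", "B"), each = 50),
                    rep_len(c(0, 1), 100), seed = 2)
  plan <- site_stratified_folds(tab, 10, seed = 5)
  validate_fold_plan(plan, tab)
  sizes <- vapply(plan$folds, function(f) length(f$test), 1L)
  expect_true(all(sizes == 10))
  for (f in plan$folds) {
    m <- tab$meta[match(f$test, tab$meta$subject_id), ]
    expect_true(all(table(m$site_id) == 5))
  }
})

test_that("a tiny site spreads one subject per fold under the <=1 rule", {
  tab <- make_table(c(rep("big", 97), rep("tiny", 3)),
                    rep_len(c(0, 1), 100), seed = 3)
  plan <- site_stratified_folds(tab, 10, seed = 1)
  tiny_ids <- tab$meta$subject_id[tab$meta$site_id == "tiny"]
  per_fold <- vapply(plan$folds,
                     function(f) length(intersect(f$test, tiny_ids)), 1L)
  expect_identical(sum(per_fold > 0), 3L)
  expect_true(all(per_fold <= 1))
  # global size balance within one subject
  sizes <- vapply(plan$folds, function(f) length(f$test), 1L)
  expect_lte(diff(range(sizes)), 1L)
})

test_that("fold plans are deterministic in the seed and randomized across", {
  co <- small_cohort(seed = 9, n_sites = 5, size = c(20, 40))
  p1 <- site_stratified_folds(co$table, 10, seed = 4)
  p2 <- site_stratified_folds(co$table, 10, seed = 4)
  expect_identical(p1, p2)
  p3 <- site_stratified_folds(co$table, 10, seed = 5)
  expect_false(identical(p1$folds, p3$folds))
  expect_error(site_stratified_folds(co$table, 10 * n_subjects(co$table), 1),
               "exceeds")
})

test_that("LOSO uses each site once as an intact external test set", {
  co <- small_cohort(seed = 9, n_sites = 5, size = c(20, 40))
  plan <- loso_folds(co$table)
  validate_fold_plan(plan, co$table)
  expect_length(plan$folds, 5L)
  for (i in seq_along(plan$folds)) {
    test_sites <- unique(co$table$meta$site_id[
      match(plan$folds[[i]]$test, co$table$meta$subject_id)])
    expect_identical(test_sites, plan$test_sites[i])
  }
  expect_identical(sum(vapply(plan$folds, function(f) length(f$test), 1L)),
                   n_subjects(co$table))
  one_site <- subset_table(co$table, co$table$meta$site_id ==
                             co$table$meta$site_id[1])
  expect_error(loso_folds(one_site), "at least two sites")
})

test_that("single-class test sites are flagged for AUC skipping", {
  tab <- make_table(c(rep("A", 20), rep("B", 5)),
                    c(rep_len(c(0, 1), 20), rep(1, 5)), seed = 4)
  plan <- loso_folds(tab)
  expect_identical(plan$single_class_test, c(FALSE, TRUE))
})

test_that("matched folds reproduce the LOSO size multiset while mixing sites", {
  co <- small_cohort(seed = 12, n_sites = 6, size = c(15, 60))
  lp <- loso_folds(co$table)
  mp <- matched_size_folds(co$table, lp, seed = 3)
  validate_fold_plan(mp, co$table)
  loso_sizes <- sort(vapply(lp$folds, function(f) length(f$test), 1L))
  m_sizes <- sort(vapply(mp$folds, function(f) length(f$test), 1L))
  expect_identical(m_sizes, loso_sizes)
  n_sites_per_fold <- vapply(mp$folds, function(f)
    length(unique(co$table$meta$site_id[
      match(f$test, co$table$meta$subject_id)])), 1L)
  expect_true(all(n_sites_per_fold > 1))
  expect_identical(mp, matched_size_folds(co$table, lp, seed = 3))
})

test_that("two equal sites give a matched plan of equal halves", {
  tab <- make_table(rep(c("A", "B"), each = 20), rep_len(c(0, 1), 40),
                    seed = 5)
  mp <- matched_size_folds(tab, loso_folds(tab), seed = 1)
  sizes <- vapply(mp$folds, function(f) length(f$test), 1L)
  expect_identical(sizes, c(20L, 20L))
})

test_that("repeated k-fold gives stratified partitions per repeat", {
  tab <- make_table(rep("solo", 50), rep_len(c(0, 1), 50), seed = 8)
  plans <- repeated_kfold(tab, k = 5, repeats = 10, seed = 2)
  expect_length(plans, 10L)
  for (pl in plans) {
    validate_fold_plan(pl, tab)
    sizes <- vapply(pl$folds, function(f) length(f$test), 1L)
    expect_true(all(sizes == 10))
  }
  expect_false(identical(plans[[1]]$folds, plans[[2]]$folds))
  small <- make_table(rep("solo", 8), c(rep(1, 3), rep(0, 5)))
  expect_error(repeated_kfold(small, k = 5, repeats = 2, seed = 1),
               "smaller k")
})

test_that("fold plans survive the JSON round trip", {
  co <- small_cohort(seed = 9, n_sites = 4, size = c(10, 20))
  plan <- site_stratified_folds(co$table, 5, seed = 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_fold_plan(plan, path)
  back <- read_fold_plan(path)
  expect_identical(back$folds, plan$folds)
  expect_identical(back$scheme, plan$scheme)
  expect_identical(back$seed, plan$seed)
})
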
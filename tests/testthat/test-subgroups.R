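.clin_table <- function() {
  make_table(rep("s1", 10), c(rep(0, 4), rep(1, 6)), seed = 3,
             medicated = c(rep(NA, 4), 1, 1, 0, 0, 1, NA),
             ybocs = c(rep(NA, 4), 24, 25, 10, 30, 24, 18),
             age_of_onset = c(rep(NA, 4), 17.9, 18, 25, 10, 18.1, NA),
             illness_duration = c(rep(NA, 4), 7.0, 7.1, 3, 20, 6, 2))
}

test_that("clinical thresholds split exactly as printed", {
  tab <- .clin_table()
  cons <- build_contrasts(tab)
  ids <- function(cs, side = "a") {
    f <- if (side == "a") cs$filter_a else cs$filter_b
    tab$meta$subject_id[f(tab$meta)]
  }
  # YBOCS 24 belongs to the low-severity group (<= 24)
  expect_true(all(c("s005", "s009") %in% ids(cons$hc_vs_low_severity)))
  expect_false("s005" %in% ids(cons$hc_vs_high_severity))
  # onset at exactly 18 years is late (>= 18)
  expect_true(all(c("s006", "s009") %in% ids(cons$hc_vs_late_onset)))
  expect_true("s005" %in% ids(cons$hc_vs_early_onset))  # 17.9 < 18
  # duration exactly 7 years is short (<= 7)
  expect_true("s005" %in% ids(cons$hc_vs_short_duration))
  expect_true("s006" %in% ids(cons$hc_vs_long_duration))  # 7.1 > 7
  # groups are disjoint and exhaust the patients up to missing values
  for (v in c("low_severity", "high_severity")) {
    a <- ids(cons[[paste0("hc_vs_", v)]])
    expect_true(all(grepl("^s0(0[5-9]|10)$", a)))
  }
  lowhigh <- union(ids(cons$hc_vs_low_severity), ids(cons$hc_vs_high_severity))
  expect_identical(sort(lowhigh), sprintf("s%03d", 5:10))
  expect_length(intersect(ids(cons$hc_vs_low_severity),
                          ids(cons$hc_vs_high_severity)), 0L)
})

test_that("contrast application relabels and drops everything else", {
  tab <- .clin_table()
  cons <- build_contrasts(tab)
  sub <- apply_contrast(tab, cons$medicated_vs_unmedicated)
  expect_identical(sort(sub$meta$subject_id),
                   c("s005", "s006", "s007", "s008", "s009"))
  expect_identical(sub$meta$diagnosis[sub$meta$subject_id == "s007"], 0L)
  expect_identical(sub$meta$diagnosis[sub$meta$subject_id == "s005"], 1L)
  empty <- contrast_spec("impossible",
                         function(m) m$diagnosis == 1 & m$age < 0,
                         function(m) m$diagnosis == 0)
  expect_error(apply_contrast(tab, empty), "empty subgroup")
})

test_that("the correlation screen dispatches types and matches hand values", {
  n <- 40
  tab <- make_table(rep("s1", n), rep(1, n), seed = 5,
                    medicated = rep_len(c(0, 0, 1, 1), n),
                    illness_duration = rep_len(c(1, 2, 3, 4), n),
                    ybocs = rep_len(c(20, 28, 22, 30), n))
  tab$meta$comorbid <- rep_len(c(0, 0, 1, 1), n)  # second dichotomous field
  scr <- clinical_correlation_screen(tab, variables = c(
    "medicated", "illness_duration", "ybocs", "comorbid"))
  pb <- scr[scr$var1 == "medicated" & scr$var2 == "illness_duration", ]
  expect_identical(pb$type, "point_biserial")
  expect_equal(pb$r, 0.8944272, tolerance = 1e-6)
  phi <- scr[scr$var1 == "medicated" & scr$var2 == "comorbid", ]
  expect_identical(phi$type, "phi")
  expect_equal(phi$r, 1.0)    # a = d cells only
  pe <- scr[scr$var1 == "illness_duration" & scr$var2 == "ybocs", ]
  expect_identical(pe$type, "pearson")
  expect_identical(nrow(scr), 6L)   # all pairs of the four variables
})

test_that("the screen recovers the injected medication-duration coupling", {
  co <- generate_cohort(cohort_config(n_sites = 30, site_size_range =
                                        c(120, 160), seed = 17))
  expect_gte(sum(co$table$meta$diagnosis), 2000)
  scr <- clinical_correlation_screen(co$table)
  r <- scr$r[scr$var1 == "medicated" & scr$var2 == "illness_duration"]
  expect_lt(abs(r - (-0.094)), 0.05)
  expect_lt(r, 0)
})

test_that("sensitivity reruns refuse an all-missing split variable", {
  tab <- make_table(rep(c("s1", "s2"), 10), rep_len(c(0, 1), 20),
                    medicated = rep_len(c(NA, 1), 20),
                    illness_duration = rep(NA_real_, 20))
  cfg <- run_config(model_specs = model_spec("rfc", n_trees = 50, seed = 1),
                    seed = 1)
  expect_error(sensitivity_reruns(tab, cfg), "disable the sensitivity rerun")
})

test_that("contrast manifests serialize", {
  tab <- .clin_table()
  cons <- build_contrasts(tab)
  path <- withr::local_tempfile(fileext = ".json")
  contrasts_to_json(cons, path)
  manifest <- jsonlite::read_json(path)
  expect_length(manifest, length(cons))
  expect_identical(manifest$hc_vs_medicated$variable, "medicated")
})
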
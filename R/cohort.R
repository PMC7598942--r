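#' Synthetic multi-site cohort configuration
#'
#' Parameterises the generator that emulates the statistical structure of a
#' multi-site consortium table of FreeSurfer-style regional measures:
#' many site blocks of skewed size, per-site additive offsets and
#' multiplicative scale factors (scanner effects), a small distributed
#' diagnosis effect, a larger distributed medication effect among cases,
#' a weak negative coupling between medication status and illness duration,
#' sites that are exclusively medicated or exclusively unmedicated, and
#' cell-wise missingness with a subset of heavily affected subjects.
#'
#' Effects are expressed in within-site residual standard-deviation units
#' (the per-feature noise is unit Gaussian), so `diagnosis_effect = c(20, 0.2)`
#' means a Cohen's d of 0.2 added to cases on 20 randomly chosen features.
#'
#' @param n_sites number of site blocks (default 46).
#' @param site_size_range integer `(min, max)`; sizes are drawn log-uniformly
#'   to mimic skewed consortium site sizes.  `min` must be at least 4 so a
#'   site can host both classes.
#' @param case_fraction expected proportion of cases per site.
#' @param n_features number of brain features (default 157: 2 x 34 cortical
#'   thickness + 2 x 34 surface area ROIs, 2 + 2 whole-hemisphere measures,
#'   2 x 7 subcortical volumes, 2 lateral ventricles, and ICV).
#' @param site_offset_sd SD of per-site additive offsets per feature.
#' @param site_scale_sd log-scale SD of per-site multiplicative factors.
#' @param diagnosis_effect `c(n_affected, d)`: case-vs-control shift.
#' @param medication_effect `c(n_affected, d)`: medicated-vs-unmedicated
#'   shift among cases.
#' @param medicated_fraction expected proportion of cases medicated.
#' @param site_medication_purity fraction of sites whose cases are either
#'   all medicated or all unmedicated.
#' @param medication_duration_target_r target point-biserial correlation
#'   between medication status and illness duration (default -0.094).
#' @param age_range years, uniform draw. @param sex_ratio proportion male.
#' @param covariate_feature_slopes list with `age_sd` and `sex_sd`: SDs of
#'   per-feature age (per decade) and sex loadings.
#' @param missing_rate per-cell MCAR probability.
#' @param heavy_missing_fraction fraction of subjects forced above 10%
#'   missing cells (these are the subjects preprocessing later excludes).
#' @param duration_mean,duration_sd illness-duration distribution (years)
#'   for cases, before the medication coupling shift.
#' @param seed integer; mandatory, drives every random draw.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_sites = 46L,
                          site_size_range = c(20L, 250L),
                          case_fraction = 0.53,
                          n_features = 157L,
                          site_offset_sd = 0.4,
                          site_scale_sd = 0.1,
                          diagnosis_effect = c(20L, 0.2),
                          medication_effect = c(40L, 0.5),
                          medicated_fraction = 0.5,
                          site_medication_purity = 0.3,
                          medication_duration_target_r = -0.094,
                          age_range = c(18, 65),
                          sex_ratio = 0.5,
                          covariate_feature_slopes = list(age_sd = 0.01,
                                                          sex_sd = 0.05),
                          missing_rate = 0.01,
                          heavy_missing_fraction = 0.05,
                          duration_mean = 12,
                          duration_sd = 8,
                          seed) {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- structure(as.list(environment()), class = "cohort_config")
  props <- c(case_fraction = case_fraction,
             medicated_fraction = medicated_fraction,
             site_medication_purity = site_medication_purity,
             missing_rate = missing_rate,
             heavy_missing_fraction = heavy_missing_fraction,
             sex_ratio = sex_ratio)
  bad <- props < 0 | props > 1
  if (any(bad))
    stop("proportions outside [0,1]: ", paste(names(props)[bad], collapse = ", "))
  if (site_size_range[1] < 4)
    stop("site_size_range minimum must be >= 4 so every site can host both classes")
  if (n_features < max(diagnosis_effect[1], medication_effect[1]))
    stop("n_features smaller than the number of affected features")
  if (abs(medication_duration_target_r) >= 1)
    stop("medication_duration_target_r must lie in (-1, 1)")
  cfg
}

# Desikan-Killiany cortical parcels (34 per hemisphere)
.dk_regions <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
  "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
  "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
  "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
  "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
  "precentral", "precuneus", "rostralanteriorcingulate",
  "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
  "superiortemporal", "supramarginal", "temporalpole", "transversetemporal")

.subcortical <- c("thalamus", "caudate", "putamen", "pallidum",
                  "hippocampus", "amygdala", "accumbens")

#' FreeSurfer-style feature names
#'
#' The canonical 157-column layout: per-hemisphere cortical thickness and
#' surface area for the 34 Desikan-Killiany parcels, whole-hemisphere mean
#' thickness and total surface area, 7 subcortical volumes per hemisphere,
#' the two lateral ventricles, and total intracranial volume.  For
#' `n != 157` the list is truncated or padded with generic volume names.
#'
#' @param n number of names wanted.
#' @return character vector of length `n`.
#' @export
freesurfer_feature_names <- function(n = 157L) {
  hemi <- function(pre, suf) as.vector(t(outer(c("lh", "rh"),
                                               paste0(pre, "_", suf), paste,
                                               sep = "_")))
  nm <- c(hemi(.dk_regions, "thickavg"),
          hemi(.dk_regions, "surfavg"),
          c("lh_meanthickness_thickavg", "rh_meanthickness_thickavg",
            "lh_totalsurfarea_surfavg", "rh_totalsurfarea_surfavg"),
          hemi(.subcortical, "vol"),
          c("lh_lateralventricle_vol", "rh_lateralventricle_vol"),
          "icv")
  if (n <= length(nm)) return(nm[seq_len(n)])
  c(nm, sprintf("extra_roi%03d_vol", seq_len(n - length(nm))))
}

# mean gap between medicated/unmedicated duration distributions that yields a
# target point-biserial correlation r, given prevalence q and within-group sd s
.pb_gap <- function(r, q, s) {
  if (q <= 0 || q >= 1) {
    if (r != 0)
      stop("infeasible correlation target: medication status is constant ",
           "(medicated fraction ", q, ") but target r is ", r)
    return(0)
  }
  r * s / sqrt(q * (1 - q) * (1 - r^2))
}

#' Generate a synthetic multi-site cohort
#'
#' Each subject's feature vector is assembled as
#' `site offset x site scale + covariate loadings + diagnosis effect (cases)
#' + medication effect (medicated cases) + unit Gaussian noise`, after which
#' missingness is applied.  All draws derive from `config$seed`; the same
#' configuration always reproduces the same cohort.
#'
#' @param config a [cohort_config()].
#' @return a list with `table` (a [subject_table()]) and `truth`, a ground
#'   truth record holding the complete (pre-missingness) feature matrix,
#'   affected feature indices and effect sizes, per-site offset/scale draws
#'   and covariate loadings — sufficient to recompute every expected group
#'   difference.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  p <- as.integer(cfg$n_features)
  fn <- freesurfer_feature_names(p)
  with_seed(cfg$seed, "cohort", {
    # --- site structure -----------------------------------------------------
    lo <- log(cfg$site_size_range[1]); hi <- log(cfg$site_size_range[2])
    sizes <- pmin(pmax(round(exp(stats::runif(cfg$n_sites, lo, hi))),
                       cfg$site_size_range[1]), cfg$site_size_range[2])
    n <- sum(sizes)
    site_id <- rep(sprintf("site%02d", seq_len(cfg$n_sites)), times = sizes)
    offsets <- matrix(stats::rnorm(cfg$n_sites * p, 0, cfg$site_offset_sd),
                      cfg$n_sites, p)
    scales <- matrix(exp(stats::rnorm(cfg$n_sites * p, 0, cfg$site_scale_sd)),
                     cfg$n_sites, p)
    # --- subjects -----------------------------------------------------------
    dx <- integer(n)
    for (s in seq_len(cfg$n_sites)) {
      idx <- which(site_id == sprintf("site%02d", s))
      k <- min(max(stats::rbinom(1, length(idx), cfg$case_fraction), 1L),
               length(idx) - 1L)
      dx[sample(idx, k)] <- 1L
    }
    age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
    sex <- ifelse(stats::runif(n) < cfg$sex_ratio, "M", "F")
    # --- medication: pure sites first, then per-case draws -------------------
    medicated <- rep(NA_integer_, n)
    n_pure <- round(cfg$site_medication_purity * cfg$n_sites)
    pure_sites <- sample(cfg$n_sites, n_pure)
    pure_level <- stats::rbinom(n_pure, 1, cfg$medicated_fraction)
    site_index <- match(site_id, sprintf("site%02d", seq_len(cfg$n_sites)))
    for (k in seq_along(pure_sites)) {
      idx <- which(site_index == pure_sites[k] & dx == 1L)
      medicated[idx] <- pure_level[k]
    }
    open <- which(dx == 1L & is.na(medicated))
    medicated[open] <- stats::rbinom(length(open), 1, cfg$medicated_fraction)
    # --- clinical variables --------------------------------------------------
    cases <- which(dx == 1L)
    q <- mean(medicated[cases])
    gap <- .pb_gap(cfg$medication_duration_target_r, q, cfg$duration_sd)
    mu <- cfg$duration_mean + gap * (medicated[cases] - q)
    duration <- rep(NA_real_, n)
    duration[cases] <- pmin(pmax(stats::rnorm(length(cases), mu,
                                              cfg$duration_sd), 0.5),
                            age[cases] - 3)
    onset <- rep(NA_real_, n)
    onset[cases] <- age[cases] - duration[cases]
    ybocs <- rep(NA_real_, n)
    ybocs[cases] <- pmin(pmax(round(stats::rnorm(length(cases), 24, 6)), 8), 40)
    # --- features ------------------------------------------------------------
    idx_dx <- sample(p, cfg$diagnosis_effect[1])
    idx_med <- sample(p, cfg$medication_effect[1])
    age_slope <- stats::rnorm(p, 0, cfg$covariate_feature_slopes$age_sd)
    sex_slope <- stats::rnorm(p, 0, cfg$covariate_feature_slopes$sex_sd)
    X <- offsets[site_index, , drop = FALSE] *
      scales[site_index, , drop = FALSE]
    X <- X + outer((age - mean(cfg$age_range)) / 10, age_slope)
    X <- X + outer(as.numeric(sex == "M"), sex_slope)
    X[dx == 1L, idx_dx] <- X[dx == 1L, idx_dx] + cfg$diagnosis_effect[2]
    med1 <- which(!is.na(medicated) & medicated == 1L)
    X[med1, idx_med] <- X[med1, idx_med] + cfg$medication_effect[2]
    X <- X + matrix(stats::rnorm(n * p), n, p)
    colnames(X) <- fn
    meta <- data.frame(subject_id = sprintf("sub%05d", seq_len(n)),
                       site_id = site_id, diagnosis = dx, age = age,
                       sex = sex, medicated = medicated, ybocs = ybocs,
                       age_of_onset = onset, illness_duration = duration,
                       stringsAsFactors = FALSE)
    tab <- subject_table(meta, X)
    truth <- list(complete_features = X,
                  diagnosis_idx = sort(idx_dx),
                  diagnosis_d = cfg$diagnosis_effect[2],
                  medication_idx = sort(idx_med),
                  medication_d = cfg$medication_effect[2],
                  site_offsets = offsets, site_scales = scales,
                  age_slope = age_slope, sex_slope = sex_slope,
                  site_sizes = sizes, duration_gap = gap)
    tab <- inject_missingness(tab, cfg$missing_rate,
                              cfg$heavy_missing_fraction,
                              derive_seed(cfg$seed, "missingness"))
    list(table = tab, truth = truth)
  })
}

#' Mask feature cells at random, with a heavy-missingness subset
#'
#' Selected subjects (each independently with probability
#' `heavy_missing_fraction`) have strictly more than 10% of their feature
#' cells masked, which marks them for later exclusion by
#' [exclude_high_missingness()]; every remaining cell is masked i.i.d. at
#' `missing_rate`.  Values at masked cells are replaced by `NA`.
#'
#' @param table a [subject_table()].
#' @param missing_rate per-cell probability in `[0,1]`.
#' @param heavy_missing_fraction per-subject probability in `[0,1]`.
#' @param seed integer seed.
#' @return a new `subject_table` with the updated mask.
#' @export
inject_missingness <- function(table, missing_rate, heavy_missing_fraction,
                               seed) {
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            heavy_missing_fraction >= 0, heavy_missing_fraction <= 1)
  n <- n_subjects(table); p <- ncol(table$features)
  with_seed(seed, "mask", {
    mask <- matrix(stats::runif(n * p) < missing_rate, n, p)
    heavy <- which(stats::runif(n) < heavy_missing_fraction)
    floor10 <- floor(0.10 * p)
    for (i in heavy) {
      k <- sample((floor10 + 1L):max(floor10 + 1L, ceiling(0.25 * p)), 1L)
      mask[i, sample(p, k)] <- TRUE
    }
    X <- table$features
    X[mask] <- NA_real_
    subject_table(table$meta, X, mask)
  })
}
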
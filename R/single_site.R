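#' Per-site classification and the site-size/performance relation
#'
#' Runs diagnosis-stratified repeated k-fold classification separately
#' within every site large enough to support it, records each site's mean
#' fold AUC, and computes the Spearman correlation between site size and
#' site performance.
#'
#' @param table a [subject_table()].
#' @param spec a [model_spec()] (default: the random forest).
#' @param k folds (default 5). @param repeats repeats (default 10).
#' @param feature_regime passed to [run_config()]; site indicators are
#'   constant within a site, so `"brain_only"` is the default here.
#' @param min_per_class smallest per-class count for a site to be
#'   evaluated (must be at least `k`).
#' @param seed integer seed.
#' @return list with `per_site` (site, n, n_cases, mean fold AUC, SD) and
#'   `correlation` (`rho`, `p`) from
#'   [site_size_performance_correlation()], `NULL` when fewer than three
#'   sites were evaluable.
#' @export
single_site_analysis <- function(table, spec = NULL, k = 5L, repeats = 10L,
                                 feature_regime = "brain_only",
                                 min_per_class = max(10L, k), seed = 1L) {
  if (is.null(spec)) spec <- model_spec("rfc", seed = seed)
  sites <- sort(unique(table$meta$site_id))
  rows <- list()
  for (s in sites) {
    sub <- subset_table(table, table$meta$site_id == s)
    n1 <- sum(sub$meta$diagnosis == 1); n0 <- sum(sub$meta$diagnosis == 0)
    if (min(n1, n0) < max(min_per_class, k)) next
    cfg <- run_config(cv_scheme = "single_site_repeated", n_folds = k,
                      n_repeats = repeats, model_specs = list(spec),
                      feature_regime = feature_regime,
                      seed = derive_seed(seed, paste0("site/", s)))
    rep1 <- run_pipeline(cfg, sub)[[1L]]
    rows[[s]] <- data.frame(site_id = s, n = n_subjects(sub),
                            n_cases = n1,
                            mean_auc = rep1$fold_auc_mean,
                            sd_auc = rep1$fold_auc_sd,
                            stringsAsFactors = FALSE)
  }
  per_site <- do.call(rbind, rows)
  correlation <- if (!is.null(per_site) && nrow(per_site) >= 3L)
    site_size_performance_correlation(per_site$mean_auc, per_site$n)
  else NULL
  list(per_site = per_site, correlation = correlation)
}
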
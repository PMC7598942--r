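#' Read / write run configurations
#'
#' A run configuration file is a structured YAML or JSON document whose
#' keys mirror the [run_config()] field names exactly; model specs appear
#' under `model_specs` as a list of `{family, pca, n_trees, seed}` records.
#' The format is chosen by file extension (`.yaml`/`.yml` needs the yaml
#' package; anything else is parsed as JSON).
#'
#' @param path file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- NULL
  if (!is.null(x$model_specs)) {
    ms <- x$model_specs
    if (is.data.frame(ms)) ms <- split(ms, seq_len(nrow(ms)))
    specs <- lapply(ms, function(s)
      model_spec(s$family, pca = isTRUE(as.logical(s$pca %||% FALSE)),
                 n_trees = as.integer(s$n_trees %||% 500L),
                 seed = as.integer(s$seed %||% x$seed)))
  }
  run_config(cv_scheme = x$cv_scheme %||% "site_stratified_fixed",
             n_folds = x$n_folds %||% 10L,
             n_repeats = x$n_repeats %||% 10L,
             model_specs = specs,
             feature_regime = x$feature_regime %||% "brain_plus_covariates",
             alpha = x$alpha %||% 0.05,
             n_comparisons = x$n_comparisons %||% 30L,
             missing_threshold = x$missing_threshold %||% 0.10,
             seed = x$seed)
}

#' @rdname read_run_config
#' @param config a [run_config()] to serialise (JSON).
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$model_specs <- lapply(config$model_specs, function(s)
    list(family = s$family, pca = s$pca, n_trees = s$n_trees,
         seed = s$seed))
  x$subgroup_contrast <- NULL  # closures are rebuilt via build_contrasts()
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}
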
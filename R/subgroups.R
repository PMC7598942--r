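#' Clinical subgroup contrast
#'
#' A named pair of disjoint group filters over subject rows.  Group A is
#' the positive class (label 1) in downstream classification.  The
#' canonical clinical thresholds are: symptom severity low when
#' YBOCS <= 24 and high when YBOCS > 24; age of onset early when < 18
#' years and late when >= 18; illness duration short when <= 7 years and
#' long when > 7.
#'
#' @param name contrast identifier.
#' @param filter_a,filter_b pure predicates `function(meta) logical`
#'   selecting group A (positive) and group B rows.
#' @param variable clinical variable the contrast splits on (or `NA`).
#' @param threshold threshold used (or `NA`).
#' @param population `"combined"`, `"adult"` or `"pediatric"`.
#' @return an object of class `contrast_spec`.
#' @export
contrast_spec <- function(name, filter_a, filter_b, variable = NA_character_,
                          threshold = NA_real_, population = "combined") {
  structure(list(name = name, filter_a = filter_a, filter_b = filter_b,
                 variable = variable, threshold = threshold,
                 population = population),
            class = "contrast_spec")
}

.is_case <- function(m) m$diagnosis == 1
.is_hc <- function(m) m$diagnosis == 0
.not_na <- function(v) !is.na(v)

# canonical dichotomies for the clinical variables
.clinical_split <- function(variable) {
  switch(variable,
         medicated = list(levels = c("unmedicated", "medicated"),
                          fn = function(m) ifelse(is.na(m$medicated), NA,
                                                  ifelse(m$medicated == 1,
                                                         "medicated",
                                                         "unmedicated"))),
         ybocs = list(levels = c("low_severity", "high_severity"),
                      fn = function(m) ifelse(is.na(m$ybocs), NA,
                                              ifelse(m$ybocs <= 24,
                                                     "low_severity",
                                                     "high_severity"))),
         age_of_onset = list(levels = c("early_onset", "late_onset"),
                             fn = function(m) ifelse(is.na(m$age_of_onset), NA,
                                                     ifelse(m$age_of_onset < 18,
                                                            "early_onset",
                                                            "late_onset"))),
         illness_duration = list(levels = c("short_duration", "long_duration"),
                                 fn = function(m)
                                   ifelse(is.na(m$illness_duration), NA,
                                          ifelse(m$illness_duration <= 7,
                                                 "short_duration",
                                                 "long_duration"))),
         stop("unknown clinical variable: ", variable))
}

#' Build the canonical clinical contrasts
#'
#' Emits: HC vs medicated / unmedicated and medicated vs unmedicated; HC vs
#' low / high severity and low vs high; HC vs early / late onset and early
#' vs late; HC vs short / long duration and short vs long.  Patients with
#' the stratification variable missing are excluded from that contrast
#' only.  With `adult_only_onset = TRUE` the onset contrasts are restricted
#' to adults (age >= 18), the population in which late onset can occur.
#'
#' @param table a [subject_table()] (used to check which clinical columns
#'   are available; contrasts for absent variables are omitted).
#' @param adult_only_onset restrict onset contrasts to adults.
#' @return named list of [contrast_spec()]s.
#' @export
build_contrasts <- function(table, adult_only_onset = FALSE) {
  m <- table$meta
  out <- list()
  for (variable in c("medicated", "ybocs", "age_of_onset",
                     "illness_duration")) {
    if (!variable %in% names(m)) next
    if (all(is.na(m[[variable]][.is_case(m)]))) next
    sp <- .clinical_split(variable)
    adult <- variable == "age_of_onset" && adult_only_onset
    gate <- if (adult) function(m) !is.na(m$age) & m$age >= 18
            else function(m) rep(TRUE, nrow(m))
    pop <- if (adult) "adult" else "combined"
    lv <- sp$levels
    # factory so each closure captures its own split rule and gate
    grp <- local({
      sp0 <- sp; gate0 <- gate
      function(level) {
        force(level)
        function(m) {
          v <- sp0$fn(m)
          .is_case(m) & !is.na(v) & v == level & gate0(m)
        }
      }
    })
    hc <- local({
      gate0 <- gate
      function(m) .is_hc(m) & gate0(m)
    })
    for (level in lv)
      out[[paste0("hc_vs_", level)]] <-
        contrast_spec(paste0("hc_vs_", level), grp(level), hc,
                      variable, population = pop)
    out[[paste(lv[2], "vs", lv[1], sep = "_")]] <-
      contrast_spec(paste(lv[2], "vs", lv[1], sep = "_"),
                    grp(lv[2]), grp(lv[1]), variable, population = pop)
  }
  out
}

#' Apply a contrast to a subject table
#'
#' Returns the rows of groups A and B with the diagnosis column recoded to
#' the contrast label (A = 1, B = 0), ready for [run_pipeline()].
#'
#' @param table a [subject_table()]. @param contrast a [contrast_spec()].
#' @return a relabelled `subject_table`.
#' @export
apply_contrast <- function(table, contrast) {
  stopifnot(inherits(contrast, "contrast_spec"))
  a <- contrast$filter_a(table$meta)
  b <- contrast$filter_b(table$meta)
  if (any(a & b))
    stop("contrast groups overlap in contrast '", contrast$name, "'")
  if (!any(a) || !any(b))
    stop("empty subgroup: contrast '", contrast$name, "' has an empty side")
  keep <- which(a | b)
  out <- subset_table(table, keep)
  out$meta$diagnosis <- as.integer(a[keep])
  out
}

#' Correlation screen over clinical variables
#'
#' Pairwise correlations among the patients' clinical variables with the
#' correlation type dispatched by variable type: phi for two dichotomous
#' variables, point-biserial for dichotomous-continuous pairs, and Pearson
#' for two continuous variables (all computed as the Pearson coefficient of
#' the coded variables, with the t-approximation p-value).  Rows are
#' pairwise complete; significance is Bonferroni-corrected over the number
#' of tested pairs.
#'
#' @param table a [subject_table()].
#' @param alpha family-wise level (default 0.05).
#' @param variables clinical columns to screen.
#' @return data.frame with `var1`, `var2`, `type`, `r`, `p`, `n`,
#'   `significant`; constant pairs are skipped with a warning.
#' @export
clinical_correlation_screen <- function(table, alpha = 0.05,
                                        variables = c("medicated", "ybocs",
                                                      "age_of_onset",
                                                      "illness_duration")) {
  m <- table$meta[table$meta$diagnosis == 1, , drop = FALSE]
  variables <- intersect(variables, names(m))
  if (length(variables) < 2L)
    stop("need at least two clinical variables to screen")
  is_dich <- function(v) all(stats::na.omit(v) %in% c(0, 1))
  rows <- list()
  for (i in seq_len(length(variables) - 1L))
    for (j in (i + 1L):length(variables)) {
      v1 <- variables[i]; v2 <- variables[j]
      x <- m[[v1]]; y <- m[[v2]]
      ok <- !is.na(x) & !is.na(y)
      type <- if (is_dich(x) && is_dich(y)) "phi"
              else if (is_dich(x) || is_dich(y)) "point_biserial"
              else "pearson"
      if (sum(ok) < 3L || length(unique(x[ok])) < 2L ||
          length(unique(y[ok])) < 2L) {
        warning("skipping constant or empty pair ", v1, " / ", v2)
        next
      }
      ct <- stats::cor.test(as.numeric(x[ok]), as.numeric(y[ok]),
                            method = "pearson")
      rows[[length(rows) + 1L]] <-
        data.frame(var1 = v1, var2 = v2, type = type,
                   r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
                   stringsAsFactors = FALSE)
    }
  out <- do.call(rbind, rows)
  out$significant <- bonferroni(out$p, alpha, nrow(out))
  out
}

#' Intersected-split sensitivity reruns
#'
#' Reruns HC-vs-patient-subgroup classifications after further splitting
#' patients on a correlated clinical variable: every cell of the crossed
#' split (e.g. medicated x short duration) is classified against HC with
#' the same scheme and models, alongside the unsplit contrasts, and the
#' AUC deltas are tabulated.  Cells below the minimum class size are
#' skipped and logged.
#'
#' @param table a [subject_table()].
#' @param config a [run_config()] (its `subgroup_contrast` is overridden).
#' @param primary_variable clinical variable defining the primary split
#'   (default `"medicated"`).
#' @param split_variable correlated variable for the intersected split
#'   (default `"illness_duration"`).
#' @param min_cell_size minimum subjects per class (default 50).
#' @return list with `comparison` (data.frame of AUCs and deltas),
#'   `reports` (all pipeline reports) and `skipped` (character log).
#' @export
sensitivity_reruns <- function(table, config,
                               primary_variable = "medicated",
                               split_variable = "illness_duration",
                               min_cell_size = 50L) {
  ps <- .clinical_split(primary_variable)
  ss <- .clinical_split(split_variable)
  m <- table$meta
  if (all(is.na(m[[split_variable]][.is_case(m)])))
    stop("split variable '", split_variable, "' is missing for all ",
         "patients; disable the sensitivity rerun")
  run_one <- function(contrast) {
    cfg <- config
    cfg$subgroup_contrast <- contrast
    run_pipeline(cfg, table)
  }
  reports <- list()
  rows <- list()
  skipped <- character(0)
  unsplit_auc <- stats::setNames(numeric(0), character(0))
  for (p_lv in ps$levels) {
    base <- contrast_spec(
      paste0("hc_vs_", p_lv),
      local({p_lv; function(m) {
        v <- ps$fn(m); .is_case(m) & !is.na(v) & v == p_lv
      }}),
      .is_hc, primary_variable)
    rep_base <- run_one(base)
    reports[[base$name]] <- rep_base
    for (mod in names(rep_base)) {
      unsplit_auc[paste(p_lv, mod)] <- rep_base[[mod]]$pooled_auc
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = base$name, model = mod, primary_level = p_lv,
        split_level = NA_character_,
        pooled_auc = rep_base[[mod]]$pooled_auc,
        delta_vs_unsplit = 0, stringsAsFactors = FALSE)
    }
    for (s_lv in ss$levels) {
      nm <- paste0("hc_vs_", p_lv, "_", s_lv)
      filt <- local({p_lv; s_lv; function(m) {
        vp <- ps$fn(m); vs <- ss$fn(m)
        .is_case(m) & !is.na(vp) & vp == p_lv & !is.na(vs) & vs == s_lv
      }})
      n_a <- sum(filt(m)); n_b <- sum(.is_hc(m))
      if (n_a < min_cell_size || n_b < min_cell_size) {
        skipped <- c(skipped, sprintf("%s: cell sizes %d/%d below %d",
                                      nm, n_a, n_b, min_cell_size))
        next
      }
      rep_cell <- run_one(contrast_spec(nm, filt, .is_hc, split_variable))
      reports[[nm]] <- rep_cell
      for (mod in names(rep_cell))
        rows[[length(rows) + 1L]] <- data.frame(
          contrast = nm, model = mod, primary_level = p_lv,
          split_level = s_lv, pooled_auc = rep_cell[[mod]]$pooled_auc,
          delta_vs_unsplit = rep_cell[[mod]]$pooled_auc -
            unsplit_auc[paste(p_lv, mod)],
          stringsAsFactors = FALSE)
    }
  }
  list(comparison = do.call(rbind, rows), reports = reports,
       skipped = skipped)
}

#' Export contrast definitions as a JSON manifest
#'
#' Records name, variable, threshold rule and population for each contrast
#' so external tables can reuse the exact filters.
#'
#' @param contrasts list of [contrast_spec()]s. @param path file path.
#' @return the path, invisibly.
#' @export
contrasts_to_json <- function(contrasts, path) {
  manifest <- lapply(contrasts, function(cs)
    list(name = cs$name, variable = cs$variable,
         threshold = cs$threshold, population = cs$population))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
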
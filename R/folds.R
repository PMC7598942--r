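#' Fold plans for site-aware cross-validation
#'
#' A `fold_plan` is an ordered list of train/test splits (subject ids) plus
#' scheme metadata.  Four designs are provided: site-stratified k-fold with
#' (near-)equal fold sizes, leave-one-site-out (LOSO), site-and-diagnosis
#' stratified folds whose test sizes are forced to match the LOSO test-size
#' multiset, and diagnosis-stratified repeated k-fold for single-site runs.
#'
#' @name fold_plan
NULL

.new_fold_plan <- function(scheme, folds, seed = NA_integer_, extra = list()) {
  structure(c(list(scheme = scheme, folds = folds,
                   seed = as.integer(seed)), extra),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) length(f$test), 1L)
  cat(sprintf("fold_plan [%s]: %d folds, test sizes %s\n", x$scheme,
              length(x$folds), paste(sizes, collapse = "/")))
  invisible(x)
}

#' Check the partition invariants of a fold plan
#'
#' Every subject must appear in exactly one test fold, no subject may sit in
#' both the train and test side of any fold, and every test set must be
#' non-empty.
#'
#' @param plan a `fold_plan`.
#' @param table the [subject_table()] the plan was built from.
#' @return `TRUE` invisibly; errors on the first violated invariant.
#' @export
validate_fold_plan <- function(plan, table) {
  ids <- table$meta$subject_id
  test_all <- unlist(lapply(plan$folds, `[[`, "test"))
  if (anyDuplicated(test_all))
    stop("a subject appears in more than one test fold")
  if (!setequal(test_all, ids))
    stop("test folds do not partition the cohort")
  for (f in plan$folds) {
    if (length(f$test) == 0L) stop("empty test fold")
    if (length(intersect(f$train, f$test)))
      stop("train and test sets overlap")
  }
  invisible(TRUE)
}

# Assign the members of stratification cells to k folds so that within each
# cell fold counts differ by <= 1 and, when `capacity` is NULL, global fold
# sizes differ by <= 1 (remainders always go to the currently least-filled
# folds).  With `capacity` given, folds are instead filled proportionally to
# remaining capacity and end up at exactly the requested sizes.
.stratified_assign <- function(cells, k, capacity = NULL) {
  n <- sum(lengths(cells))
  fold_of <- integer(n)
  if (is.null(capacity)) {
    totals <- integer(k)
    for (cn in names(sort(vapply(cells, length, 1L), decreasing = TRUE))) {
      idx <- cells[[cn]]
      idx <- if (length(idx) > 1L) sample(idx) else idx
      m <- length(idx)
      counts <- rep(m %/% k, k)
      r <- m %% k
      if (r > 0L) {
        pick <- order(totals, sample.int(k))[seq_len(r)]
        counts[pick] <- counts[pick] + 1L
      }
      totals <- totals + counts
      fold_of[idx] <- rep(seq_len(k), times = counts)[sample.int(m)]
    }
  } else {
    capr <- as.integer(capacity)
    for (cn in names(sort(vapply(cells, length, 1L), decreasing = TRUE))) {
      idx <- cells[[cn]]
      idx <- if (length(idx) > 1L) sample(idx) else idx
      m <- length(idx)
      ideal <- m * capr / sum(capr)
      counts <- pmin(floor(ideal), capr)
      r <- m - sum(counts)
      if (r > 0L) {
        frac <- ideal - floor(ideal)
        open <- which(capr > counts)
        pick <- open[order(-frac[open], sample.int(length(open)))][seq_len(r)]
        counts[pick] <- counts[pick] + 1L
      }
      capr <- capr - counts
      fold_of[idx] <- rep(seq_len(k), times = counts)[sample.int(m)]
    }
  }
  fold_of
}

.plan_from_assignment <- function(table, fold_of, k, scheme, seed,
                                  extra = list()) {
  ids <- table$meta$subject_id
  folds <- lapply(seq_len(k), function(f)
    list(train = ids[fold_of != f], test = ids[fold_of == f]))
  .new_fold_plan(scheme, folds, seed, extra)
}

#' Site-stratified k-fold plan
#'
#' Folds have globally near-equal sizes (difference at most one subject) and,
#' within every site-by-diagnosis cell, fold counts differing by at most one,
#' so each fold preserves the per-site and per-class composition of the
#' cohort as closely as integer counts allow.  Assignment is randomised under
#' `seed` with subjects stably ordered by id before shuffling.
#'
#' @param table a [subject_table()].
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return a `fold_plan` with scheme `"site_stratified_fixed"`.
#' @export
site_stratified_folds <- function(table, k = 10L, seed) {
  n <- n_subjects(table)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k = ", k, " exceeds the number of subjects (", n, ")")
  meta <- table$meta
  ord <- order(meta$subject_id)
  cell <- paste(meta$site_id, meta$diagnosis, sep = "\r")
  cells <- split(ord, cell[ord])
  with_seed(seed, "folds/site_stratified", {
    fold_of <- .stratified_assign(cells, k)
    .plan_from_assignment(table, fold_of, k, "site_stratified_fixed", seed)
  })
}

#' Leave-one-site-out plan
#'
#' One fold per site, the fold's test set being exactly that site's
#' subjects.  Deterministic; no seed involved.  Test sites containing a
#' single diagnosis class are flagged (`single_class_test`) so evaluation
#' can skip their AUC with a logged count.
#'
#' @param table a [subject_table()] with at least two sites.
#' @return a `fold_plan` with scheme `"loso"`.
#' @export
loso_folds <- function(table) {
  sites <- sort(unique(table$meta$site_id))
  if (length(sites) < 2L) stop("LOSO requires at least two sites")
  ids <- table$meta$subject_id
  folds <- lapply(sites, function(s) {
    test <- ids[table$meta$site_id == s]
    list(train = setdiff(ids, test), test = test)
  })
  single <- vapply(sites, function(s)
    length(unique(table$meta$diagnosis[table$meta$site_id == s])) < 2L,
    logical(1))
  .new_fold_plan("loso", folds, NA_integer_,
                 list(test_sites = sites,
                      single_class_test = unname(single)))
}

#' Size-matched stratified plan
#'
#' Builds as many folds as a LOSO plan, with exactly the same multiset of
#' test-fold sizes, but fills each fold by randomised site-then-diagnosis
#' stratified allocation so that folds mix sites.  This isolates the effect
#' of variable fold sizes from that of between-site heterogeneity.
#'
#' @param table the [subject_table()] the LOSO plan was derived from.
#' @param loso_plan the corresponding [loso_folds()] plan.
#' @param seed integer seed.
#' @return a `fold_plan` with scheme `"site_stratified_matched"`.
#' @export
matched_size_folds <- function(table, loso_plan, seed) {
  stopifnot(inherits(loso_plan, "fold_plan"), loso_plan$scheme == "loso")
  sizes <- vapply(loso_plan$folds, function(f) length(f$test), 1L)
  if (sum(sizes) != n_subjects(table))
    stop("loso_plan was not derived from this table")
  k <- length(sizes)
  meta <- table$meta
  ord <- order(meta$subject_id)
  cell <- paste(meta$site_id, meta$diagnosis, sep = "\r")
  cells <- split(ord, cell[ord])
  with_seed(seed, "folds/matched", {
    fold_of <- .stratified_assign(cells, k, capacity = sizes)
    .plan_from_assignment(table, fold_of, k, "site_stratified_matched", seed,
                          list(target_sizes = sizes))
  })
}

#' Repeated diagnosis-stratified k-fold plans
#'
#' For single-site evaluation: `repeats` independent diagnosis-stratified
#' k-fold partitions, each under its own derived seed.
#'
#' @param table a [subject_table()], typically restricted to one site.
#' @param k folds per repeat (default 5). @param repeats default 10.
#' @param seed integer seed.
#' @return list of `fold_plan`s, one per repeat.
#' @export
repeated_kfold <- function(table, k = 5L, repeats = 10L, seed) {
  n1 <- sum(table$meta$diagnosis == 1)
  n0 <- sum(table$meta$diagnosis == 0)
  if (n1 < k || n0 < k)
    stop("fewer than k = ", k, " cases or controls (", n1, "/", n0,
         "); use a smaller k")
  ord <- order(table$meta$subject_id)
  cells <- split(ord, table$meta$diagnosis[ord])
  lapply(seq_len(repeats), function(r)
    with_seed(seed, paste0("folds/repeat/", r), {
      fold_of <- .stratified_assign(cells, k)
      .plan_from_assignment(table, fold_of, k, "single_site_repeated", seed,
                            list(repeat_index = r))
    }))
}

#' Serialise / restore a fold plan as JSON
#'
#' The JSON records the scheme, seed and per-fold id lists, so any run can
#' be replayed exactly.
#'
#' @param plan a `fold_plan`. @param path file path.
#' @return `write_fold_plan()` returns `path` invisibly;
#'   `read_fold_plan()` the restored `fold_plan`.
#' @export
write_fold_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", na = "null")
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$folds <- lapply(seq_len(nrow_or_len(x$folds)), function(i)
    list(train = as.character(fold_field(x$folds, i, "train")),
         test = as.character(fold_field(x$folds, i, "test"))))
  seed <- if (is.null(x$seed)) NA_integer_ else as.integer(x$seed)
  .new_fold_plan(x$scheme, x$folds, seed,
                 x[setdiff(names(x), c("scheme", "folds", "seed"))])
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
fold_field <- function(folds, i, what) {
  if (is.data.frame(folds)) folds[[what]][[i]] else folds[[i]][[what]]
}
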
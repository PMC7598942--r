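#' Rank-based AUC
#'
#' The probability that a randomly chosen case scores above a randomly
#' chosen control, with ties counted half:
#' `AUC = (#{case > control} + 0.5 #{case == control}) / (n1 * n0)`,
#' computed through the mid-rank (Mann-Whitney) formulation.
#'
#' @param scores numeric decision scores, higher = more case-like.
#' @param labels 0/1 vector (1 = case), same length.
#' @return the AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: only one class present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mann-Whitney significance and Hanley-McNeil interval for an AUC
#'
#' `U = AUC * n1 * n0`.  The two-sided p-value comes from exact enumeration
#' of all label assignments when `n1 + n0 <= exact_limit` (default 12),
#' otherwise from the normal approximation with tie-corrected null variance
#' and a 0.5 continuity correction.  The confidence interval uses the
#' Hanley-McNeil variance estimate with normal quantiles, truncated to
#' `[0, 1]`.
#'
#' @inheritParams auc_rank
#' @param alpha confidence level is `1 - alpha` (default 0.05).
#' @param exact_limit largest `n1 + n0` for which the exact permutation
#'   null is enumerated.
#' @return list with `auc`, `U`, `p`, `ci` (length-2), `method`.
#' @export
mwu_auc_inference <- function(scores, labels, alpha = 0.05,
                              exact_limit = 12L) {
  labels <- as.integer(labels)
  a <- auc_rank(scores, labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  U <- a * n1 * n0
  N <- n1 + n0
  if (N <= exact_limit) {
    # enumerate every assignment of n1 case labels to the observed scores
    r <- rank(scores, ties.method = "average")
    combos <- utils::combn(N, n1)
    u_null <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- 2 * min(mean(u_null <= U + eps), mean(u_null >= U - eps))
    p <- min(p, 1)
    method <- "exact"
  } else {
    mu <- n1 * n0 / 2
    ties <- table(scores)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n0 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal"
  }
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  v <- (a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
    (n1 * n0)
  zq <- stats::qnorm(1 - alpha / 2)
  ci <- c(max(0, a - zq * sqrt(max(v, 0))), min(1, a + zq * sqrt(max(v, 0))))
  list(auc = a, U = U, p = p, ci = ci, method = method)
}

#' Bonferroni significance flags
#'
#' @param p numeric p-values.
#' @param alpha family-wise level (default 0.05).
#' @param m number of comparisons (e.g. 30 for 3 CV designs x 10
#'   classifiers).
#' @return logical vector: `p <= alpha / m`.
#' @export
bonferroni <- function(p, alpha = 0.05, m) {
  stopifnot(m >= 1)
  p <= alpha / m
}

#' Balanced accuracy, sensitivity and specificity at a threshold
#'
#' Hard labels are `score > threshold`; probability-type scores use 0.5 and
#' margin-type scores 0 (the pipeline records the rule per model family).
#'
#' @inheritParams auc_rank
#' @param threshold decision threshold.
#' @return list with `balanced_accuracy`, `sensitivity`, `specificity`.
#' @export
secondary_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("both classes must be present")
  pred <- as.integer(scores > threshold)
  sens <- mean(pred[labels == 1L] == 1L)
  spec <- mean(pred[labels == 0L] == 0L)
  list(balanced_accuracy = (sens + spec) / 2,
       sensitivity = sens, specificity = spec)
}

#' Spearman correlation between site size and site performance
#'
#' @param site_auc per-site mean AUC (averaged over folds and repeats).
#' @param site_n per-site subject counts.
#' @return list with `rho` (average-rank tie handling) and two-sided `p`.
#' @export
site_size_performance_correlation <- function(site_auc, site_n) {
  stopifnot(length(site_auc) == length(site_n))
  if (length(site_auc) < 3L) stop("need at least 3 sites")
  if (length(unique(site_auc)) < 2L || length(unique(site_n)) < 2L)
    stop("correlation undefined for constant input")
  ct <- suppressWarnings(stats::cor.test(site_n, site_auc,
                                         method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
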
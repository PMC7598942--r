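# Fixtures are built in code at test time.

# Hand-built table: explicit control over sites, diagnosis, clinical fields
# and a small feature block.  `features` defaults to standard-normal draws.
make_table <- function(site, diagnosis, n_features = 3, seed = 1,
                       age = NULL, sex = NULL, medicated = NULL,
                       ybocs = NULL, age_of_onset = NULL,
                       illness_duration = NULL, features = NULL) {
  n <- length(site)
  set.seed(seed)
  if (is.null(age)) age <- runif(n, 18, 65)
  if (is.null(sex)) sex <- rep_len(c("M", "F"), n)
  if (is.null(features)) {
    features <- matrix(rnorm(n * n_features), n, n_features)
    colnames(features) <- paste0("roi", seq_len(n_features), "_thickavg")
  }
  meta <- data.frame(subject_id = sprintf("s%03d", seq_len(n)),
                     site_id = site, diagnosis = diagnosis,
                     age = age, sex = sex, stringsAsFactors = FALSE)
  for (cn in c("medicated", "ybocs", "age_of_onset", "illness_duration")) {
    v <- get(cn)
    if (!is.null(v)) meta[[cn]] <- v
  }
  subject_table(meta, features)
}

# Small synthetic cohort for pipeline-level tests
small_cohort <- function(seed = 11, n_sites = 6, size = c(30, 60), ...) {
  generate_cohort(cohort_config(n_sites = n_sites, site_size_range = size,
                                seed = seed, ...))
}

# brute-force AUC by exhaustive pairwise comparison (independent oracle)
auc_bruteforce <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}
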
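#' Derive a stage-specific seed from a global seed
#'
#' A single user-supplied seed is expanded deterministically into independent
#' per-stage seeds so that, e.g., cohort generation, fold assignment, model
#' initialisation and permutation draws each consume their own stream.  The
#' rule is a small polynomial string hash of the stage label folded into the
#' global seed modulo a 31-bit prime, so derived seeds are portable R integers.
#'
#' @param seed integer global seed.
#' @param label character scalar naming the stage (e.g. `"folds"`,
#'   `"model/rfc"`, `"perm/7"`).  Different labels give (for practical
#'   purposes) unrelated seeds; identical labels always give the same seed.
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @examples
#' derive_seed(42, "folds")
#' derive_seed(42, "folds") == derive_seed(42L, "folds")
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label),
            length(label) == 1L)
  m <- 2147483629  # prime below 2^31
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% m
  s <- (as.double(seed) %% m) * 7919 %% m
  as.integer((s + h) %% (m - 1L) + 1L)
}

# run `expr` under a derived seed without disturbing the caller's RNG state
with_seed <- function(seed, label, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(derive_seed(seed, label))
  expr
}
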
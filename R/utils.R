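# Internal numeric and bookkeeping helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

mve_stop <- function(...) stop(..., call. = FALSE)

#' Derive a reproducible sub-seed for a named pipeline stage
#'
#' All randomness in the package flows from a single global seed; each stage
#' (cohort generation, splitting, masking, probe fitting, ...) draws from its
#' own substream so that rerunning one stage never perturbs another.  The
#' derived seed is a deterministic 31-bit integer.
#'
#' @param seed Global integer seed.
#' @param stage Character stage name, e.g. `"cohort"` or `"folds/rep2"`.
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @examples
#' derive_seed(1, "cohort")
#' derive_seed(1, "folds")
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(stage))
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 2147483647
  as.integer(((abs(as.numeric(seed)) %% 1048573) * 2039 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Gaussian-CDF GELU and its derivative (used by the encoder and discriminators)
gelu <- function(x) x * stats::pnorm(x)
dgelu <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# Row-wise numerically stable softmax; `keep` marks columns (keys) that may
# receive probability mass.  Fully masked rows would be degenerate; callers
# guarantee at least one valid key.
softmax_rows <- function(x, keep = NULL) {
  if (!is.null(keep) && any(!keep)) x[, !keep] <- -Inf
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / rowSums(e)
}

add_bias <- function(m, b) m + rep(b, each = nrow(m))

# Truncated-normal initialiser (+-2 sd), the conventional transformer init.
rtrunc_norm <- function(n, sd = 0.02) {
  lo <- stats::pnorm(-2); hi <- stats::pnorm(2)
  sd * stats::qnorm(lo + stats::runif(n) * (hi - lo))
}

check_prob_vector <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0))
    mve_stop(what, " must be a vector of nonnegative finite probabilities")
  if (abs(sum(p) - 1) > 1e-9)
    mve_stop(what, " must sum to 1 (got ", format(sum(p), digits = 12), ")")
  invisible(p)
}

# Cheap deterministic content hash for run records / sidecar metadata.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
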
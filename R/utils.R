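#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm rpois runif rbinom dist quantile integrate
#' @importFrom utils head tail
NULL

# single-knob reproducibility: one global seed fans out to per-stage seeds via a
# fixed string hash, keeping every derived seed inside the 32-bit integer range
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  codes <- utf8ToInt(label)
  h <- (seed %% 2147483647)
  for (k in codes) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0.", name))
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}
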
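# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library calls never perturb user-level randomness.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

#' Derive a stream seed from a master seed and a stage tag
#'
#' Every source of randomness in the package descends from one master seed via
#' this deterministic hash, so independent stages (splitting, initialisation,
#' negative sampling, per-pair noise) draw from decorrelated streams while the
#' whole run stays reproducible from a single integer.
#'
#' @param seed Master integer seed.
#' @param tag Character tag naming the consuming stage (e.g. `"init"`).
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1L, "split")
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647 # 2^31 - 1, keeps everything in integer range
  h <- as.double(abs(seed) %% m)
  for (ch in utf8ToInt(tag)) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

clip_to_bounds <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(n) {
  is.numeric(n) && length(n) == 1L && is.finite(n) && n >= 0 && n == floor(n)
}

stop_input <- function(...) stop(..., call. = FALSE)
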
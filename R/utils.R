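#' @importFrom rlang abort warn %||%
#' @importFrom stats predict rnorm runif setNames
#' @importFrom utils head read.csv write.csv
NULL

# Deterministic 25-bit polynomial hash of an integer vector.  Kept well below
# 2^31 so all arithmetic is exact in doubles on every platform.
HASH_PRIME <- 33554393L

hash_ints <- function(x) {
  h <- 2166136
  for (v in x) h <- (h * 31 + v) %% HASH_PRIME
  as.integer(h)
}

# Fan a global seed out to a stable per-stage seed (< 2^31).
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  codes <- utf8ToInt(as.character(stage))
  as.integer((hash_ints(c(as.integer(seed %% HASH_PRIME), codes)) %% 2147483546L) + 1L)
}

stop_config <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "bbbalert_config_error")
}

`%notin%` <- function(x, table) !(x %in% table)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}
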
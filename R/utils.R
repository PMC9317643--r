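#' Derive a child RNG seed from a master seed
#'
#' Deterministically mixes a master seed with one or more integer indices so
#' that every stochastic stage of a simulation (replicate, biospecimen,
#' method, ...) gets its own reproducible stream. The result is always a
#' positive integer below 2^31, so it is safe for `set.seed()`.
#'
#' @param seed master seed (single integer).
#' @param ... integer indices identifying the stage (replicate number,
#'   matrix index, ...). Character values are hashed by their bytes.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.numeric(seed) %% m
  for (k in list(...)) {
    if (is.character(k)) k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
    for (ki in k) {
      # multiplier kept small enough that s * mult + ki stays exact in doubles
      s <- (s * 69069 + as.numeric(ki) + 1) %% m
    }
  }
  as.integer(s %% (m - 2)) + 1L
}

# run an expression under a temporary RNG state so callers' streams are
# untouched
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)
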
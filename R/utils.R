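# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = call.)
}

## Deterministic local RNG: run `expr` under `seed` without disturbing the
## caller's RNG stream. Used by every stochastic operation taking a seed.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  .assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
          "seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  expr
}

## Adjusted Rand index between two label vectors.
#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used to compare recovered cluster/scenario labels with planted truth.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A number in \[-1, 1\]; 1 means identical partitions.
#' @export
rand_index <- function(a, b) {
  .assert(length(a) == length(b), "label vectors must have equal length")
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  denom <- (ai + bj) / 2 - expected
  if (denom == 0) return(1)
  (nij - expected) / denom
}
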
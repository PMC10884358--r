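## Small internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Global field power of a scalp map
#'
#' GFP is the standard deviation of the potential across channels
#' (root-mean-square about the channel mean), the conventional per-sample
#' amplitude measure in scalp-field analysis.
#'
#' @param v numeric vector of per-channel potentials.
#' @return a single non-negative number.
#' @export
#' @examples
#' gfp(c(2, 0, 0, -2, 0, 0, 0, 0))
gfp <- function(v) {
  v <- as.numeric(v)
  sqrt(mean((v - mean(v))^2))
}

stop_ms <- function(...) stop(..., call. = FALSE)

## Clamp to [-1, 1] preserving dim attributes (pmin/pmax with a scalar
## first argument drop them).
clamp1 <- function(x) {
  d <- dim(x)
  x <- pmin(1, pmax(-1, x))
  dim(x) <- d
  x
}

## Integer-ish scalar check used by several validators.
is_count <- function(x, min = 1L) {
  length(x) == 1L && is.finite(x) && x >= min && abs(x - round(x)) < 1e-8
}
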
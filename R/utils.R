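# Shared helpers.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All stochastic operations in the package funnel
# through this so that a single integer seed makes a whole run reproducible.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# derive a child seed from a base seed, staying inside 32-bit integer range
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1103L + as.numeric(k) * 12345L) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x) pmin(pmax(x, 0), 1)

stopifnot_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image) || any(!is.finite(image))) {
    stop("`image` must be a finite numeric matrix", call. = FALSE)
  }
}
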
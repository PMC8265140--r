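# Internal weighted helpers. Weighted moments use the population
# (normalized-weight) form throughout: no n/(n-1) correction, so that
# C = (2/mu) cov_w(y, R) closes exactly against the decomposition identity.

wmean <- function(x, w) sum(w * x) / sum(w)

wcov <- function(x, y, w) {
  w <- w / sum(w)
  sum(w * (x - sum(w * x)) * (y - sum(w * y)))
}

wvar <- function(x, w) wcov(x, x, w)

check_weights <- function(w, n) {
  if (is.null(w)) w <- rep(1, n)
  if (length(w) != n) stop("weights must have length ", n, call. = FALSE)
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("weights must be positive and finite", call. = FALSE)
  }
  w
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
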
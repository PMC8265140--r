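#' Weighted concentration index and curve
#'
#' Fits the concentration index of a health variable against a socio-economic
#' ranking: \deqn{C = \frac{2}{\mu} \mathrm{cov}_w(y_i, R_i)} where \eqn{R_i}
#' is the weighted fractional rank in the wealth distribution, \eqn{\mu} the
#' weighted mean of the outcome, and the covariance uses normalized weights
#' (population form, no small-sample correction). Negative values indicate
#' concentration of the outcome among the poor (the concentration curve then
#' lies above the line of equality).
#'
#' Either `scores` (a socio-economic score per individual, from which ranks
#' are computed via [fractional_rank()]) or precomputed `ranks` must be
#' supplied.
#'
#' @param y numeric outcome per individual, binary or continuous; must have a
#'   strictly positive weighted mean.
#' @param scores socio-economic scores used to rank individuals
#'   (poorest to richest).
#' @param weights positive sampling weights; default equal.
#' @param ranks optional precomputed fractional ranks; overrides `scores` for
#'   the index but `scores` (if given) still order the curve.
#' @param stratum optional label stored on the result.
#' @return an object of class `"concindex"`: a list with elements `C` (the
#'   index), `mu` (weighted outcome mean), `n`, `curve` (data frame of
#'   cumulative population share vs cumulative outcome share, starting at
#'   (0,0)), and `stratum`.
#' @seealso [wagstaff()] for decomposing the index, [stratified_ci()] for
#'   per-stratum indices.
#' @examples
#' # all outcome mass in the poorest of four individuals
#' fit <- concindex(c(1, 0, 0, 0), scores = 1:4)
#' fit$C  # -0.75
#' @export
concindex <- function(y, scores = NULL, weights = NULL, ranks = NULL,
                      stratum = NULL) {
  n <- length(y)
  if (n == 0) stop("empty input", call. = FALSE)
  if (any(!is.finite(y))) stop("non-finite outcome values", call. = FALSE)
  w <- check_weights(weights, n)
  if (is.null(ranks)) {
    if (is.null(scores)) stop("supply either scores or ranks", call. = FALSE)
    ranks <- fractional_rank(scores, w)
  }
  if (length(ranks) != n) stop("ranks must match y in length", call. = FALSE)
  mu <- wmean(y, w)
  if (mu <= 0) stop("outcome has zero mean; index undefined", call. = FALSE)
  C <- 2 * wcov(y, ranks, w) / mu
  curve <- if (!is.null(scores)) concentration_curve(y, scores, w) else NULL
  structure(
    list(C = C, mu = mu, n = n, curve = curve, stratum = stratum),
    class = "concindex"
  )
}

#' Concentration curve coordinates
#'
#' Orders individuals poorest to richest and accumulates population share
#' (x) against outcome share (y). The curve starts at (0,0), ends at (1,1),
#' and lies above the diagonal exactly when the concentration index is
#' negative.
#'
#' @inheritParams concindex
#' @return data frame with columns `pop_share` and `outcome_share`.
#' @export
concentration_curve <- function(y, scores, weights = NULL) {
  n <- length(y)
  w <- check_weights(weights, n)
  mu <- wmean(y, w)
  if (mu <= 0) stop("outcome has zero mean; curve undefined", call. = FALSE)
  o <- order(scores)
  wn <- w[o] / sum(w)
  data.frame(
    pop_share = c(0, cumsum(wn)),
    outcome_share = c(0, cumsum(wn * y[o]) / mu)
  )
}

#' Concentration index by stratum
#'
#' Recomputes fractional ranks *within* each stratum and returns one
#' [concindex()] result per stratum (the pooled index is generally not the
#' average of stratum indices). Strata whose outcome mean is zero, whose
#' outcome is constant, or that lack two distinct wealth scores are skipped
#' and reported with a reason.
#'
#' @param data data frame of individuals.
#' @param stratum name of the stratum column (e.g. region or state).
#' @param outcome name of the binary/numeric outcome column.
#' @param score name of the wealth-score column.
#' @param weight optional name of the weight column.
#' @return list with `results` (named list of `concindex` objects),
#'   `skipped` (named character vector of reasons) and `table` (data frame of
#'   stratum, n, mu, C).
#' @export
stratified_ci <- function(data, stratum, outcome, score, weight = NULL) {
  for (col in c(stratum, outcome, score, weight)) {
    if (!col %in% names(data)) {
      stop("column not found: ", col, call. = FALSE)
    }
  }
  sp <- split(seq_len(nrow(data)), data[[stratum]])
  results <- list()
  skipped <- character()
  for (s in names(sp)) {
    idx <- sp[[s]]
    y <- data[[outcome]][idx]
    sc <- data[[score]][idx]
    w <- if (is.null(weight)) rep(1, length(idx)) else data[[weight]][idx]
    if (length(unique(sc)) < 2) {
      skipped[s] <- "fewer than 2 distinct wealth scores"
    } else if (wmean(y, w) <= 0) {
      skipped[s] <- "zero outcome mean"
    } else if (stats::var(y) == 0) {
      skipped[s] <- "zero-variance outcome"
    } else {
      results[[s]] <- concindex(y, scores = sc, weights = w, stratum = s)
    }
  }
  tab <- data.frame(
    stratum = names(results),
    n = vapply(results, function(r) r$n, numeric(1)),
    mu = vapply(results, function(r) r$mu, numeric(1)),
    C = vapply(results, function(r) r$C, numeric(1)),
    row.names = NULL
  )
  list(results = results, skipped = skipped, table = tab)
}

#' @export
print.concindex <- function(x, digits = 4, ...) {
  lab <- if (is.null(x$stratum)) "" else paste0(" [", x$stratum, "]")
  cat("Concentration index", lab, "\n", sep = "")
  cat("  C  = ", format(round(x$C, digits)),
      if (x$C < 0) "  (concentrated among the poor)" else
        if (x$C > 0) "  (concentrated among the rich)" else "", "\n", sep = "")
  cat("  mu = ", format(round(x$mu, digits)), "   n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' @export
summary.concindex <- function(object, ...) {
  out <- object
  # feasible range of C for a binary outcome with mean mu
  out$binary_bounds <- c(object$mu - 1, 1 - object$mu)
  class(out) <- c("summary.concindex", "concindex")
  out
}

#' @export
print.summary.concindex <- function(x, digits = 4, ...) {
  print.concindex(x, digits = digits)
  cat("  feasible C for binary outcome: [",
      format(round(x$binary_bounds[1], digits)), ", ",
      format(round(x$binary_bounds[2], digits)), "]\n", sep = "")
  invisible(x)
}

#' Plot a concentration curve
#'
#' Draws the concentration curve against the line of equality; a curve above
#' the diagonal means the outcome is concentrated among the poor.
#'
#' @param x a `concindex` object fitted with `scores` (so the curve exists).
#' @param ... passed to [graphics::plot()].
#' @export
plot.concindex <- function(x, ...) {
  if (is.null(x$curve)) stop("no curve stored; fit with scores =", call. = FALSE)
  graphics::plot(x$curve$pop_share, x$curve$outcome_share, type = "l",
                 xlab = "cumulative population share (poorest to richest)",
                 ylab = "cumulative outcome share",
                 main = sprintf("Concentration curve (C = %.3f)", x$C), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}
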
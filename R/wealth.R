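#' Household wealth scores from asset indicators
#'
#' Scores households on the first principal component of their (standardized)
#' asset indicators, the usual DHS-style wealth index construction. Each
#' asset column is centred and scaled to unit variance; zero-variance columns
#' are dropped with a warning. The sign of the component is fixed so that the
#' score correlates positively with the raw asset sum, i.e. asset-richer
#' households get higher scores.
#'
#' @param assets a numeric matrix or data frame, one row per household, one
#'   column per asset indicator (binary or coded). At least 2 assets and 3
#'   households are required.
#' @param household_id optional vector of household identifiers used to name
#'   the returned scores; defaults to row names / indices.
#' @return a named numeric vector of wealth scores, one per household.
#' @examples
#' a <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
#' asset_scores(a)
#' @export
asset_scores <- function(assets, household_id = NULL) {
  A <- as.matrix(assets)
  storage.mode(A) <- "double"
  if (anyNA(A)) stop("asset matrix contains missing values", call. = FALSE)
  if (ncol(A) < 2) stop("need at least 2 asset indicators", call. = FALSE)
  if (nrow(A) < 3) stop("need at least 3 households", call. = FALSE)
  v <- apply(A, 2, stats::var)
  keep <- v > 0
  if (!any(keep)) stop("no variation in assets", call. = FALSE)
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " zero-variance asset column(s): ",
            paste(colnames(A)[!keep] %||% which(!keep), collapse = ", "))
    A <- A[, keep, drop = FALSE]
    if (ncol(A) < 2) stop("fewer than 2 assets with variation", call. = FALSE)
  }
  Z <- scale(A)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  s <- pc$x[, 1]
  # orient: richer (more assets) => higher score
  orient <- sum(s * (rowSums(A) - mean(rowSums(A))))
  if (orient < 0) s <- -s
  names(s) <- household_id %||% rownames(A) %||% seq_len(nrow(A))
  s
}

#' Weighted fractional ranks in the wealth distribution
#'
#' Computes each individual's fractional rank \eqn{R_i \in (0,1)} in the
#' distribution of a socio-economic score, using normalized sampling weights
#' \eqn{\hat w_i}: after sorting ascending by score,
#' \eqn{R_i = \sum_{j<i} \hat w_j + \hat w_i / 2}. Tied scores receive the
#' weighted-average rank of their tie group (Lerman-Yitzhaki convention),
#' which makes downstream concentration indices invariant to within-tie
#' ordering. The weighted mean of the ranks is exactly 1/2.
#'
#' @param scores numeric vector of socio-economic scores (finite).
#' @param weights positive sampling weights; default equal weights.
#' @return numeric vector of fractional ranks, same order as the input.
#' @examples
#' fractional_rank(c(10, 20, 30, 40))           # 0.125 0.375 0.625 0.875
#' fractional_rank(c(1, 2), weights = c(1, 3))  # 0.125 0.625
#' @export
fractional_rank <- function(scores, weights = NULL) {
  n <- length(scores)
  if (n == 0) stop("empty input", call. = FALSE)
  bad <- which(!is.finite(scores))
  if (length(bad)) {
    stop("non-finite scores at rows: ", paste(utils::head(bad, 10), collapse = ", "),
         call. = FALSE)
  }
  w <- check_weights(weights, n)
  o <- order(scores)
  ws <- w[o] / sum(w)
  ss <- scores[o]
  grp <- cumsum(!duplicated(ss))
  gw <- as.vector(rowsum(ws, grp))
  # midpoint of each tie group's weight span = weighted-average rank in group
  rg <- cumsum(gw) - gw / 2
  R <- numeric(n)
  R[o] <- rg[grp]
  R
}

#' Population-weighted wealth quintiles
#'
#' Cuts the individual-level score distribution at the weighted quantiles
#' 0.2/0.4/0.6/0.8 so each quintile carries 20\% of the (weighted)
#' population, label 1 = poorest ... 5 = richest. All individuals sharing a
#' score share a quintile; an individual whose weight spans a cut point is
#' assigned the quintile of its cumulative-weight midpoint, so the 20\%
#' shares can break only at such a tie.
#'
#' @inheritParams fractional_rank
#' @return integer vector of quintile labels in 1..5.
#' @examples
#' assign_quintiles(1:5)          # 1 2 3 4 5
#' assign_quintiles(rep(1:5, 2))  # two individuals per quintile
#' @export
assign_quintiles <- function(scores, weights = NULL) {
  if (length(scores) == 0) stop("empty input", call. = FALSE)
  R <- fractional_rank(scores, weights)
  q <- 1L + findInterval(R, c(0.2, 0.4, 0.6, 0.8))
  q
}
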
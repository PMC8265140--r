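#' Weighted prevalence table by a background characteristic
#'
#' Tabulates, per level of a covariate: the weighted percentage of the
#' sample, the unweighted n, and the weighted prevalence (in percent) of a
#' binary outcome, with an overall row appended. A chi-square test of
#' independence is attached; for ordered covariates a Cochran-Armitage trend
#' test is attached as well.
#'
#' The chi-square is computed on weighted counts rescaled to the unweighted
#' total by default (p-values are approximate under clustering); set
#' `weighted_test = FALSE` to test raw counts. The trend test always uses
#' unweighted counts, the standard form.
#'
#' @param data data frame of individuals.
#' @param covariate name of a covariate column in `data`.
#' @param outcome name of the binary outcome column (default `"anaemic"`).
#' @param weight optional name of the weight column.
#' @param ordered if `TRUE`, also attach a Cochran-Armitage trend test with
#'   scores 1..k in level order.
#' @param weighted_test use weighted (rescaled) counts for the chi-square.
#' @return a data frame of class `"prevalence_table"` with columns `level`,
#'   `sample_pct`, `n`, `prevalence_pct`, plus attributes `chi_square` and
#'   (if ordered) `trend`.
#' @export
prevalence_by <- function(data, covariate, outcome = "anaemic",
                          weight = NULL, ordered = FALSE,
                          weighted_test = TRUE) {
  if (!covariate %in% names(data)) {
    stop("unknown covariate '", covariate, "'; available: ",
         paste(names(data), collapse = ", "), call. = FALSE)
  }
  if (!outcome %in% names(data)) {
    stop("unknown outcome column '", outcome, "'", call. = FALSE)
  }
  y <- data[[outcome]]
  g <- data[[covariate]]
  if (!is.factor(g)) g <- factor(g)
  w <- if (is.null(weight)) rep(1, nrow(data)) else data[[weight]]
  W <- sum(w)
  lev <- levels(g)
  tab <- data.frame(
    level = c(lev, "Total"),
    sample_pct = c(vapply(lev, function(l) 100 * sum(w[g == l]) / W,
                          numeric(1)), 100),
    n = c(vapply(lev, function(l) sum(g == l), numeric(1)), length(y)),
    prevalence_pct = c(vapply(lev, function(l) 100 * wmean(y[g == l], w[g == l]),
                              numeric(1)), 100 * wmean(y, w)),
    row.names = NULL
  )
  counts <- weighted_counts(y, g, w, weighted = weighted_test)
  attr(tab, "chi_square") <- tryCatch(chi_square_independence(counts),
                                      error = function(e) NULL)
  if (ordered) {
    cu <- weighted_counts(y, g, w, weighted = FALSE)
    attr(tab, "trend") <- cochran_armitage_trend(cu)
  }
  class(tab) <- c("prevalence_table", "data.frame")
  tab
}

# level x {non-case, case} counts; weighted counts are rescaled to the
# unweighted total so the chi-square keeps a nominal sample size
weighted_counts <- function(y, g, w, weighted = TRUE) {
  if (!weighted) w <- rep(1, length(y))
  m <- rbind(
    non_case = vapply(levels(g), function(l) sum(w[g == l & y == 0]),
                      numeric(1)),
    case = vapply(levels(g), function(l) sum(w[g == l & y == 1]), numeric(1))
  )
  m <- t(m)
  if (weighted) m <- m * length(y) / sum(m)
  m
}

#' @export
print.prevalence_table <- function(x, digits = 1, ...) {
  out <- as.data.frame(x)
  out$sample_pct <- round(out$sample_pct, digits)
  out$prevalence_pct <- round(out$prevalence_pct, digits)
  print(out, row.names = FALSE)
  cs <- attr(x, "chi_square")
  if (!is.null(cs)) {
    cat(sprintf("chi-square: X2 = %.3f, df = %d, p = %.3g\n",
                cs$statistic, cs$df, cs$p))
  }
  tr <- attr(x, "trend")
  if (!is.null(tr)) {
    cat(sprintf("Cochran-Armitage trend: Z = %.3f, p = %.3g\n", tr$Z, tr$p))
  }
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Classic Pearson test on a contingency table of counts; a zero row or
#' column margin makes the expected counts undefined and raises an error.
#'
#' @param counts matrix of (non-negative) counts, levels in rows.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square_independence <- function(counts) {
  m <- as.matrix(counts)
  if (any(m < 0)) stop("negative counts", call. = FALSE)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least a 2x2 table", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero row or column margin; expected counts undefined", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Cochran-Armitage test for trend in proportions
#'
#' Tests for a linear trend in case proportions across ordered levels:
#' \eqn{T = \sum_i s_i (n_{1i} - n_i \bar p)}, \eqn{\mathrm{Var}(T) =
#' \bar p (1 - \bar p) [\sum_i n_i s_i^2 - (\sum_i n_i s_i)^2 / N]},
#' \eqn{Z = T / \sqrt{\mathrm{Var}(T)}}, with a two-sided normal p-value.
#' The statistic is invariant to affine rescaling of the scores.
#'
#' @param counts matrix with ordered levels in rows and columns
#'   (non-case, case) — as produced inside [prevalence_by()] — or a
#'   two-column matrix `cbind(non_cases, cases)`.
#' @param scores numeric level scores; default `1..k`.
#' @return list with `Z`, `p` (two-sided), `T`, `varT`.
#' @export
cochran_armitage_trend <- function(counts, scores = NULL) {
  m <- as.matrix(counts)
  if (ncol(m) != 2) stop("counts must have two columns (non-case, case)",
                         call. = FALSE)
  if (nrow(m) < 3) stop("need at least 3 ordered levels", call. = FALSE)
  s <- scores %||% seq_len(nrow(m))
  n_i <- rowSums(m)
  n1 <- m[, 2]
  N <- sum(n_i)
  pbar <- sum(n1) / N
  if (pbar <= 0 || pbar >= 1) {
    stop("no variation in outcome; trend test undefined", call. = FALSE)
  }
  T_stat <- sum(s * (n1 - n_i * pbar))
  varT <- pbar * (1 - pbar) * (sum(n_i * s^2) - sum(n_i * s)^2 / N)
  Z <- T_stat / sqrt(varT)
  list(Z = Z, p = 2 * stats::pnorm(-abs(Z)), T = T_stat, varT = varT)
}

#' Variance inflation factors
#'
#' For each column of a design matrix, \eqn{VIF_j = 1 / (1 - R^2_j)} where
#' \eqn{R^2_j} comes from an OLS regression of column j on all other columns
#' plus an intercept. Columns with VIF above 10 are flagged as collinear;
#' a perfectly collinear column is reported as `Inf` rather than erroring.
#'
#' @param X numeric matrix or data frame with at least two non-constant
#'   columns.
#' @param cutoff flag threshold, default 10.
#' @return data frame with columns `variable`, `vif`, `flag`.
#' @export
variance_inflation_factors <- function(X, cutoff = 10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  nonconst <- apply(X, 2, stats::var) > 0
  if (sum(nonconst) < 2) {
    stop("need at least 2 non-constant columns", call. = FALSE)
  }
  vifs <- vapply(seq_len(ncol(X)), function(j) {
    if (!nonconst[j]) return(NA_real_)
    others <- X[, setdiff(which(nonconst), j), drop = FALSE]
    fit <- stats::lm.fit(cbind(1, others), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(variable = colnames(X), vif = vifs,
             flag = !is.na(vifs) & vifs > cutoff, row.names = NULL)
}
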
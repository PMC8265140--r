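#' Wagstaff decomposition of the concentration index
#'
#' Decomposes the concentration index of a (typically binary) health outcome
#' into per-regressor contributions. A weighted linear probability model
#' \deqn{y_i = \alpha + \sum_k \beta_k x_{ki} + \varepsilon_i} is fitted by
#' weighted OLS, and the index then satisfies the exact identity
#' \deqn{C = \sum_k \left(\frac{\beta_k \bar x_k}{\mu}\right) C_k +
#'       \frac{GC_\varepsilon}{\mu}}
#' where \eqn{\bar x_k} is the weighted regressor mean, \eqn{\mu} the weighted
#' outcome mean, \eqn{\eta_k = \beta_k \bar x_k / \mu} the elasticity,
#' \eqn{C_k} the concentration index of regressor \eqn{k} against the same
#' fractional ranks, and the residual term the generalized concentration
#' index of the error scaled by \eqn{\mu}. The same weight vector and the
#' same ranks are used for the OLS fit, for \eqn{C} and for every \eqn{C_k};
#' this is what makes the identity close to float precision.
#'
#' The linear probability model (not logit marginal effects) is used because
#' the additive identity is exact only under OLS.
#'
#' @param x a model formula (outcome on the left, covariates on the right;
#'   factors are dummy-coded against their reference level), or a numeric
#'   regressor matrix for the default method.
#' @param ... passed to methods.
#' @return an object of class `"wagstaff"`; see Details.
#'
#' @details The returned object has components
#' \describe{
#'   \item{table}{per-regressor data frame: `variable` (covariate group),
#'     `term`, `coefficient`, `mean`, `elasticity`, `ci` (the regressor's
#'     concentration index \eqn{C_k}), `contribution` (\eqn{\eta_k C_k}) and
#'     `pct` (percentage contribution under the chosen denominator).}
#'   \item{explained_ci, actual_ci, residual}{the "calculated" (explained)
#'     index \eqn{\sum_k \eta_k C_k}, the actual index \eqn{C}, and their
#'     difference; `explained_ci + residual == actual_ci` exactly.}
#'   \item{residual_check}{\eqn{(2/\mu)\,\mathrm{cov}_w(\varepsilon, R)},
#'     stored as a consistency check against `residual`.}
#'   \item{mu, n, ranks, weights, fit}{outcome mean, sample size, fractional
#'     ranks, normalized weights and the underlying OLS fit.}
#' }
#'
#' @examples
#' d <- data.frame(y = c(1, 1, 0, 0), g = factor(c("a", "a", "b", "b")),
#'                 s = 1:4)
#' fit <- wagstaff(y ~ g, data = d, scores = d$s)
#' fit$actual_ci  # equals explained + residual
#' @seealso [concindex()], [percentage_contributions()],
#'   [group_contributions()]
#' @export
wagstaff <- function(x, ...) UseMethod("wagstaff")

#' @rdname wagstaff
#' @param data data frame containing the model variables.
#' @param scores wealth scores per individual: a numeric vector or the name
#'   of a column of `data`.
#' @param weights positive sampling weights (vector or column name);
#'   normalized internally to mean 1. Default: equal weights.
#' @param denominator denominator for percentage contributions:
#'   `"explained"` (default; percentages over all regressors sum to 100) or
#'   `"actual"`.
#' @export
wagstaff.formula <- function(x, data, scores, weights = NULL,
                             denominator = c("explained", "actual"), ...) {
  denominator <- match.arg(denominator)
  if (is.character(scores)) scores <- data[[scores]] %||%
      stop("scores column not found: ", scores, call. = FALSE)
  if (is.character(weights)) weights <- data[[weights]] %||%
      stop("weights column not found: ", weights, call. = FALSE)
  mf <- stats::model.frame(x, data, na.action = stats::na.pass)
  keep <- stats::complete.cases(mf) & is.finite(scores)
  if (!is.null(weights)) keep <- keep & is.finite(weights)
  if (!all(keep)) {
    mf <- mf[keep, , drop = FALSE]
    scores <- scores[keep]
    if (!is.null(weights)) weights <- weights[keep]
  }
  mt <- attr(mf, "terms")
  y <- stats::model.response(mf)
  mm <- stats::model.matrix(mt, mf)
  res <- wagstaff_core(y, mm, scores, weights, denominator,
                       term_labels = attr(mt, "term.labels"),
                       assign = attr(mm, "assign"),
                       dropped = sum(!keep))
  res$call <- match.call()
  res$terms <- mt
  res$xlevels <- stats::.getXlevels(mt, mf)
  res
}

#' @rdname wagstaff
#' @param y numeric outcome vector (for the default method).
#' @export
wagstaff.default <- function(x, y, scores, weights = NULL,
                             denominator = c("explained", "actual"), ...) {
  denominator <- match.arg(denominator)
  X <- as.matrix(x)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  mm <- cbind(`(Intercept)` = 1, X)
  res <- wagstaff_core(y, mm, scores, weights, denominator,
                       term_labels = colnames(X),
                       assign = c(0L, seq_len(ncol(X))), dropped = 0L)
  res$call <- match.call()
  res
}

wagstaff_core <- function(y, mm, scores, weights, denominator,
                          term_labels, assign, dropped) {
  n <- length(y)
  if (n == 0) stop("empty input", call. = FALSE)
  w <- check_weights(weights, n)
  w <- w / mean(w)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  mu <- wmean(y, w)
  if (mu <= 0) stop("outcome has zero mean; index undefined", call. = FALSE)
  ranks <- fractional_rank(scores, w)

  fit <- stats::lm.wfit(mm, y, w)
  beta <- fit$coefficients
  eps <- fit$residuals

  X <- mm[, -1, drop = FALSE]
  k_assign <- assign[-1]
  beta_k <- beta[-1]
  xbar <- apply(X, 2, wmean, w = w)
  cov_xr <- apply(X, 2, wcov, y = ranks, w = w)
  elasticity <- beta_k * xbar / mu
  ck <- ifelse(xbar != 0, 2 * cov_xr / xbar, NA_real_)
  contribution <- 2 * beta_k * cov_xr / mu

  actual <- 2 * wcov(y, ranks, w) / mu
  explained <- sum(contribution)
  residual <- actual - explained
  residual_check <- 2 * wcov(eps, ranks, w) / mu

  denom <- if (denominator == "explained") explained else actual
  tab <- data.frame(
    variable = term_labels[k_assign],
    term = colnames(X),
    coefficient = unname(beta_k),
    mean = unname(xbar),
    elasticity = unname(elasticity),
    ci = unname(ck),
    contribution = unname(contribution),
    pct = if (denom != 0) 100 * unname(contribution) / denom else NA_real_,
    row.names = NULL
  )

  structure(
    list(table = tab, explained_ci = explained, actual_ci = actual,
         residual = residual, residual_check = residual_check,
         mu = mu, n = n, dropped = dropped, denominator = denominator,
         ranks = ranks, weights = w,
         coefficients = beta, fit = fit),
    class = "wagstaff"
  )
}

#' Percentage contributions from a Wagstaff decomposition
#'
#' Expresses each regressor's absolute contribution \eqn{\eta_k C_k} as a
#' percentage of either the explained ("calculated") index — under which the
#' regressor percentages sum to 100 — or the actual index.
#'
#' @param object a [wagstaff()] fit.
#' @param denominator `"explained"` (default) or `"actual"`.
#' @return named numeric vector of percentages, one per regressor.
#' @export
percentage_contributions <- function(object,
                                     denominator = c("explained", "actual")) {
  stopifnot(inherits(object, "wagstaff"))
  denominator <- match.arg(denominator)
  denom <- if (denominator == "explained") object$explained_ci else
    object$actual_ci
  if (denom == 0) stop("zero denominator", call. = FALSE)
  stats::setNames(100 * object$table$contribution / denom, object$table$term)
}

#' Covariate-group totals of decomposition contributions
#'
#' Sums absolute and percentage contributions over the dummy columns of each
#' covariate (e.g. all wealth-quintile dummies), the usual group subtotals of
#' a decomposition table. By default the grouping follows the model terms; a
#' custom grouping must partition the regressor columns.
#'
#' @param object a [wagstaff()] fit.
#' @param grouping optional named list mapping group name to a character
#'   vector of regressor (`term`) names; must assign each term at most once.
#'   Terms not mentioned are ignored.
#' @param denominator `"explained"` (default) or `"actual"`.
#' @return data frame with columns `group`, `contribution`, `pct`.
#' @export
group_contributions <- function(object, grouping = NULL,
                                denominator = c("explained", "actual")) {
  stopifnot(inherits(object, "wagstaff"))
  denominator <- match.arg(denominator)
  pct <- percentage_contributions(object, denominator)
  tab <- object$table
  if (is.null(grouping)) {
    grouping <- split(tab$term, tab$variable)
    grouping <- grouping[unique(tab$variable)]  # preserve model order
  } else {
    all_terms <- unlist(grouping, use.names = FALSE)
    if (anyDuplicated(all_terms)) {
      stop("term assigned to two groups: ",
           paste(unique(all_terms[duplicated(all_terms)]), collapse = ", "),
           call. = FALSE)
    }
    if (!all(all_terms %in% tab$term)) {
      stop("unknown terms in grouping: ",
           paste(setdiff(all_terms, tab$term), collapse = ", "),
           call. = FALSE)
    }
  }
  data.frame(
    group = names(grouping),
    contribution = vapply(grouping, function(tt)
      sum(tab$contribution[tab$term %in% tt]), numeric(1)),
    pct = vapply(grouping, function(tt)
      sum(pct[tt]), numeric(1)),
    row.names = NULL
  )
}

#' @export
print.wagstaff <- function(x, digits = 3, ...) {
  cat("Wagstaff decomposition of the concentration index\n")
  if (!is.null(x$call)) {
    cat("Call: ", deparse(x$call), "\n", sep = "")
  }
  cat("n = ", x$n,
      if (x$dropped > 0) paste0(" (", x$dropped, " incomplete rows dropped)"),
      ",  weighted outcome mean = ", format(round(x$mu, 4)), "\n\n", sep = "")
  tab <- x$table
  out <- data.frame(
    variable = tab$variable, term = tab$term,
    coefficient = round(tab$coefficient, digits),
    elasticity = round(tab$elasticity, digits),
    CI = round(tab$ci, digits),
    contribution = round(tab$contribution, digits),
    pct = round(tab$pct, 1)
  )
  print(out, row.names = FALSE)
  cat("\nCalculated (explained) CI: ", format(round(x$explained_ci, digits)),
      "\nActual CI:                 ", format(round(x$actual_ci, digits)),
      "\nResidual:                  ", format(round(x$residual, digits)),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.wagstaff <- function(object, ...) {
  gc <- group_contributions(object)
  structure(list(fit = object, groups = gc),
            class = "summary.wagstaff")
}

#' @export
print.summary.wagstaff <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat("\nGroup totals (% of explained CI):\n")
  out <- x$groups
  out$contribution <- round(out$contribution, digits)
  out$pct <- round(out$pct, 1)
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
coef.wagstaff <- function(object, ...) object$coefficients

#' @export
residuals.wagstaff <- function(object, ...) object$fit$residuals

#' @export
predict.wagstaff <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fit$fitted.values)
  if (is.null(object$terms)) {
    stop("predict with newdata requires a formula fit", call. = FALSE)
  }
  mm <- stats::model.matrix(stats::delete.response(object$terms), newdata,
                            xlev = object$xlevels)
  drop(mm %*% object$coefficients)
}

#' Plot decomposition group contributions
#'
#' Horizontal bar chart of each covariate group's percentage contribution to
#' the explained concentration index.
#'
#' @param x a [wagstaff()] fit.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.wagstaff <- function(x, ...) {
  gc <- group_contributions(x)
  op <- graphics::par(mar = c(4, 8, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(gc$pct), names.arg = rev(gc$group), horiz = TRUE,
                    las = 1, xlab = "% of explained CI",
                    main = "Decomposition of the concentration index", ...)
  invisible(x)
}
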
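#' Survey-weighted logistic regression with odds ratios
#'
#' Fits a logistic model to a binary outcome by iteratively reweighted least
#' squares, maximizing the weighted log-likelihood
#' \eqn{\sum_i w_i [y_i \log p_i + (1 - y_i) \log(1 - p_i)]}. Weights are
#' treated as analytic (frequency-style) weights and normalized to mean 1,
#' so doubling every weight changes neither coefficients nor standard
#' errors. Standard errors come from the weighted information matrix
#' (dispersion fixed at 1); Wald 95\% intervals on the odds-ratio scale are
#' reported. Optionally, cluster-robust (sandwich) standard errors replace
#' them.
#'
#' @param data data frame of individuals.
#' @param outcome name of the binary outcome column.
#' @param covariates character vector of covariate column names; factors are
#'   dummy-coded against their reference level. Numeric columns enter
#'   linearly.
#' @param weights optional name of the weight column (or a numeric vector).
#' @param ref_levels optional named list covariate -> reference level, used
#'   to relevel factors before fitting.
#' @param robust if `TRUE`, use cluster-robust standard errors.
#' @param cluster name of the cluster-id column (required when
#'   `robust = TRUE`).
#' @return object of class `"wlogit"`: list with `table` (term, level,
#'   estimate, se, or, ci_lo, ci_hi, p, stars — reference rows excluded),
#'   `converged`, `n`, `fit` (the underlying `glm`).
#' @export
fit_weighted_logistic <- function(data, outcome, covariates, weights = NULL,
                                  ref_levels = NULL, robust = FALSE,
                                  cluster = NULL) {
  cov_cols <- setdiff(covariates, "1")  # "1" = intercept-only model
  missing_cols <- setdiff(c(outcome, cov_cols), names(data))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("outcome must have both classes present", call. = FALSE)
  }
  d <- droplevels(data[, c(outcome, cov_cols), drop = FALSE])
  for (nm in names(ref_levels %||% list())) {
    if (!nm %in% covariates) next
    d[[nm]] <- stats::relevel(factor(d[[nm]]), ref = ref_levels[[nm]])
  }
  w <- if (is.character(weights)) data[[weights]] else weights
  w <- check_weights(w, nrow(d))
  w <- w / mean(w)

  fml <- stats::reformulate(covariates, response = outcome)
  # binomial IRLS; non-integer weighted "successes" warning is expected and
  # harmless for analytic weights
  fit <- suppressWarnings(
    stats::glm(fml, data = d, family = stats::binomial(), weights = w,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  beta <- stats::coef(fit)
  big <- abs(beta[-1]) > 10
  if (any(big, na.rm = TRUE)) {
    stop("possible separation: diverging coefficient(s) for ",
         paste(names(beta[-1])[big], collapse = ", "), call. = FALSE)
  }
  vc <- if (robust) {
    if (is.null(cluster)) stop("robust = TRUE requires a cluster column",
                               call. = FALSE)
    sandwich::vcovCL(fit, cluster = data[[cluster]])
  } else {
    # information-matrix SEs at fixed dispersion 1
    summary(fit, dispersion = 1)$cov.scaled
  }
  se <- sqrt(diag(vc))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  stars <- ifelse(p < 0.001, "***", ifelse(p < 0.05, "**",
                  ifelse(p < 0.10, "*", "")))
  tab <- data.frame(
    term = names(beta),
    estimate = unname(beta),
    se = unname(se),
    or = exp(unname(beta)),
    ci_lo = exp(unname(beta - 1.96 * se)),
    ci_hi = exp(unname(beta + 1.96 * se)),
    p = unname(p),
    stars = unname(stars),
    row.names = NULL
  )
  structure(
    list(table = tab, converged = fit$converged, n = nrow(d),
         robust = robust, fit = fit),
    class = "wlogit"
  )
}

#' @export
print.wlogit <- function(x, digits = 3, ...) {
  cat("Weighted logistic regression (n = ", x$n, ")",
      if (!x$converged) "  [NOT CONVERGED]",
      if (x$robust) "  [cluster-robust SEs]", "\n\n", sep = "")
  tab <- x$table
  out <- data.frame(
    term = tab$term,
    OR = round(tab$or, digits),
    `95% CI` = sprintf("(%.*f-%.*f)", digits, tab$ci_lo, digits, tab$ci_hi),
    sig = tab$stars,
    check.names = FALSE
  )
  print(out[-1, , drop = FALSE], row.names = FALSE)
  cat("significance: *** p<0.001, ** p<0.05, * p<0.10\n")
  invisible(x)
}

#' @export
coef.wlogit <- function(object, ...) stats::coef(object$fit)

#' @export
summary.wlogit <- function(object, ...) {
  print(object)
  invisible(object)
}
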
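#' Configuration for the synthetic survey generator
#'
#' Builds and validates the configuration of [simulate_survey()], a
#' generator of NFHS-like two-stage cluster-sample microdata of adult men
#' with a binary anaemia outcome and planted socio-economic inequality.
#'
#' Defaults emulate the national survey this generator mimics: covariate
#' marginals follow the published sample profile (age, marital status,
#' education, mass-media exposure, BMI class, tobacco use, caste, religion,
#' residence, region), log odds-ratio signs follow the published adjusted
#' model (protective education/media/overweight wealth gradients; elevated
#' risk for underweight, rural, East region, ages 50-54), the intercept is
#' calibrated so overall prevalence is close to 23.3\%, and `wealth_effect`
#' is calibrated so the large-sample concentration index of the outcome is
#' close to -0.12 (pro-poor concentration).
#'
#' @param n_clusters number of primary sampling units (villages/blocks).
#' @param households_per_cluster households sampled per cluster.
#' @param member_rate men per household are `1 + Poisson(member_rate)`.
#' @param category_probs named list of per-covariate probability vectors;
#'   each must be non-negative and sum to 1 (renormalized exactly).
#' @param logit_intercept intercept of the outcome logit model.
#' @param logit_coefs named list (covariate -> named vector of per-level log
#'   odds ratios; omitted levels are the reference, coefficient 0).
#' @param asset_loadings loadings of the 10 binary asset indicators on the
#'   latent household affluence (length defines the number of assets, >= 2).
#' @param wealth_effect coefficient (<= 0 for pro-poor inequality) of the
#'   standardized household wealth score in the outcome logit.
#' @param cluster_sd standard deviation share of the cluster component of
#'   latent affluence, in `[0, 1)` (affluence is standardized overall).
#' @param weight_dispersion log-normal sigma of household sampling weights;
#'   0 gives a self-weighting sample. Weights are normalized to mean 1.
#' @param seed integer seed; all randomness flows from it.
#' @return an object of class `"sim_config"` (a validated list).
#' @examples
#' cfg <- sim_config(n_clusters = 20, households_per_cluster = 10, seed = 1)
#' @export
sim_config <- function(n_clusters = 560,
                       households_per_cluster = 50,
                       member_rate = 0.8,
                       category_probs = NULL,
                       logit_intercept = -0.90,
                       logit_coefs = NULL,
                       asset_loadings = seq(0.9, 1.8, length.out = 10),
                       wealth_effect = -0.28,
                       cluster_sd = 0.45,
                       weight_dispersion = 0.25,
                       seed = 1L) {
  probs <- default_category_probs()
  if (!is.null(category_probs)) {
    unknown <- setdiff(names(category_probs), names(probs))
    if (length(unknown)) {
      stop("invalid config: unknown covariate in category_probs: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    probs[names(category_probs)] <- category_probs
  }
  coefs <- default_logit_coefs()
  if (!is.null(logit_coefs)) {
    unknown <- setdiff(names(logit_coefs), names(coefs))
    if (length(unknown)) {
      stop("invalid config: unknown covariate in logit_coefs: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    coefs[names(logit_coefs)] <- logit_coefs
  }
  cfg <- structure(
    list(n_clusters = n_clusters,
         households_per_cluster = households_per_cluster,
         member_rate = member_rate,
         category_probs = probs,
         logit_intercept = logit_intercept,
         logit_coefs = coefs,
         asset_loadings = asset_loadings,
         wealth_effect = wealth_effect,
         cluster_sd = cluster_sd,
         weight_dispersion = weight_dispersion,
         seed = as.integer(seed)),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop("invalid config: field '", field, "' ", why, call. = FALSE)
  }
  for (f in c("n_clusters", "households_per_cluster")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v)) {
      bad(f, "must be a positive integer")
    }
  }
  if (!is.numeric(cfg$member_rate) || cfg$member_rate < 0) {
    bad("member_rate", "must be non-negative")
  }
  for (nm in names(cfg$category_probs)) {
    p <- cfg$category_probs[[nm]]
    if (any(p < 0)) bad("category_probs", paste0("(", nm, ") has negative entries"))
    if (abs(sum(p) - 1) > 1e-6) {
      bad("category_probs", paste0("(", nm, ") does not sum to 1"))
    }
    if (is.null(names(p))) bad("category_probs", paste0("(", nm, ") must be named"))
    cfg$category_probs[[nm]] <- p / sum(p)  # exact within 1e-12 after this
  }
  for (nm in names(cfg$logit_coefs)) {
    co <- cfg$logit_coefs[[nm]]
    if (length(co) && is.null(names(co))) {
      bad("logit_coefs", paste0("(", nm, ") must be named by level"))
    }
    extra <- setdiff(names(co), names(cfg$category_probs[[nm]]))
    if (length(extra)) {
      bad("logit_coefs", paste0("(", nm, ") has unknown level(s): ",
                                paste(extra, collapse = ", ")))
    }
  }
  if (!is.numeric(cfg$logit_intercept) || !is.finite(cfg$logit_intercept)) {
    bad("logit_intercept", "must be a finite number")
  }
  if (length(cfg$asset_loadings) < 2 || any(!is.finite(cfg$asset_loadings))) {
    bad("asset_loadings", "must be >= 2 finite loadings")
  }
  if (!is.numeric(cfg$wealth_effect) || !is.finite(cfg$wealth_effect)) {
    bad("wealth_effect", "must be a finite number")
  }
  if (cfg$cluster_sd < 0 || cfg$cluster_sd >= 1) {
    bad("cluster_sd", "must be in [0, 1)")
  }
  if (cfg$weight_dispersion < 0) {
    bad("weight_dispersion", "must be non-negative")
  }
  if (!is.finite(cfg$seed)) bad("seed", "must be an integer")
  cfg
}

# Published sample-profile marginals (renormalized to sum exactly to 1).
default_category_probs <- function() {
  norm <- function(p) p / sum(p)
  list(
    age       = norm(c("15-19" = 0.167, "20-29" = 0.291, "30-39" = 0.254,
                       "40-49" = 0.210, "50-54" = 0.078)),
    marital   = norm(c(never_married = 0.360, currently_married = 0.640)),
    education = norm(c(none = 0.131, primary = 0.127, secondary = 0.572,
                       higher = 0.171)),
    media     = norm(c(no_exposure = 0.080, exposure = 0.920)),
    bmi       = norm(c(underweight = 0.197, normal = 0.607,
                       overweight = 0.195)),
    tobacco   = norm(c(no = 0.542, yes = 0.458)),
    caste     = norm(c(scheduled_caste = 0.199, scheduled_tribe = 0.089,
                       obc = 0.438, other = 0.274)),
    religion  = norm(c(hindu = 0.819, muslim = 0.128, other = 0.053)),
    residence = norm(c(urban = 0.373, rural = 0.627)),
    region    = norm(c(north = 0.141, central = 0.220, east = 0.189,
                       northeast = 0.033, west = 0.181, south = 0.237))
  )
}

# Log odds ratios with the published signs/magnitudes; reference levels
# (first level of each covariate) carry coefficient 0 implicitly.
default_logit_coefs <- function() {
  list(
    age       = log(c("20-29" = 0.70, "30-39" = 0.77, "40-49" = 0.96,
                      "50-54" = 1.20)),
    marital   = log(c(currently_married = 0.99)),
    education = log(c(primary = 0.90, secondary = 0.83, higher = 0.71)),
    media     = log(c(exposure = 0.93)),
    bmi       = log(c(underweight = 1.51, overweight = 0.80)),
    tobacco   = log(c(yes = 0.92)),
    caste     = log(c(scheduled_caste = 0.97, scheduled_tribe = 1.33,
                      obc = 0.97)),
    religion  = log(c(muslim = 0.88, other = 0.97)),
    residence = log(c(rural = 1.12)),
    region    = log(c(central = 1.01, east = 1.40, northeast = 0.75,
                      west = 0.87, south = 0.93))
  )
}

#' @export
print.sim_config <- function(x, ...) {
  n_exp <- x$n_clusters * x$households_per_cluster * (1 + x$member_rate)
  cat("Synthetic survey configuration\n")
  cat("  clusters: ", x$n_clusters, " x ", x$households_per_cluster,
      " households, ~", round(n_exp), " individuals expected\n", sep = "")
  cat("  wealth_effect: ", x$wealth_effect,
      "  intercept: ", x$logit_intercept,
      "  seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate synthetic two-stage survey microdata
#'
#' Draws a two-stage cluster sample of men: clusters carry a region, a
#' residence type and a latent affluence component; households within a
#' cluster draw a latent affluence, ten binary asset indicators whose
#' ownership probability rises with affluence, a wealth score (first
#' principal component of the assets, shared by all household members) and a
#' log-normal sampling weight; individuals draw demographic covariates and
#' an anaemia outcome from `Bernoulli(logistic(intercept + covariate effects
#' + wealth_effect * standardized wealth score))`. Haemoglobin is then drawn
#' from a truncated normal on the matching side of 13.0 g/dL, so
#' `haemoglobin < 13` reproduces the binary outcome exactly.
#'
#' The generator is deterministic given the config seed and does not disturb
#' the caller's RNG state.
#'
#' @param config a [sim_config()] object.
#' @param n_clusters optional override of `config$n_clusters` (used to scale
#'   a draw up or down without touching the rest of the design).
#' @param seed optional override of `config$seed`.
#' @return a data frame, one row per individual, with columns `person_id`,
#'   `cluster_id`, `household_id`, `weight`, `haemoglobin`, `anaemic`, the
#'   covariate columns, `wealth_score`, `wealth_quintile`, the synthetic
#'   truth column `latent_affluence`, and `asset1..assetK`. The config is
#'   attached as attribute `"config"`.
#' @export
simulate_survey <- function(config, n_clusters = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  config <- validate_sim_config(config)
  K <- as.integer(n_clusters %||% config$n_clusters)
  seed <- as.integer(seed %||% config$seed)
  with_seed(seed, simulate_survey_impl(config, K))
}

simulate_survey_impl <- function(cfg, K) {
  H <- cfg$households_per_cluster
  n_hh <- K * H
  probs <- cfg$category_probs

  draw_cat <- function(nm, n) {
    p <- probs[[nm]]
    factor(sample(names(p), n, replace = TRUE, prob = p), levels = names(p))
  }

  # cluster level: region, residence, affluence component
  cl_region <- draw_cat("region", K)
  cl_residence <- draw_cat("residence", K)
  cl_aff <- stats::rnorm(K)

  # household level
  hh_cluster <- rep(seq_len(K), each = H)
  rho <- cfg$cluster_sd
  hh_aff <- rho * cl_aff[hh_cluster] + sqrt(1 - rho^2) * stats::rnorm(n_hh)

  # binary assets: ownership probability rises with affluence; intercepts
  # spread from common to rare assets
  L <- cfg$asset_loadings
  a0 <- seq(1.5, -1.5, length.out = length(L))
  assets <- vapply(seq_along(L), function(j) {
    stats::rbinom(n_hh, 1, stats::plogis(a0[j] + L[j] * hh_aff))
  }, numeric(n_hh))
  colnames(assets) <- paste0("asset", seq_along(L))

  hh_score <- asset_scores(assets, household_id = seq_len(n_hh))

  # household sampling weights: positive, right-skewed, mean 1
  wd <- cfg$weight_dispersion
  hh_weight <- if (wd > 0) stats::rlnorm(n_hh, -wd^2 / 2, wd) else rep(1, n_hh)

  # household caste/religion; individual-level members and covariates
  hh_caste <- draw_cat("caste", n_hh)
  hh_religion <- draw_cat("religion", n_hh)
  n_members <- 1L + stats::rpois(n_hh, cfg$member_rate)
  n <- sum(n_members)
  hh_of <- rep(seq_len(n_hh), n_members)

  d <- data.frame(
    person_id = seq_len(n),
    cluster_id = hh_cluster[hh_of],
    household_id = hh_of,
    weight = hh_weight[hh_of],
    age = draw_cat("age", n),
    marital = draw_cat("marital", n),
    education = draw_cat("education", n),
    media = draw_cat("media", n),
    bmi = draw_cat("bmi", n),
    tobacco = draw_cat("tobacco", n),
    caste = hh_caste[hh_of],
    religion = hh_religion[hh_of],
    residence = cl_residence[hh_cluster[hh_of]],
    region = cl_region[hh_cluster[hh_of]],
    wealth_score = unname(hh_score[hh_of]),
    latent_affluence = hh_aff[hh_of]
  )
  d$weight <- d$weight / mean(d$weight)

  # outcome logit: intercept + covariate effects + wealth gradient
  lp <- rep(cfg$logit_intercept, n)
  for (nm in names(cfg$logit_coefs)) {
    co <- cfg$logit_coefs[[nm]]
    if (!length(co)) next
    full <- stats::setNames(rep(0, nlevels(d[[nm]])), levels(d[[nm]]))
    full[names(co)] <- co
    lp <- lp + full[as.character(d[[nm]])]
  }
  zscore <- (d$wealth_score - mean(d$wealth_score)) / stats::sd(d$wealth_score)
  lp <- lp + cfg$wealth_effect * zscore
  d$anaemic <- stats::rbinom(n, 1, stats::plogis(lp))

  d$haemoglobin <- draw_haemoglobin(d$anaemic)
  d$wealth_quintile <- assign_quintiles(d$wealth_score, d$weight)

  d <- cbind(d, as.data.frame(assets[hh_of, , drop = FALSE],
                              row.names = seq_len(n)))
  attr(d, "config") <- cfg
  d
}

# Haemoglobin conditional on anaemia status: truncated normals on either
# side of the 13.0 g/dL cut, so thresholding reproduces the binary outcome
# exactly.
draw_haemoglobin <- function(anaemic, cut = 13.0) {
  n <- length(anaemic)
  hb <- numeric(n)
  rtrunc <- function(k, mean, sd, lo, hi) {
    plo <- stats::pnorm(lo, mean, sd)
    phi <- stats::pnorm(hi, mean, sd)
    stats::qnorm(plo + stats::runif(k) * (phi - plo), mean, sd)
  }
  k1 <- sum(anaemic == 1)
  if (k1) hb[anaemic == 1] <- pmin(rtrunc(k1, 11.5, 1.4, 5, cut),
                                   cut - 1e-9)
  k0 <- sum(anaemic == 0)
  if (k0) hb[anaemic == 0] <- pmax(rtrunc(k0, 14.8, 1.1, cut, 22), cut)
  hb
}

#' Ground truth of a synthetic configuration
#'
#' Computes the planted "truth" of a [sim_config()] by drawing one large
#' reference sample and measuring it: the weighted prevalence and the
#' large-sample concentration index of the outcome against the wealth score,
#' alongside the coefficients actually planted. The reference draw uses a
#' seed derived from (but distinct from) the config seed, so the truth is
#' not the analysis draw itself.
#'
#' @param config a [sim_config()] object.
#' @param n_reference target number of individuals in the reference draw;
#'   must be at least 1000 (small references give unstable truth).
#' @return object of class `"true_parameters"`: list with `prevalence`,
#'   `large_sample_ci`, `planted_logit_coefs` (including intercept and
#'   `wealth_effect`), and `n` (achieved reference size).
#' @export
planted_truth <- function(config, n_reference = 1e5) {
  stopifnot(inherits(config, "sim_config"))
  if (n_reference < 1000) {
    stop("n_reference must be >= 1000 (unstable truth below that)",
         call. = FALSE)
  }
  per_cluster <- config$households_per_cluster * (1 + config$member_rate)
  K <- max(1L, as.integer(ceiling(n_reference / per_cluster)))
  ref_seed <- (config$seed + 500009L) %% .Machine$integer.max
  d <- simulate_survey(config, n_clusters = K, seed = ref_seed)
  ci <- concindex(d$anaemic, scores = d$wealth_score, weights = d$weight)
  structure(
    list(prevalence = ci$mu,
         large_sample_ci = ci$C,
         planted_logit_coefs = c(
           config$logit_coefs,
           list(intercept = config$logit_intercept,
                wealth_effect = config$wealth_effect)),
         n = nrow(d)),
    class = "true_parameters"
  )
}

#' @export
print.true_parameters <- function(x, ...) {
  cat("Planted truth (reference draw, n = ", x$n, ")\n", sep = "")
  cat("  prevalence:       ", format(round(x$prevalence, 4)), "\n", sep = "")
  cat("  large-sample CI:  ", format(round(x$large_sample_ci, 4)), "\n",
      sep = "")
  invisible(x)
}

#' Write a synthetic survey and its truth sidecar
#'
#' `write_survey()` writes the microdata as UTF-8 CSV (header row, `.`
#' decimal separator); `write_truth()` writes the [planted_truth()] and the
#' full generating configuration as JSON.
#'
#' @param records data frame from [simulate_survey()].
#' @param path output file path.
#' @export
write_survey <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_survey
#' @param truth a [planted_truth()] object.
#' @param config the generating [sim_config()].
#' @export
write_truth <- function(truth, config, path) {
  jsonlite::write_json(
    list(truth = unclass(truth), config = unclass(config)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
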
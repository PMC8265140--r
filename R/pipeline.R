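#' Run the full inequality-analysis pipeline
#'
#' Configuration-driven end-to-end run: load (or simulate) survey microdata,
#' derive the wealth score / quintiles / fractional ranks, and emit a report
#' bundle of CSV tables — sample profile (`table1.csv`), weighted prevalence
#' with association tests (`table2.csv`), weighted logistic odds ratios
#' (`table3.csv`), Wagstaff decomposition (`table4.csv`), concentration
#' curve coordinates (`curves/*.csv`) and per-stratum concentration indices
#' (`stratum_ci.csv`) — plus a run log with the seed and row accounting.
#' Rows with missing values in any analysis variable are dropped
#' (complete-case analysis) and counted in the log.
#'
#' If any stage fails, files already written by this run are removed and the
#' error is re-raised with the stage name.
#'
#' @param config a list, or the path to a YAML file, with entries:
#'   exactly one of `input` (CSV path) or `simulation` (arguments for
#'   [sim_config()]); `roles` (named list: `outcome`, optionally
#'   `haemoglobin`, `weight`, `score` or `assets`, `covariates`,
#'   `ref_levels`, `stratum`); `output_dir`; `seed`; and optional `options`
#'   (`pct_denominator` = "explained"/"actual", `weighted_chisq` = TRUE).
#' @return invisibly, a list with the loaded data and fitted objects.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  written <- character()
  stage <- "validate"
  out <- tryCatch(
    run_pipeline_impl(config, track = function(p) written <<- c(written, p),
                      set_stage = function(s) stage <<- s),
    error = function(e) {
      for (p in written) unlink(p)
      stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  invisible(out)
}

run_pipeline_impl <- function(config, track, set_stage) {
  ## ---- validate ----
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulation)
  if (has_input == has_sim) {
    stop("config must contain exactly one of 'input' or 'simulation'")
  }
  roles <- config$roles %||% list()
  outdir <- config$output_dir %||% stop("config$output_dir is required")
  seed <- config$seed %||% 1L
  opts <- config$options %||% list()
  pct_denom <- opts$pct_denominator %||% "explained"
  weighted_chisq <- isTRUE(opts$weighted_chisq %||% TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "curves"), showWarnings = FALSE)

  logf <- file.path(outdir, "run_log.txt")
  log_lines <- c(
    paste0("svyineq pipeline run ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("R version: ", R.version.string),
    paste0("seed: ", seed)
  )
  emit <- function(path, df) {
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
    track(path)
  }

  ## ---- load or simulate ----
  set_stage("load")
  if (has_sim) {
    cfg <- do.call(sim_config, c(config$simulation, list(seed = seed)))
    d <- simulate_survey(cfg)
    truth <- planted_truth(cfg)
    emit(file.path(outdir, "data.csv"), d)
    write_truth(truth, cfg, file.path(outdir, "truth.json"))
    track(file.path(outdir, "truth.json"))
    roles_default <- list(
      outcome = "anaemic", haemoglobin = "haemoglobin", weight = "weight",
      score = "wealth_score", stratum = "region",
      covariates = c("age", "marital", "education", "media", "bmi",
                     "tobacco", "caste", "religion", "residence", "region",
                     "wealth_quintile")
    )
    roles <- utils::modifyList(roles_default, roles)
  } else {
    d <- utils::read.csv(config$input, stringsAsFactors = TRUE)
  }
  n_input <- nrow(d)

  outcome <- roles$outcome %||% stop("roles$outcome is required")
  covars <- roles$covariates %||% stop("roles$covariates is required")
  declared <- unlist(c(covars, roles$weight, roles$haemoglobin,
                       roles$score, roles$assets, roles$stratum))
  if (!outcome %in% names(d) && is.null(roles$haemoglobin)) {
    declared <- c(outcome, declared)  # not derivable either
  }
  absent <- setdiff(declared, names(d))
  if (length(absent)) stop("declared columns missing from data: ",
                           paste(absent, collapse = ", "))

  ## ---- derive ----
  set_stage("derive")
  if (!outcome %in% names(d)) {
    hbcol <- roles$haemoglobin %||%
      stop("outcome column absent and no haemoglobin column declared")
    d[[outcome]] <- classify_anaemia(d[[hbcol]])$anaemic
  }
  if (is.null(roles$score)) {
    if (is.null(roles$assets)) stop("declare either a score or asset columns")
    hh <- d[[roles$household %||% "household_id"]] %||% seq_len(nrow(d))
    A <- unique(cbind(hh = hh, d[roles$assets]))
    sc <- asset_scores(A[roles$assets], household_id = A$hh)
    d$wealth_score <- unname(sc[as.character(hh)])
    roles$score <- "wealth_score"
  }
  wcol <- roles$weight
  if (is.null(wcol)) {
    d$.w <- 1
    wcol <- ".w"
  }

  analysis_vars <- unique(c(outcome, covars, wcol, roles$score, roles$stratum))
  cc <- stats::complete.cases(d[analysis_vars])
  n_drop <- sum(!cc)
  d <- droplevels(d[cc, , drop = FALSE])
  log_lines <- c(log_lines,
                 paste0("input rows: ", n_input),
                 paste0("rows dropped (incomplete analysis variables): ",
                        n_drop),
                 paste0("rows analyzed: ", nrow(d)))
  stopifnot(n_input == nrow(d) + n_drop)

  d$wealth_quintile <- factor(assign_quintiles(d[[roles$score]], d[[wcol]]),
                              levels = 1:5)
  d$fractional_rank <- fractional_rank(d[[roles$score]], d[[wcol]])
  if (!"wealth_quintile" %in% covars) covars <- c(covars, "wealth_quintile")

  ## ---- table 1: profile ----
  set_stage("table1")
  t1 <- do.call(rbind, lapply(covars, function(v) {
    pt <- prevalence_by(d, v, outcome, wcol)
    data.frame(variable = v, level = pt$level, sample_pct = pt$sample_pct,
               n = pt$n)
  }))
  emit(file.path(outdir, "table1.csv"), t1)

  ## ---- table 2: prevalence + tests ----
  set_stage("table2")
  ordered_vars <- intersect(c("education", "wealth_quintile"), covars)
  t2 <- do.call(rbind, lapply(covars, function(v) {
    pt <- prevalence_by(d, v, outcome, wcol, ordered = v %in% ordered_vars,
                        weighted_test = weighted_chisq)
    cs <- attr(pt, "chi_square")
    tr <- attr(pt, "trend")
    data.frame(variable = v, level = pt$level,
               prevalence_pct = pt$prevalence_pct,
               chi_square_p = if (is.null(cs)) NA else cs$p,
               trend_p = if (is.null(tr)) NA else tr$p)
  }))
  emit(file.path(outdir, "table2.csv"), t2)

  ## ---- table 3: logistic ----
  set_stage("table3")
  m3 <- fit_weighted_logistic(d, outcome, covars, weights = wcol,
                              ref_levels = roles$ref_levels)
  emit(file.path(outdir, "table3.csv"), m3$table)

  ## ---- inequality ----
  set_stage("inequality")
  overall <- concindex(d[[outcome]], scores = d[[roles$score]],
                       weights = d[[wcol]])
  emit(file.path(outdir, "curves", "overall.csv"), overall$curve)
  strat <- NULL
  if (!is.null(roles$stratum)) {
    strat <- stratified_ci(d, roles$stratum, outcome, roles$score, wcol)
    emit(file.path(outdir, "stratum_ci.csv"), strat$table)
    for (s in names(strat$results)) {
      emit(file.path(outdir, "curves", paste0(make.names(s), ".csv")),
           strat$results[[s]]$curve)
    }
    if (length(strat$skipped)) {
      log_lines <- c(log_lines, paste0("stratum skipped: ",
                                       names(strat$skipped), " (",
                                       strat$skipped, ")"))
    }
  }

  ## ---- table 4: decomposition ----
  set_stage("table4")
  decomp_covars <- setdiff(covars, roles$stratum_only %||% character())
  fml <- stats::reformulate(decomp_covars, response = outcome)
  dd <- d
  for (nm in names(roles$ref_levels %||% list())) {
    if (nm %in% decomp_covars) {
      dd[[nm]] <- stats::relevel(factor(dd[[nm]]), ref = roles$ref_levels[[nm]])
    }
  }
  dd$wealth_quintile <- factor(dd$wealth_quintile)
  dd <- droplevels(dd)
  w4 <- wagstaff(fml, data = dd, scores = dd[[roles$score]],
                 weights = dd[[wcol]], denominator = pct_denom)
  gt <- group_contributions(w4, denominator = pct_denom)
  t4 <- w4$table
  t4$row_type <- "regressor"
  footer <- data.frame(
    variable = c("Calculated CI", "Actual CI", "Residual"),
    term = "", coefficient = NA, mean = NA, elasticity = NA, ci = NA,
    contribution = c(w4$explained_ci, w4$actual_ci, w4$residual),
    pct = NA, row_type = "footer"
  )
  groups <- data.frame(
    variable = gt$group, term = "", coefficient = NA, mean = NA,
    elasticity = NA, ci = NA, contribution = gt$contribution, pct = gt$pct,
    row_type = "group_total"
  )
  emit(file.path(outdir, "table4.csv"), rbind(t4, groups, footer))

  set_stage("log")
  log_lines <- c(log_lines,
                 sprintf("overall concentration index: %.6f", overall$C),
                 sprintf("weighted prevalence: %.4f", overall$mu))
  writeLines(log_lines, logf)
  track(logf)
  message(paste(log_lines, collapse = "\n"))

  list(data = d, table1 = t1, table2 = t2, logistic = m3,
       concindex = overall, stratified = strat, decomposition = w4,
       output_dir = outdir)
}
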
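# End-to-end analysis pipeline: descriptives and zygosity comparison,
# within-individual regression models, then ICE FALCON on the exposure-outcome
# pairs that screen as significant.

#' Define an analysis configuration
#'
#' @param input path of a long-format twin CSV, or a [twin_dataset] supplied
#'   directly via `data`.
#' @param data optional [twin_dataset] (used instead of `input`).
#' @param exposures,outcomes variable names; the two sets must be disjoint.
#' @param covariates adjustment covariates (default age and height).
#' @param alpha two-sided significance level for screening and
#'   classification.
#' @param standardize standardize exposures and outcomes to mean 0, SD 1
#'   before modelling (default `TRUE`, the reference analysis convention).
#' @param screen which stage-2 column qualifies a pair for ICE FALCON:
#'   `"either"` (default), `"univariable"` or `"mutually_adjusted"`.
#' @param method,n_boot,seed delta-inference controls (see
#'   [joint_delta_inference()]).
#' @param schema optional CSV column mapping for [read_twin_csv()].
#' @param output_dir optional directory for CSV/JSON outputs and the run log.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(input = NULL, data = NULL, exposures, outcomes,
                            covariates = c("age", "height"), alpha = 0.05,
                            standardize = TRUE,
                            screen = c("either", "univariable", "mutually_adjusted"),
                            method = c("stacked", "bootstrap"),
                            n_boot = 1000L, seed = NULL, schema = NULL,
                            output_dir = NULL) {
  screen <- match.arg(screen)
  method <- match.arg(method)
  if (length(intersect(exposures, outcomes)))
    stop("exposures and outcomes must be disjoint")
  if (is.null(input) && is.null(data)) stop("supply 'input' or 'data'")
  structure(list(input = input, data = data, exposures = exposures,
                 outcomes = outcomes, covariates = covariates, alpha = alpha,
                 standardize = standardize, screen = screen, method = method,
                 n_boot = n_boot, seed = seed, schema = schema,
                 output_dir = output_dir),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' @param path configuration file; keys mirror the arguments of
#'   [analysis_config()].
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(analysis_config, cfg)
}

#' Univariable and mutually adjusted within-individual models
#'
#' For one outcome: a covariate-adjusted pair-clustered GEE per exposure
#' (univariable column) and a single GEE including both exposures
#' concurrently (mutually adjusted column), the layout of a two-exposure
#' regression table.
#'
#' @param x a [twin_dataset].
#' @param exposures character vector of (typically two) exposures.
#' @param outcome outcome name.
#' @param covariates adjustment covariates.
#' @param working GEE working correlation.
#' @return data frame with one row per exposure: univariable and mutually
#'   adjusted b, SE, p and significance markers.
#' @export
mutually_adjusted_models <- function(x, exposures, outcome,
                                     covariates = c("age", "height"),
                                     working = "exchangeable") {
  stopifnot(inherits(x, "twin_dataset"))
  d <- drop_incomplete_pairs(x, c(exposures, outcome, covariates))
  dd <- as.data.frame(d)
  if (length(exposures) >= 2L) {
    cors <- stats::cor(dd[, exposures, drop = FALSE])
    off <- abs(cors[upper.tri(cors)])
    if (any(off > 0.99)) stop("exposures are collinear (|r| > 0.99)")
  }
  uni <- lapply(exposures, function(e) {
    f <- fit_gee(stats::reformulate(c(e, covariates), response = outcome),
                 dd, id = dd$pair_id, working = working)
    st <- summary_table(f)[e, ]
    c(b = st$estimate, se = st$robust_se, p = st$p)
  })
  uni <- do.call(rbind, uni)
  if (length(exposures) >= 2L) {
    fm <- fit_gee(stats::reformulate(c(exposures, covariates), response = outcome),
                  dd, id = dd$pair_id, working = working)
    stm <- summary_table(fm)[exposures, ]
    mut <- cbind(b = stm$estimate, se = stm$robust_se, p = stm$p)
  } else {
    mut <- uni
  }
  data.frame(outcome = outcome, exposure = exposures,
             b_uni = uni[, "b"], se_uni = uni[, "se"], p_uni = uni[, "p"],
             sig_uni = sig_stars(uni[, "p"]),
             b_adj = mut[, "b"], se_adj = mut[, "se"], p_adj = mut[, "p"],
             sig_adj = sig_stars(mut[, "p"]),
             n_pairs = n_pairs(d), row.names = NULL)
}

#' Run the full twin analysis pipeline
#'
#' Stage 1: per-trait descriptives (mean, SD by zygosity) with the
#' covariate-adjusted MZ-vs-DZ mean comparison. Stage 2: univariable and
#' mutually adjusted within-individual GEE models of every outcome on the
#' exposures. Stage 3: the ICE FALCON procedure, run only for the
#' exposure-outcome pairs that are significant in stage 2 at `alpha`
#' (screening column per `config$screen`); if no pair qualifies, stage 3 is
#' skipped with a notice. When `config$output_dir` is set, writes
#' `table1_descriptives.csv`, `table2_models.csv`, `table3_ice_falcon.csv`,
#' `results.json` and `run_log.txt`.
#'
#' @param config an [analysis_config()].
#' @return invisibly, a list with `table1`, `table2`, `table3`, `ice_falcon`
#'   (the fitted objects), `correlations` and `config`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  t0 <- Sys.time()
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg))
    message(msg)
  }

  d <- config$data %||% read_twin_csv(config$input, schema = config$schema,
                                      traits = c(config$exposures, config$outcomes),
                                      covariates = config$covariates)
  vars <- c(config$exposures, config$outcomes)
  d <- drop_incomplete_pairs(d, c(vars, config$covariates))
  note("analysis sample: %d complete pairs (%d removed)",
       n_pairs(d), attr(d, "n_pairs_removed"))
  if (config$standardize) d <- standardize_traits(d, vars)

  # stage 1 -- descriptives and zygosity comparison
  desc_vars <- c(config$covariates, vars)
  table1 <- do.call(rbind, lapply(desc_vars, function(tr)
    compare_group_means(d, tr, setdiff(config$covariates, tr))$table))
  note("stage 1 done: %d traits compared between zygosity groups", nrow(table1))

  corr <- tryCatch(correlation_table(d, traits = config$exposures,
                                     covariates = config$covariates),
                   error = function(e) { note("correlation table skipped: %s",
                                              conditionMessage(e)); NULL })

  # stage 2 -- within-individual models
  table2 <- do.call(rbind, lapply(config$outcomes, function(oc)
    mutually_adjusted_models(d, config$exposures, oc, config$covariates)))
  note("stage 2 done: %d outcome x exposure fits", nrow(table2))

  # stage 3 -- ICE FALCON on screened pairs
  qualifies <- switch(config$screen,
                      univariable = table2$p_uni < config$alpha,
                      mutually_adjusted = table2$p_adj < config$alpha,
                      either = table2$p_uni < config$alpha |
                               table2$p_adj < config$alpha)
  cand <- table2[qualifies, c("exposure", "outcome")]
  fits <- list()
  if (nrow(cand) == 0L) {
    note("stage 3 skipped: no exposure-outcome pair significant at alpha = %g",
         config$alpha)
    table3 <- NULL
  } else {
    fits <- lapply(seq_len(nrow(cand)), function(i)
      run_ice_falcon(d, cand$exposure[i], cand$outcome[i],
                     covariates = config$covariates, alpha = config$alpha,
                     method = config$method, n_boot = config$n_boot,
                     seed = if (!is.null(config$seed)) mix_seed(config$seed, i)))
    table3 <- ice_falcon_table(fits)
    note("stage 3 done: ICE FALCON on %d screened pair(s)", nrow(cand))
  }

  out <- list(table1 = table1, table2 = table2, table3 = table3,
              correlations = corr, ice_falcon = fits, config = config)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    wp <- function(obj, file) if (!is.null(obj))
      utils::write.csv(obj, file.path(config$output_dir, file), row.names = FALSE)
    wp(table1, "table1_descriptives.csv")
    wp(corr, "within_pair_correlations.csv")
    wp(table2, "table2_models.csv")
    wp(table3, "table3_ice_falcon.csv")
    jsonlite::write_json(
      list(n_pairs = n_pairs(d),
           alpha = config$alpha, screen = config$screen, seed = config$seed,
           table2 = table2, table3 = table3,
           labels = lapply(fits, `[[`, "label"),
           r_version = R.version.string,
           package_version = as.character(utils::packageVersion("icefalcon"))),
      file.path(config$output_dir, "results.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
    log_lines <- c(log_lines, sprintf("total elapsed: %.2f s",
                                      as.numeric(Sys.time() - t0, units = "secs")))
    writeLines(log_lines, file.path(config$output_dir, "run_log.txt"))
  }
  invisible(out)
}
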
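# Replication harness: bias, MSE, size and power of the ICE FALCON
# change statistics under chosen generative scenarios.

ice_stats <- c("beta_self", "beta_cotwin", "beta_self_adj", "beta_cotwin_adj",
               "delta_self", "delta_cotwin")

#' Run replicated ICE FALCON analyses under one scenario
#'
#' For each replicate: simulate a cohort from the scenario, run the
#' three-model procedure, and record every coefficient's estimate, model SE,
#' p-value and the interpretation label. Replicate seeds are derived from the
#' root seed with [mix_seed()], so replicate k is identical whether it is run
#' alone or as part of a longer run, and extending `n_reps` reproduces the
#' earlier replicates exactly. Bias and MSE are taken against the population
#' coefficients from [expected_coefficients()] (pooled group, matching
#' working correlation); the population value of both change statistics is
#' the difference of the corresponding population coefficients.
#'
#' @param scenario a [scenario_config()].
#' @param n_reps number of replicates (>= 100 for a meaningful summary;
#'   smaller values are allowed but warn).
#' @param seed root integer seed.
#' @param alpha significance level for the rejection-rate columns and for
#'   classification.
#' @param covariates covariates included in the fitted models (default age
#'   and height, as in the reference analysis).
#' @param method delta-SE method passed to [run_ice_falcon()] (`"stacked"`
#'   recommended inside replicates; `"bootstrap"` for spot checks).
#' @param n_boot bootstrap replicates when `method = "bootstrap"`.
#' @param keep_replicates keep the per-replicate estimates in the result.
#' @return a `simulation_summary`: list with `summary` (per-statistic data
#'   frame: truth, mean, bias, MSE, empirical SE, mean model SE, rejection
#'   rate), `labels` (classification counts), `n_failed`, and optionally
#'   `replicates`.
#' @export
run_replicates <- function(scenario, n_reps, seed, alpha = 0.05,
                           covariates = c("age", "height"),
                           method = c("stacked", "bootstrap"),
                           n_boot = 1000L, keep_replicates = TRUE) {
  method <- match.arg(method)
  if (n_reps < 100L) warning("fewer than 100 replicates: summaries will be noisy")
  truth_tab <- expected_coefficients(scenario)
  tp <- truth_tab[truth_tab$group == "pooled", ]
  truth <- c(beta_self = tp$beta_self, beta_cotwin = tp$beta_cotwin,
             beta_self_adj = tp$beta_self_adj, beta_cotwin_adj = tp$beta_cotwin_adj,
             delta_self = tp$beta_self - tp$beta_self_adj,
             delta_cotwin = tp$beta_cotwin - tp$beta_cotwin_adj)

  est <- se <- pv <- matrix(NA_real_, n_reps, length(ice_stats),
                            dimnames = list(NULL, ice_stats))
  labels <- character(n_reps)
  failed <- 0L
  for (k in seq_len(n_reps)) {
    res <- tryCatch({
      d <- simulate_twins(scenario, seed = mix_seed(seed, k))
      run_ice_falcon(d, scenario$exposure, scenario$outcome,
                     covariates = covariates, alpha = alpha, method = method,
                     n_boot = n_boot, seed = mix_seed(seed, n_reps + k))
    }, error = function(e) e)
    if (inherits(res, "error")) { failed <- failed + 1L; next }
    co <- res$coefficients
    est[k, ] <- co[ice_stats, "estimate"]
    se[k, ] <- co[ice_stats, "se"]
    pv[k, ] <- co[ice_stats, "p"]
    labels[k] <- res$label
  }
  if (failed > 0.05 * n_reps)
    stop(failed, " of ", n_reps, " replicate fits failed (> 5%)")
  ok <- !is.na(est[, 1])

  mean_est <- colMeans(est[ok, , drop = FALSE])
  bias <- mean_est - truth
  emp_var <- apply(est[ok, , drop = FALSE], 2, function(v) mean((v - mean(v))^2))
  summary <- data.frame(
    statistic = ice_stats,
    truth = unname(truth),
    mean = unname(mean_est),
    bias = unname(bias),
    mse = unname(bias^2 + emp_var),
    empirical_se = unname(sqrt(emp_var)),
    mean_model_se = unname(colMeans(se[ok, , drop = FALSE])),
    rejection_rate = unname(colMeans(pv[ok, , drop = FALSE] < alpha)),
    row.names = NULL)

  out <- list(scenario = scenario$label, config = scenario,
              n_reps = n_reps, n_failed = failed, alpha = alpha, seed = seed,
              summary = summary,
              labels = table(factor(labels[ok], levels = c(
                "consistent_with_causation", "consistent_with_familial_confounding",
                "mixed", "inconclusive"))))
  if (keep_replicates)
    out$replicates <- data.frame(replicate = which(ok), est[ok, , drop = FALSE],
                                 p = pv[ok, , drop = FALSE])
  class(out) <- "simulation_summary"
  out
}

#' @export
print.simulation_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Simulation summary '%s': %d replicates (%d failed), alpha = %.2f\n",
              x$scenario, x$n_reps, x$n_failed, x$alpha))
  s <- x$summary
  s[-1] <- lapply(s[-1], signif, digits)
  print(s, row.names = FALSE)
  cat("classification counts:\n")
  print(x$labels)
  invisible(x)
}

#' Compare simulation summaries across scenarios
#'
#' Tabulates bias and MSE of every statistic side by side for two or more
#' scenario summaries and, if an observed ICE FALCON result (or a named
#' coefficient quadruple) is supplied, scores each scenario by the distance
#' between the observed `(beta_self, beta_cotwin, beta_self_adj,
#' beta_cotwin_adj)` and the scenario's mean estimates, each component
#' standardized by the scenario's empirical SE. The scenario with the
#' smallest distance is flagged as the better-matching generative model.
#'
#' @param summaries list of `simulation_summary` objects with a common
#'   statistic set.
#' @param observed optional `ice_falcon` object or named numeric vector with
#'   the four coefficients.
#' @return list with `table` (long bias/MSE comparison), and when `observed`
#'   is given, `distances` and `best_match`.
#' @export
compare_scenarios <- function(summaries, observed = NULL) {
  if (length(summaries) < 2L) stop("need at least two summaries")
  stat_sets <- lapply(summaries, function(s) s$summary$statistic)
  if (!all(vapply(stat_sets, identical, TRUE, stat_sets[[1]])))
    stop("summaries have mismatched statistic sets")
  tab <- do.call(rbind, lapply(summaries, function(s)
    data.frame(scenario = s$scenario,
               s$summary[c("statistic", "truth", "bias", "mse",
                           "empirical_se", "rejection_rate")])))
  rownames(tab) <- NULL
  out <- list(table = tab)

  if (!is.null(observed)) {
    quad <- c("beta_self", "beta_cotwin", "beta_self_adj", "beta_cotwin_adj")
    obs <- if (inherits(observed, "ice_falcon"))
      stats::setNames(observed$coefficients[quad, "estimate"], quad)
    else unlist(observed)[quad]
    if (anyNA(obs)) stop("observed pattern must supply the four coefficients")
    dist <- vapply(summaries, function(s) {
      m <- s$summary
      mu <- stats::setNames(m$mean, m$statistic)[quad]
      sdv <- stats::setNames(m$empirical_se, m$statistic)[quad]
      sqrt(sum(((obs - mu) / pmax(sdv, 1e-12))^2))
    }, 1)
    names(dist) <- vapply(summaries, `[[`, "", "scenario")
    out$distances <- dist
    out$best_match <- names(dist)[which.min(dist)]
  }
  out
}
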
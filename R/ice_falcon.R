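# The three-model coefficient-change procedure on double-entered twin pairs.
#
# Model 1: y_self ~ x_self   + covariates   -> beta_self
# Model 2: y_self ~ x_cotwin + covariates   -> beta_cotwin
# Model 3: y_self ~ x_self + x_cotwin + covariates -> beta_self_adj, beta_cotwin_adj
#
# all fitted by GEE clustered on the pair with an exchangeable working
# correlation. A causal exposure attenuates the cross-pair cross-trait
# coefficient towards zero after adjustment (beta_cotwin > beta_cotwin_adj)
# while leaving the within-individual coefficient unchanged; familial
# confounding leaves the cross-pair coefficient significant with no material
# change. The change statistics delta_self = beta_self - beta_self_adj and
# delta_cotwin = beta_cotwin - beta_cotwin_adj get standard errors either from
# the stacked-estimating-equation joint sandwich (all three models' cluster
# scores stacked, so that Var(delta) = Var(b1) + Var(b3) - 2 Cov(b1, b3)) or
# from a cluster bootstrap resampling whole pairs.

ice_models <- function(table, covariates) {
  d <- as.data.frame(table)
  Z <- if (length(covariates)) as.matrix(d[, covariates, drop = FALSE]) else NULL
  one <- rep(1, nrow(d))
  X1 <- cbind(`(Intercept)` = one, x_self = d$x_self)
  X2 <- cbind(`(Intercept)` = one, x_cotwin = d$x_cotwin)
  X3 <- cbind(`(Intercept)` = one, x_self = d$x_self, x_cotwin = d$x_cotwin)
  if (!is.null(Z)) { X1 <- cbind(X1, Z); X2 <- cbind(X2, Z); X3 <- cbind(X3, Z) }
  list(y = d$y_self, X = list(X1, X2, X3), cluster = d$cluster_id)
}

fit_three_models <- function(ms, working = "exchangeable") {
  lapply(ms$X, function(X) gee_core(ms$y, X, ms$cluster, working = working))
}

# indices of (model, coefficient) inside the stacked parameter vector
stack_index <- function(fits) {
  sizes <- vapply(fits, function(f) length(f$coefficients), 1L)
  offs <- cumsum(c(0L, sizes))
  list(m1_self = offs[1] + 2L,
       m2_cotwin = offs[2] + 2L,
       m3_self = offs[3] + 2L,
       m3_cotwin = offs[3] + 3L)
}

wald_row <- function(est, se) {
  if (se == 0) {
    p <- if (abs(est) < 1e-12) 1 else 0
    z <- if (abs(est) < 1e-12) 0 else sign(est) * Inf
  } else {
    z <- est / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  c(estimate = est, se = se, z = z, p = p)
}

#' Joint inference on the coefficient changes across the three models
#'
#' Computes standard errors and two-sided p-values for the change statistics
#' `delta_self` and `delta_cotwin`. With `method = "stacked"` the estimating
#' functions of the three models are concatenated and the joint sandwich
#' covariance is formed from cluster-level scores, giving
#' `Var(delta) = Var(b_before) + Var(b_after) - 2 Cov(b_before, b_after)`.
#' With `method = "bootstrap"` whole pairs are resampled with replacement,
#' all three models are refitted per replicate, and the empirical SD of each
#' delta is used. Both methods then apply a normal-reference Wald test.
#'
#' @param table a `regression_table` from [build_regression_table()].
#' @param covariates covariate column names included in every model.
#' @param method `"stacked"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap replicates (>= 100) when `method = "bootstrap"`.
#' @param seed seed for the bootstrap resampling.
#' @param working working correlation passed to the GEE fits.
#' @return list with the three `fits`, the stacked coefficient vector and
#'   `joint_vcov` (stacked method), and `deltas`, a data frame with one row
#'   per change statistic (estimate, se, z, p).
#' @export
joint_delta_inference <- function(table, covariates = attr(table, "covariate_names"),
                                  method = c("stacked", "bootstrap"),
                                  n_boot = 1000L, seed = NULL,
                                  working = "exchangeable") {
  method <- match.arg(method)
  ms <- ice_models(table, covariates)
  fits <- fit_three_models(ms, working = working)
  ix <- stack_index(fits)
  est <- unlist(lapply(fits, function(f) unname(f$coefficients)))
  d_self <- est[ix$m1_self] - est[ix$m3_self]
  d_cotwin <- est[ix$m2_cotwin] - est[ix$m3_cotwin]

  joint_vcov <- NULL
  if (method == "stacked") {
    infl <- do.call(cbind, lapply(fits, `[[`, "influence"))
    joint_vcov <- crossprod(infl)
    vd <- function(i, j) joint_vcov[i, i] + joint_vcov[j, j] - 2 * joint_vcov[i, j]
    se_self <- sqrt(max(vd(ix$m1_self, ix$m3_self), 0))
    se_cotwin <- sqrt(max(vd(ix$m2_cotwin, ix$m3_cotwin), 0))
  } else {
    if (n_boot < 100L) stop("n_boot must be at least 100")
    np <- nrow(table) / 2L
    draws <- matrix(NA_real_, n_boot, 2L)
    y <- ms$y; Xl <- ms$X
    with_seed(seed, {
      for (b in seq_len(n_boot)) {
        pick <- sample.int(np, np, replace = TRUE)
        rows <- as.vector(rbind(2L * pick - 1L, 2L * pick))
        clus <- rep(seq_len(np), each = 2L)
        fb <- lapply(Xl, function(X)
          gee_core(y[rows], X[rows, , drop = FALSE], clus, working = working))
        eb <- unlist(lapply(fb, function(f) unname(f$coefficients)))
        draws[b, ] <- c(eb[ix$m1_self] - eb[ix$m3_self],
                        eb[ix$m2_cotwin] - eb[ix$m3_cotwin])
      }
    })
    se_self <- stats::sd(draws[, 1]); se_cotwin <- stats::sd(draws[, 2])
    if (!is.finite(se_self) || !is.finite(se_cotwin) ||
        (se_self == 0 && abs(d_self) > 1e-12) ||
        (se_cotwin == 0 && abs(d_cotwin) > 1e-12))
      stop("degenerate bootstrap variance for a change statistic")
  }

  deltas <- rbind(delta_self = wald_row(d_self, se_self),
                  delta_cotwin = wald_row(d_cotwin, se_cotwin))
  list(fits = fits, estimates = est, index = ix,
       joint_vcov = joint_vcov, method = method,
       deltas = as.data.frame(deltas))
}

#' Run the ICE FALCON three-model procedure
#'
#' Fits the within-individual, cross-pair cross-trait, and mutually adjusted
#' models by pair-clustered GEE, tests the changes in the coefficients before
#' and after mutual adjustment, and classifies the evidence pattern.
#'
#' @param x a [twin_dataset] or a prebuilt `regression_table`.
#' @param exposure,outcome variable names (ignored when `x` is already a
#'   regression table).
#' @param covariates adjustment covariates included in all models.
#' @param alpha two-sided significance level used by the classification rule.
#' @param method delta-SE method, `"stacked"` or `"bootstrap"`
#'   (see [joint_delta_inference()]).
#' @param n_boot,seed bootstrap controls.
#' @param working GEE working correlation.
#' @return an `ice_falcon` object. Component `coefficients` is a data frame
#'   with rows `beta_self`, `beta_cotwin`, `beta_self_adj`, `beta_cotwin_adj`,
#'   `delta_self`, `delta_cotwin` and columns estimate, se, z, p; `label` is
#'   the interpretation from [classify_ice_falcon()].
#' @export
#' @examples
#' d <- simulate_twins(causal_scenario(b = 0.4, n_mz = 200, n_dz = 100), seed = 2)
#' run_ice_falcon(d, "exposure", "outcome", covariates = c("age", "height"))
run_ice_falcon <- function(x, exposure, outcome,
                           covariates = c("age", "height"), alpha = 0.05,
                           method = c("stacked", "bootstrap"),
                           n_boot = 1000L, seed = NULL,
                           working = "exchangeable") {
  method <- match.arg(method)
  table <- if (inherits(x, "regression_table")) x
           else build_regression_table(x, outcome = outcome, exposure = exposure,
                                       covariates = covariates)
  covariates <- attr(table, "covariate_names")
  np <- nrow(table) / 2L
  if (np < 10L) stop("need at least 10 complete pairs (have ", np, ")")
  for (v in c("y_self", "x_self")) {
    vals <- table[[v]]
    # thresholds widen at small n so sampling noise does not trip the warning
    if (abs(mean(vals)) > 0.2 + 3 / sqrt(length(vals)) ||
        abs(stats::sd(vals) - 1) > 0.25 + 3 / sqrt(length(vals)))
      warning("variable behind '", v, "' does not look standardized ",
              "(mean ", signif(mean(vals), 2), ", sd ", signif(stats::sd(vals), 2),
              "); coefficients are on the raw scale")
  }

  ji <- tryCatch(
    joint_delta_inference(table, covariates = covariates, method = method,
                          n_boot = n_boot, seed = seed, working = working),
    error = function(e) stop("ICE FALCON model fitting failed: ",
                             conditionMessage(e), call. = FALSE))
  fits <- ji$fits
  pick <- function(m, coefname) {
    est <- fits[[m]]$coefficients[[coefname]]
    se <- sqrt(fits[[m]]$robust[coefname, coefname])
    wald_row(est, se)
  }
  co <- rbind(beta_self = pick(1, "x_self"),
              beta_cotwin = pick(2, "x_cotwin"),
              beta_self_adj = pick(3, "x_self"),
              beta_cotwin_adj = pick(3, "x_cotwin"),
              as.matrix(ji$deltas))
  co <- as.data.frame(co)

  res <- structure(list(
    coefficients = co,
    exposure = attr(table, "exposure_name"),
    outcome = attr(table, "outcome_name"),
    covariates = covariates,
    n_pairs = np,
    alpha = alpha,
    method = method,
    working_alpha = vapply(fits, `[[`, numeric(1), "alpha"),
    fits = fits,
    joint_vcov = ji$joint_vcov),
    class = "ice_falcon")
  res$label <- classify_ice_falcon(res, alpha = alpha)
  res
}

#' Classify an ICE FALCON result
#'
#' Codifies the qualitative reading of the three-model output as a pure
#' function of the component tests at level `alpha`:
#' * `consistent_with_causation` — the cross-pair coefficient changed
#'   significantly, the within-individual coefficient did not, and the
#'   adjusted cross-pair coefficient is indistinguishable from zero;
#' * `consistent_with_familial_confounding` — the adjusted cross-pair
#'   coefficient remains significant and its change is not significant;
#' * `mixed` — both the change and the adjusted cross-pair coefficient are
#'   significant;
#' * `inconclusive` — anything else.
#'
#' @param result an `ice_falcon` object, or a named list/vector with elements
#'   `p_delta_self`, `p_delta_cotwin`, `p_beta_cotwin_adj`.
#' @param alpha two-sided significance level.
#' @return a length-one character label.
#' @export
classify_ice_falcon <- function(result, alpha = 0.05) {
  p <- if (inherits(result, "ice_falcon")) {
    co <- result$coefficients
    c(p_delta_self = co["delta_self", "p"],
      p_delta_cotwin = co["delta_cotwin", "p"],
      p_beta_cotwin_adj = co["beta_cotwin_adj", "p"])
  } else {
    unlist(result)[c("p_delta_self", "p_delta_cotwin", "p_beta_cotwin_adj")]
  }
  if (anyNA(p)) stop("incomplete result: need p_delta_self, p_delta_cotwin, p_beta_cotwin_adj")
  sig <- p < alpha
  if (sig[["p_delta_cotwin"]] && sig[["p_beta_cotwin_adj"]]) "mixed"
  else if (sig[["p_delta_cotwin"]] && !sig[["p_delta_self"]] &&
           !sig[["p_beta_cotwin_adj"]]) "consistent_with_causation"
  else if (sig[["p_beta_cotwin_adj"]] && !sig[["p_delta_cotwin"]])
    "consistent_with_familial_confounding"
  else "inconclusive"
}

#' @export
print.ice_falcon <- function(x, digits = 3, ...) {
  cat(sprintf("ICE FALCON: %s -> %s (%d pairs, covariates: %s)\n",
              x$exposure, x$outcome, x$n_pairs,
              if (length(x$covariates)) paste(x$covariates, collapse = ", ") else "none"))
  co <- x$coefficients
  printed <- data.frame(estimate = round(co$estimate, digits),
                        se = round(co$se, digits),
                        p = signif(co$p, digits),
                        row.names = rownames(co))
  print(printed)
  cat(sprintf("interpretation at alpha = %.2f: %s (delta SEs: %s)\n",
              x$alpha, x$label, x$method))
  invisible(x)
}

#' Tabulate ICE FALCON results in the reporting layout
#'
#' Flattens one or more `ice_falcon` objects into the one-row-per-analysis
#' layout used for reporting: cross-pair coefficient before and after
#' adjustment (each with SE and p), the change with its p, the self
#' coefficients, and the interpretation label.
#'
#' @param ... `ice_falcon` objects (or one list of them).
#' @return a data frame.
#' @export
ice_falcon_table <- function(...) {
  objs <- list(...)
  if (length(objs) == 1L && !inherits(objs[[1]], "ice_falcon")) objs <- objs[[1]]
  rows <- lapply(objs, function(r) {
    co <- r$coefficients
    data.frame(
      exposure = r$exposure, outcome = r$outcome, n_pairs = r$n_pairs,
      beta_cotwin = co["beta_cotwin", "estimate"],
      se_cotwin = co["beta_cotwin", "se"],
      p_cotwin = co["beta_cotwin", "p"],
      beta_cotwin_adj = co["beta_cotwin_adj", "estimate"],
      se_cotwin_adj = co["beta_cotwin_adj", "se"],
      p_cotwin_adj = co["beta_cotwin_adj", "p"],
      change = co["delta_cotwin", "estimate"],
      p_change = co["delta_cotwin", "p"],
      beta_self = co["beta_self", "estimate"],
      p_self = co["beta_self", "p"],
      beta_self_adj = co["beta_self_adj", "estimate"],
      p_self_adj = co["beta_self_adj", "p"],
      label = r$label)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
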
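# ACE-structured bivariate twin-pair generator and its analytic oracles.
#
# Exposure X and outcome Y for each twin are built from additive-genetic (A),
# shared-environment (C) and unique-environment (E) factors under the classic
# twin assumptions: A factors correlate 1 within MZ and 0.5 within DZ pairs,
# C factors correlate 1 within both, E factors are independent. Loadings are
# on the SD scale, so a_x^2 + c_x^2 + e_x^2 = 1 makes X a standardized trait.
# The outcome adds an optional causal path b from the individual's own X, and
# familial confounding enters through the cross-trait factor correlations
# rho_a = corr(A_x, A_y) and rho_c = corr(C_x, C_y) within an individual.

#' Define a generative twin-model scenario
#'
#' Parameters of the bivariate ACE path model used by [simulate_twins()],
#' [implied_covariance()] and [expected_coefficients()]. Defaults describe the
#' reference cohort the package's simulations emulate: 98 MZ and 54 DZ female
#' pairs; an exposure (a body-composition trait) with additive-genetic
#' variance share 0.79 and no shared environment, so its within-pair
#' correlation is 0.79 in MZ and 0.395 in DZ pairs; an outcome (a bone trait)
#' residual with heritability 0.85; age mean 50.8 (SD 8.1) years shared
#' within a pair; height mean 162.7 (SD 5.9) cm with heritability 0.8.
#' Covariate slopes (per SD of the covariate) default to zero so the analytic
#' oracles stay closed-form.
#'
#' @param n_mz,n_dz numbers of MZ and DZ pairs.
#' @param a_x,c_x,e_x exposure loadings (SD scale); squares must sum to 1.
#' @param a_y,c_y,e_y outcome-residual loadings; squares must sum to 1.
#' @param b causal path coefficient from an individual's own exposure to
#'   their outcome.
#' @param rho_a,rho_c cross-trait correlations of the additive-genetic and
#'   shared-environment factors (familial confounding), each in \[-1, 1\].
#' @param slopes named numeric vector of per-SD covariate effects
#'   `c(age_x, age_y, height_x, height_y)`.
#' @param age_mean,age_sd,height_mean,height_sd,height_h2 covariate
#'   distribution parameters; age is identical within a pair, height is an
#'   additive-genetic trait with heritability `height_h2`.
#' @param exposure,outcome column names used in simulated datasets.
#' @param label optional scenario id used in reports.
#' @return a `scenario_config` object (validated list).
#' @export
#' @examples
#' scenario_config(b = 0.4)            # causal
#' scenario_config(rho_a = 0.6)        # genetic confounding
scenario_config <- function(n_mz = 98L, n_dz = 54L,
                            a_x = sqrt(0.79), c_x = 0, e_x = sqrt(0.21),
                            a_y = sqrt(0.85), c_y = 0, e_y = sqrt(0.15),
                            b = 0, rho_a = 0, rho_c = 0,
                            slopes = c(age_x = 0, age_y = 0,
                                       height_x = 0, height_y = 0),
                            age_mean = 50.8, age_sd = 8.1,
                            height_mean = 162.7, height_sd = 5.9,
                            height_h2 = 0.8,
                            exposure = "exposure", outcome = "outcome",
                            label = NULL) {
  sl <- c(age_x = 0, age_y = 0, height_x = 0, height_y = 0)
  sl[names(slopes)] <- slopes
  sc <- list(n_mz = as.integer(n_mz), n_dz = as.integer(n_dz),
             a_x = a_x, c_x = c_x, e_x = e_x,
             a_y = a_y, c_y = c_y, e_y = e_y,
             b = b, rho_a = rho_a, rho_c = rho_c, slopes = sl,
             age_mean = age_mean, age_sd = age_sd,
             height_mean = height_mean, height_sd = height_sd,
             height_h2 = height_h2,
             exposure = exposure, outcome = outcome,
             label = label %||% "scenario")
  if (sc$n_mz + sc$n_dz < 1L) stop("need at least one pair")
  for (u in list(c("a_x", "c_x", "e_x"), c("a_y", "c_y", "e_y"))) {
    s <- sum(vapply(u, function(k) sc[[k]]^2, 1))
    if (abs(s - 1) > 1e-10)
      stop("loadings ", paste(u, collapse = ", "),
           " must have squares summing to 1 (got ", format(s), ")")
  }
  if (abs(sc$rho_a) > 1 || abs(sc$rho_c) > 1) stop("rho_a, rho_c must lie in [-1, 1]")
  if (sc$height_h2 < 0 || sc$height_h2 > 1) stop("height_h2 must lie in [0, 1]")
  class(sc) <- "scenario_config"
  for (z in c("MZ", "DZ")) implied_covariance(sc, z)  # PSD check
  sc
}

#' Preset scenarios
#'
#' Thin wrappers over [scenario_config()] for the three generative regimes of
#' interest: a causal exposure (`b` nonzero, no confounding), familial
#' confounding through the genetic factors (`rho_a` nonzero, `b = 0`), and
#' the familial null (familial structure in both traits but no exposure-
#' outcome link), under which all four population coefficients are zero.
#'
#' @param b,rho_a,rho_c see [scenario_config()].
#' @param ... further arguments passed to [scenario_config()].
#' @return a `scenario_config`.
#' @export
causal_scenario <- function(b = 0.4, ...) {
  scenario_config(b = b, rho_a = 0, rho_c = 0, label = paste0("causal_b", b), ...)
}

#' @rdname causal_scenario
#' @export
confounding_scenario <- function(rho_a = 0.6, rho_c = 0, ...) {
  scenario_config(b = 0, rho_a = rho_a, rho_c = rho_c,
                  label = paste0("confounding_rhoA", rho_a,
                                 if (rho_c != 0) paste0("_rhoC", rho_c) else ""), ...)
}

#' @rdname causal_scenario
#' @export
null_scenario <- function(...) {
  scenario_config(b = 0, rho_a = 0, rho_c = 0, label = "familial_null", ...)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Twin scenario '%s': %d MZ + %d DZ pairs\n", x$label, x$n_mz, x$n_dz))
  cat(sprintf("  exposure ACE shares: %.2f/%.2f/%.2f; outcome: %.2f/%.2f/%.2f\n",
              x$a_x^2, x$c_x^2, x$e_x^2, x$a_y^2, x$c_y^2, x$e_y^2))
  cat(sprintf("  causal b = %g; confounding rho_a = %g, rho_c = %g\n",
              x$b, x$rho_a, x$rho_c))
  invisible(x)
}

r_a_of <- function(zygosity) if (zygosity == "MZ") 1 else 0.5

#' Implied covariance of the generative twin model
#'
#' Closed-form 4x4 covariance matrix of (X1, X2, Y1, Y2) for one zygosity,
#' assembled by path algebra from the scenario parameters, including the
#' marginal contribution of nonzero covariate slopes (age is perfectly shared
#' within a pair; height shares its additive-genetic fraction).
#'
#' @param scenario a [scenario_config()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return an `implied_covariance` object: list with `zygosity` and the 4x4
#'   `matrix` (dimnames X1, X2, Y1, Y2).
#' @export
implied_covariance <- function(scenario, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  s <- scenario
  rA <- r_a_of(zygosity)
  r_h <- s$height_h2 * rA          # within-pair correlation of height
  sl <- s$slopes

  cxx0 <- s$a_x^2 * rA + s$c_x^2   # cross-twin exposure covariance, base model
  Sxx <- matrix(c(1 + sl["age_x"]^2 + sl["height_x"]^2,
                  cxx0 + sl["age_x"]^2 + sl["height_x"]^2 * r_h,
                  cxx0 + sl["age_x"]^2 + sl["height_x"]^2 * r_h,
                  1 + sl["age_x"]^2 + sl["height_x"]^2), 2, 2)
  k_w <- s$a_x * s$a_y * s$rho_a + s$c_x * s$c_y * s$rho_c        # cov(X_j, R_j)
  k_c <- s$a_x * s$a_y * s$rho_a * rA + s$c_x * s$c_y * s$rho_c  # cov(X_j, R_k)
  K <- matrix(c(k_w, k_c, k_c, k_w), 2, 2)
  g_w <- sl["age_x"] * sl["age_y"] + sl["height_x"] * sl["height_y"]
  g_c <- sl["age_x"] * sl["age_y"] + sl["height_x"] * sl["height_y"] * r_h
  G <- matrix(c(g_w, g_c, g_c, g_w), 2, 2)
  Srr <- matrix(c(1, s$a_y^2 * rA + s$c_y^2, s$a_y^2 * rA + s$c_y^2, 1), 2, 2)
  H <- matrix(c(sl["age_y"]^2 + sl["height_y"]^2,
                sl["age_y"]^2 + sl["height_y"]^2 * r_h,
                sl["age_y"]^2 + sl["height_y"]^2 * r_h,
                sl["age_y"]^2 + sl["height_y"]^2), 2, 2)

  Sxy <- s$b * Sxx + K + G
  Syy <- s$b^2 * Sxx + 2 * s$b * (K + G) + Srr + H
  m <- rbind(cbind(Sxx, Sxy), cbind(t(Sxy), Syy))
  dimnames(m) <- list(c("X1", "X2", "Y1", "Y2"), c("X1", "X2", "Y1", "Y2"))
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("implied covariance not positive semi-definite (eigenvalue ",
         format(min(ev)), ") for zygosity ", zygosity)
  structure(list(zygosity = zygosity, matrix = m), class = "implied_covariance")
}

# second moments needed by the population estimating equations, per zygosity
pop_moments <- function(scenario, zygosity) {
  m <- implied_covariance(scenario, zygosity)$matrix
  c(sxx = m["X1", "X2"], vx = m["X1", "X1"],
    ksy = m["X1", "Y1"], kcy = m["X1", "Y2"],
    syy = m["Y1", "Y1"], syyp = m["Y1", "Y2"])
}

#' Population regression coefficients of the three ICE FALCON models
#'
#' The large-sample values targeted by the GEE estimators under a scenario,
#' per zygosity and pooled (pair-count-weighted). For the mutually adjusted
#' model the estimating equations reduce to the least-squares normal
#' equations whatever the working correlation, so `beta_self_adj` and
#' `beta_cotwin_adj` come from the 2x2 solve on the implied covariance. The
#' single-predictor models are different: with an exchangeable working
#' correlation their probability limits solve the population estimating
#' equations jointly with the limiting working-correlation parameter, which
#' the function obtains by fixed-point iteration; with
#' `working = "independence"` they are the plain projections
#' (`beta_self = cov(X1, Y1) / var(X)`, `beta_cotwin = cov(X2, Y1) / var(X)`).
#' Requires all covariate slopes to be zero (covariate-adjusted fits then
#' share these limits, since the covariates are independent of the traits).
#'
#' @param scenario a [scenario_config()].
#' @param working the working correlation whose probability limits are wanted.
#' @return data frame with columns `group` (`MZ`, `DZ`, `pooled`),
#'   `beta_self`, `beta_cotwin`, `beta_self_adj`, `beta_cotwin_adj`.
#' @export
expected_coefficients <- function(scenario,
                                  working = c("exchangeable", "independence")) {
  working <- match.arg(working)
  if (any(scenario$slopes != 0))
    stop("closed-form population coefficients require zero covariate slopes")

  groups <- list(MZ = c(MZ = 1), DZ = c(DZ = 1),
                 pooled = c(MZ = scenario$n_mz, DZ = scenario$n_dz) /
                   (scenario$n_mz + scenario$n_dz))
  mom <- list(MZ = pop_moments(scenario, "MZ"), DZ = pop_moments(scenario, "DZ"))

  one_group <- function(wts) {
    M <- Reduce(`+`, Map(function(w, z) w * mom[[z]], wts, names(wts)))
    if (abs(M[["sxx"]]) >= M[["vx"]] - 1e-12)
      stop("cross-twin exposure correlation is 1; mutually adjusted model singular")
    # mutually adjusted model: working-correlation-free 2x2 solve
    A3 <- matrix(c(M[["vx"]], M[["sxx"]], M[["sxx"]], M[["vx"]]), 2, 2)
    b3 <- solve(A3, c(M[["ksy"]], M[["kcy"]]))
    # single-predictor limits
    lim1 <- function(k_own, k_other) {
      # model y_self ~ d with d = own (Model 1) or cotwin (Model 2) exposure:
      # beta = (k_own - alpha * k_other) / (vx - alpha * sxx) at the limiting
      # alpha = E[e1 e2] / E[e^2]
      beta <- k_own / M[["vx"]]; alpha <- 0
      if (working == "exchangeable") {
        for (i in 1:500) {
          Ee2 <- M[["syy"]] - 2 * beta * k_own + beta^2 * M[["vx"]]
          Ee12 <- M[["syyp"]] - 2 * beta * k_other + beta^2 * M[["sxx"]]
          alpha <- Ee12 / Ee2
          beta_new <- (k_own - alpha * k_other) / (M[["vx"]] - alpha * M[["sxx"]])
          if (abs(beta_new - beta) < 1e-13) { beta <- beta_new; break }
          beta <- beta_new
        }
      }
      beta
    }
    c(beta_self = lim1(M[["ksy"]], M[["kcy"]]),
      beta_cotwin = lim1(M[["kcy"]], M[["ksy"]]),
      beta_self_adj = b3[1], beta_cotwin_adj = b3[2])
  }
  out <- do.call(rbind, lapply(groups, one_group))
  data.frame(group = rownames(out), out, row.names = NULL)
}

# twin-correlated standard-normal factor: common + unique mixture
twin_factor <- function(n, r) {
  common <- rnorm(n)
  cbind(sqrt(r) * common + sqrt(1 - r) * rnorm(n),
        sqrt(r) * common + sqrt(1 - r) * rnorm(n))
}

#' Simulate a twin cohort under a scenario
#'
#' Draws factor scores from independent standard normals following the path
#' model and returns a long-format [twin_dataset] with columns `pair_id`,
#' `twin_index`, `zygosity`, `age`, `height` and the named exposure and
#' outcome. Deterministic given `seed`; within each zygosity block the draw
#' order is fixed (age; height factors; A_x; the A_y residual factor; C_x;
#' the C_y residual factor; E_x twin 1 and 2; E_y twin 1 and 2), so any run
#' is reproducible.
#'
#' @param scenario a [scenario_config()].
#' @param seed integer seed (optional but recommended).
#' @return a [twin_dataset]; the scenario is stored in attribute `scenario`.
#' @export
simulate_twins <- function(scenario, seed = NULL) {
  s <- scenario
  gen_block <- function(n, zygosity) {
    if (n == 0L) return(NULL)
    rA <- r_a_of(zygosity)
    age <- s$age_mean + s$age_sd * rnorm(n)          # twins share their age
    hF <- twin_factor(n, s$height_h2 * rA)           # additive height factor
    # height heritability enters through the within-pair correlation of hF
    h1 <- s$height_mean + s$height_sd * hF[, 1]
    h2 <- s$height_mean + s$height_sd * hF[, 2]
    # per-pair correlated A factors; E drawn per individual
    Ax <- twin_factor(n, rA)
    Ayr <- twin_factor(n, rA)
    Ay <- s$rho_a * Ax + sqrt(1 - s$rho_a^2) * Ayr
    Cx <- rnorm(n)
    Cy <- s$rho_c * Cx + sqrt(1 - s$rho_c^2) * rnorm(n)
    Ex <- cbind(rnorm(n), rnorm(n))
    Ey <- cbind(rnorm(n), rnorm(n))
    ageZ <- (age - s$age_mean) / s$age_sd
    hZ <- cbind(hF[, 1], hF[, 2])
    x <- s$a_x * Ax + s$c_x * Cx + s$e_x * Ex +
      s$slopes[["age_x"]] * ageZ + s$slopes[["height_x"]] * hZ
    y <- s$b * x + s$a_y * Ay + s$c_y * Cy + s$e_y * Ey +
      s$slopes[["age_y"]] * ageZ + s$slopes[["height_y"]] * hZ
    ids <- sprintf("%s%05d", tolower(zygosity), seq_len(n))
    data.frame(pair_id = rep(ids, each = 2L),
               twin_index = rep(1:2, n),
               zygosity = zygosity,
               age = rep(age, each = 2L),
               height = as.vector(t(cbind(h1, h2))),
               x = as.vector(t(x)),
               y = as.vector(t(y)),
               stringsAsFactors = FALSE)
  }
  d <- with_seed(seed, rbind(gen_block(s$n_mz, "MZ"), gen_block(s$n_dz, "DZ")))
  names(d)[names(d) == "x"] <- s$exposure
  names(d)[names(d) == "y"] <- s$outcome
  out <- twin_dataset(d, traits = c(s$exposure, s$outcome),
                      covariates = c("age", "height"))
  attr(out, "scenario") <- s
  out
}

#' Read a scenario configuration from YAML or JSON
#'
#' Keys mirror the arguments of [scenario_config()].
#'
#' @param path configuration file.
#' @return a validated `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(cfg$slopes)) cfg$slopes <- unlist(cfg$slopes)
  do.call(scenario_config, cfg)
}
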
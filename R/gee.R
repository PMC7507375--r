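# Linear-mean (identity link, Gaussian) GEE for pair-clustered data.
#
# Clusters may have one or two members; two-member clusters are solved with the
# closed-form inverse of the 2x2 exchangeable working correlation, so the whole
# update is vectorized across clusters. Conventions follow the usual GEE moment
# estimators: scale phi = sum(r^2)/(N - p); exchangeable alpha =
# sum over clusters of within-cluster residual cross-products / phi, divided by
# (number of within-cluster pairs - p). Robust covariance is the cluster-level
# sandwich; the bread also yields the naive (model-based) covariance.

gee_core <- function(y, X, cluster, working = c("exchangeable", "independence"),
                     alpha_fix = NULL, tol = 1e-8, maxit = 100L) {
  working <- match.arg(working)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n || length(cluster) != n) stop("inconsistent dimensions")

  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("design matrix rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  cl <- as.integer(factor(cluster, levels = unique(cluster)))
  ord <- order(cl)
  if (is.unsorted(cl)) { y <- y[ord]; X <- X[ord, , drop = FALSE]; cl <- cl[ord] }
  sizes <- tabulate(cl)
  if (any(sizes > 2L)) stop("clusters of size > 2 are not supported")
  n_cl <- length(sizes)

  first <- cumsum(c(1L, sizes))[seq_len(n_cl)]
  pair_cl <- which(sizes == 2L)
  i1 <- first[pair_cl]; i2 <- i1 + 1L
  is1 <- first[sizes == 1L]
  npair <- length(pair_cl)
  if (n_cl < 2L) stop("need at least 2 clusters")

  X1 <- X[i1, , drop = FALSE]; X2 <- X[i2, , drop = FALSE]
  y1 <- y[i1]; y2 <- y[i2]
  Xs <- X[is1, , drop = FALSE]; ys <- y[is1]

  beta <- qr.coef(qx, y)
  alpha <- 0
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    r <- y - drop(X %*% beta)
    phi <- sum(r^2) / (n - p)
    if (working == "exchangeable" && npair > 0L) {
      if (!is.null(alpha_fix)) {
        alpha <- alpha_fix
      } else if (phi <= 0 || !is.finite(phi)) {
        alpha <- 0  # perfect fit: working correlation is unidentified
      } else {
        r1 <- r[i1]; r2 <- r[i2]
        alpha <- sum(r1 * r2) / phi / max(npair - p, 1L)
        alpha <- max(min(alpha, 0.99), -0.99)
      }
    } else {
      alpha <- if (is.null(alpha_fix) || working == "independence") 0 else alpha_fix
    }
    w <- 1 / (1 - alpha^2)
    A <- w * (crossprod(X1) + crossprod(X2) -
                alpha * (crossprod(X1, X2) + crossprod(X2, X1)))
    bv <- w * (crossprod(X1, y1 - alpha * y2) + crossprod(X2, y2 - alpha * y1))
    if (length(is1)) { A <- A + crossprod(Xs); bv <- bv + crossprod(Xs, ys) }
    beta_new <- drop(solve(A, bv))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= maxit) break
  }
  if (!converged)
    stop("GEE did not converge in ", maxit,
         " iterations (last max |change| = ", format(delta), ")")

  r <- y - drop(X %*% beta)
  w <- 1 / (1 - alpha^2)
  # cluster-level scores S_i = X_i' R(alpha)^{-1} r_i (phi omitted; it cancels
  # in the sandwich). influence rows are A^{-1} S_i, one per cluster.
  S <- matrix(0, n_cl, p)
  if (npair > 0L) {
    r1 <- r[i1]; r2 <- r[i2]
    S[pair_cl, ] <- w * (X1 * (r1 - alpha * r2) + X2 * (r2 - alpha * r1))
  }
  if (length(is1)) S[sizes == 1L, ] <- Xs * r[is1]
  A_inv <- solve(A)
  influence <- S %*% A_inv
  phi <- sum(r^2) / (n - p)

  # When alpha is estimated, the coefficient estimating functions depend on a
  # nuisance parameter whose own sampling variation contributes at first
  # order whenever the mean model is misspecified (as it is, by design, in
  # the single-predictor cross-pair models). Stack the moment equations for
  # alpha and phi with the coefficient equations and take the joint
  # M-estimation influence function; with a correctly specified mean the
  # extra terms vanish asymptotically and this reduces to the classic
  # sandwich.
  estimated_alpha <- working == "exchangeable" && is.null(alpha_fix) &&
    npair > 0L && phi > 1e-12
  if (estimated_alpha) {
    r1 <- r[i1]; r2 <- r[i2]
    psi_a <- numeric(n_cl)
    psi_a[pair_cl] <- r1 * r2 - alpha * phi
    rsq <- numeric(n_cl)
    rsq[pair_cl] <- r1^2 + r2^2
    if (length(is1)) rsq[sizes == 1L] <- r[is1]^2
    psi_f <- rsq - sizes * phi
    dRterm <- 2 * alpha * w^2 *
      (crossprod(X1, r1 - alpha * r2) + crossprod(X2, r2 - alpha * r1)) -
      w * (crossprod(X1, r2) + crossprod(X2, r1))
    G_ba <- -dRterm                                      # p x 1
    G_ab <- colSums(X1 * r2 + X2 * r1)                   # 1 x p
    G_fb <- 2 * colSums(X * r)
    G <- rbind(cbind(A, G_ba, 0),
               c(G_ab, phi * npair, alpha * npair),
               c(G_fb, 0, n))
    Psi <- cbind(S, psi_a, psi_f)
    IF <- Psi %*% t(solve(G))
    influence <- IF[, seq_len(p), drop = FALSE]
  }
  robust <- crossprod(influence)
  naive <- phi * A_inv
  dimnames(robust) <- dimnames(naive) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)

  list(coefficients = beta, robust = robust, naive = naive,
       alpha = alpha, phi = phi, n_clusters = n_cl, n_obs = n,
       converged = converged, n_iter = iter,
       influence = influence, residuals = r, score = colSums(S))
}

#' Fit a linear GEE with exchangeable working correlation
#'
#' Identity-link Gaussian generalized estimating equations for data clustered
#' in twin pairs (clusters of one or two observations). Coefficients solve the
#' estimating equations by iteratively reweighted least squares with a moment
#' update of the working correlation; inference uses the cluster-level robust
#' (sandwich) covariance. With `working = "independence"` the coefficients are
#' exactly ordinary least squares and the robust covariance is the standard
#' cluster-robust OLS covariance.
#'
#' @param formula model formula for the mean.
#' @param data data frame (e.g. a [build_regression_table()] output).
#' @param id cluster identifier: a column name in `data` or a vector.
#' @param working working correlation structure, `"exchangeable"` (default)
#'   or `"independence"`.
#' @param alpha_fix optionally hold the exchangeable correlation parameter
#'   fixed at this value instead of estimating it.
#' @param tol convergence tolerance on the maximum absolute coefficient change.
#' @param maxit maximum number of iterations.
#' @return a `gee_fit` object: coefficients, robust and naive covariance,
#'   working correlation `alpha`, scale `phi`, cluster counts and convergence
#'   information.
#' @export
#' @examples
#' sc <- null_scenario(n_mz = 30, n_dz = 20)
#' d <- simulate_twins(sc, seed = 1)
#' tab <- build_regression_table(d, "outcome", "exposure")
#' fit_gee(y_self ~ x_self + age + height, tab, id = "cluster_id")
fit_gee <- function(formula, data, id, working = c("exchangeable", "independence"),
                    alpha_fix = NULL, tol = 1e-8, maxit = 100L) {
  working <- match.arg(working)
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  X <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  cluster <- if (is.character(id) && length(id) == 1L) data[[id]] else id
  if (is.null(cluster)) stop("cluster id not found")
  fit <- gee_core(y, X, cluster, working = working, alpha_fix = alpha_fix,
                  tol = tol, maxit = maxit)
  fit$formula <- formula
  fit$working <- working
  class(fit) <- "gee_fit"
  fit
}

#' @export
coef.gee_fit <- function(object, ...) object$coefficients

#' @export
vcov.gee_fit <- function(object, ...) object$robust

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("Linear GEE (%s working correlation), %d obs in %d clusters\n",
              x$working, x$n_obs, x$n_clusters))
  cat(sprintf("  alpha = %.4f, scale = %.4f, %d iterations\n",
              x$alpha, x$phi, x$n_iter))
  print(summary_table(x))
  invisible(x)
}

summary_table <- function(fit) {
  est <- fit$coefficients
  se <- sqrt(diag(fit$robust))
  z <- est / se
  data.frame(estimate = est, robust_se = se, z = z,
             p = 2 * stats::pnorm(-abs(z)), row.names = names(est))
}

#' Compare trait means between MZ and DZ twins
#'
#' Covariate-adjusted comparison of a trait's mean between the zygosity
#' groups, using a GEE clustered by pair so that the within-pair correlation
#' is accounted for; the reported p-value is a two-sided robust Wald test of
#' the MZ - DZ difference. Also reports the unadjusted per-group mean and SD,
#' the descriptive layout of a twin-study characteristics table.
#'
#' @param x a [twin_dataset].
#' @param trait trait name.
#' @param covariates adjustment covariates (default age and height; use
#'   `character(0)` for an unadjusted comparison).
#' @return a list with `estimate` (MZ minus DZ adjusted difference), `se`,
#'   `p`, and `table`, a one-row data frame with per-group mean/SD and the p.
#' @export
compare_group_means <- function(x, trait, covariates = c("age", "height")) {
  stopifnot(inherits(x, "twin_dataset"))
  covariates <- setdiff(covariates, trait)
  d <- as.data.frame(x)
  keep <- stats::complete.cases(d[, c(trait, covariates), drop = FALSE])
  d <- d[keep, , drop = FALSE]
  if (length(unique(d$zygosity)) < 2L) stop("both zygosity groups must be present")
  d$.group <- as.numeric(d$zygosity == "MZ")
  fml <- stats::reformulate(c(".group", covariates), response = trait)
  fit <- fit_gee(fml, d, id = d$pair_id)
  est <- fit$coefficients[".group"]
  se <- sqrt(fit$robust[".group", ".group"])
  p <- 2 * stats::pnorm(-abs(est / se))
  tab <- data.frame(
    trait = trait,
    mean_dz = mean(d[[trait]][d$.group == 0]),
    sd_dz = stats::sd(d[[trait]][d$.group == 0]),
    mean_mz = mean(d[[trait]][d$.group == 1]),
    sd_mz = stats::sd(d[[trait]][d$.group == 1]),
    p = unname(p))
  list(estimate = unname(est), se = unname(se), p = unname(p), table = tab)
}
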
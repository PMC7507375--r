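#' Covariate-adjusted within-pair correlation
#'
#' Within-pair correlation of a trait for pairs of one zygosity. The trait is
#' first residualized on the covariates by ordinary least squares over all
#' individuals of that zygosity group (so group-level covariate effects cannot
#' leak into the correlation), then the double-entered Pearson correlation is
#' computed over the 2n ordered within-pair tuples (e1, e2) and (e2, e1) — an
#' intraclass-style estimate that does not depend on the arbitrary labelling
#' of the twins within a pair.
#'
#' @param x a [twin_dataset].
#' @param trait trait name.
#' @param covariates covariates to adjust for (default age and height; use
#'   `character(0)` for no adjustment).
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return a `within_pair_correlation` object: list with `zygosity`, `r`,
#'   `n_pairs`, `adjusted_for`.
#' @export
within_pair_correlation <- function(x, trait, covariates = c("age", "height"),
                                    zygosity = c("MZ", "DZ")) {
  stopifnot(inherits(x, "twin_dataset"))
  zygosity <- match.arg(zygosity)
  covariates <- setdiff(covariates, trait)
  sub <- x[x$zygosity == zygosity, , drop = FALSE]
  class(sub) <- class(x)
  attr(sub, "trait_names") <- attr(x, "trait_names")
  attr(sub, "covariate_names") <- attr(x, "covariate_names")
  sub <- drop_incomplete_pairs(sub, c(trait, covariates))
  np <- n_pairs(sub)
  if (np < 3L) stop("fewer than 3 complete ", zygosity, " pairs for '", trait, "'")

  d <- as.data.frame(sub)
  resid <- if (length(covariates)) {
    stats::resid(stats::lm(stats::reformulate(covariates, response = trait), data = d))
  } else {
    d[[trait]] - mean(d[[trait]])
  }
  e1 <- resid[seq(1, nrow(d), 2)]
  e2 <- resid[seq(2, nrow(d), 2)]
  r <- stats::cor(c(e1, e2), c(e2, e1))
  structure(list(zygosity = zygosity, r = r, n_pairs = np,
                 adjusted_for = covariates, trait = trait),
            class = "within_pair_correlation")
}

#' @export
print.within_pair_correlation <- function(x, ...) {
  adj <- if (length(x$adjusted_for))
    paste0(" adjusted for ", paste(x$adjusted_for, collapse = ", ")) else ""
  cat(sprintf("Within-pair correlation of '%s' (%s, %d pairs%s): r = %.3f\n",
              x$trait, x$zygosity, x$n_pairs, adj, x$r))
  invisible(x)
}

#' Fisher's z test for the difference of two correlations
#'
#' Compares two independent correlation coefficients via the variance-
#' stabilizing transform `atanh(r)`:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, referred to the
#' standard normal, two-sided. For within-pair twin correlations the effective
#' sample sizes are the numbers of *pairs* — the independent sampling units —
#' not of (double-entered) individuals.
#'
#' @param r1,r2 the two correlations, each strictly inside (-1, 1).
#' @param n1,n2 the corresponding sample sizes (numbers of pairs), each > 3.
#' @return an object of class `htest` with the z statistic and two-sided p.
#' @export
#' @examples
#' fisher_z_test(0.79, 98, 0.40, 54)
fisher_z_test <- function(r1, n1, r2, n2) {
  stopifnot(is.finite(r1), is.finite(r2))
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("correlations must be strictly inside (-1, 1); Fisher transform is infinite at |r| = 1")
  if (n1 <= 3 || n2 <= 3) stop("each group needs more than 3 pairs")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(
    statistic = c(z = z), p.value = p,
    estimate = c(r1 = r1, r2 = r2),
    parameter = c(n1 = n1, n2 = n2),
    method = "Fisher z test for the difference of two correlations",
    alternative = "two.sided",
    data.name = sprintf("r1 = %.3f (n1 = %d) vs r2 = %.3f (n2 = %d)",
                        r1, as.integer(n1), r2, as.integer(n2))),
    class = "htest")
}

#' Within-pair correlation table with MZ-DZ comparison
#'
#' Convenience wrapper producing, per trait, the adjusted within-pair
#' correlations in MZ and DZ pairs and the Fisher z comparison.
#'
#' @param x a [twin_dataset].
#' @param traits traits to tabulate (default: all traits).
#' @param covariates adjustment covariates.
#' @return data frame with columns `trait`, `r_mz`, `n_mz`, `r_dz`, `n_dz`,
#'   `z`, `p`.
#' @export
correlation_table <- function(x, traits = attr(x, "trait_names"),
                              covariates = c("age", "height")) {
  rows <- lapply(traits, function(tr) {
    mz <- within_pair_correlation(x, tr, covariates, "MZ")
    dz <- within_pair_correlation(x, tr, covariates, "DZ")
    ft <- fisher_z_test(mz$r, mz$n_pairs, dz$r, dz$n_pairs)
    data.frame(trait = tr, r_mz = mz$r, n_mz = mz$n_pairs,
               r_dz = dz$r, n_dz = dz$n_pairs,
               z = unname(ft$statistic), p = ft$p.value)
  })
  do.call(rbind, rows)
}
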
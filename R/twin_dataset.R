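#' Construct and validate a twin-pair dataset
#'
#' A `twin_dataset` is a long-format data frame with one row per individual:
#' columns `pair_id`, `twin_index` (1 or 2), `zygosity` (`"MZ"` or `"DZ"`) and
#' one numeric column per trait or covariate. Validation enforces the pairing
#' structure: every `pair_id` occurs exactly twice, the two members carry twin
#' indices 1 and 2 and share one zygosity, and all variable values are finite
#' or missing (`NA`).
#'
#' @param data a data frame with at least the columns `pair_id`, `twin_index`,
#'   `zygosity` plus the named variables.
#' @param traits character vector of trait (exposure/outcome) column names.
#' @param covariates character vector of covariate column names
#'   (default `c("age", "height")`, intersected with what is present).
#' @return a `twin_dataset` object (a data frame with attributes
#'   `trait_names` and `covariate_names`), rows ordered by pair and twin index.
#' @export
twin_dataset <- function(data, traits = NULL, covariates = c("age", "height")) {
  stopifnot(is.data.frame(data))
  need <- c("pair_id", "twin_index", "zygosity")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))

  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$pair_id <- as.character(data$pair_id)
  data$twin_index <- as.integer(data$twin_index)
  zyg <- toupper(trimws(as.character(data$zygosity)))
  bad_z <- setdiff(unique(zyg), c("MZ", "DZ"))
  if (length(bad_z)) stop("unknown zygosity code(s): ", paste(bad_z, collapse = ", "))
  data$zygosity <- zyg

  covariates <- intersect(covariates, names(data))
  if (is.null(traits)) {
    reserved <- c(need, covariates)
    traits <- names(data)[vapply(data, is.numeric, TRUE) & !names(data) %in% reserved]
  }
  absent <- setdiff(c(traits, covariates), names(data))
  if (length(absent)) stop("declared variables not in data: ", paste(absent, collapse = ", "))

  for (v in c(traits, covariates)) {
    data[[v]] <- as.numeric(data[[v]])
    if (!all(is_finite_or_na(data[[v]])))
      stop("non-finite values in variable '", v, "'")
  }

  cnt <- table(data$pair_id)
  bad <- names(cnt)[cnt != 2L]
  if (length(bad))
    stop("pair_id(s) not occurring exactly twice: ", paste(sort(bad), collapse = ", "))
  if (anyDuplicated(data[c("pair_id", "twin_index")]))
    stop("duplicated (pair_id, twin_index) combinations")
  if (!all(data$twin_index %in% 1:2))
    stop("twin_index must be 1 or 2")

  o <- order(data$pair_id, data$twin_index)
  data <- data[o, , drop = FALSE]
  z1 <- data$zygosity[seq(1, nrow(data), 2)]
  z2 <- data$zygosity[seq(2, nrow(data), 2)]
  if (any(z1 != z2)) {
    bad <- unique(data$pair_id[seq(1, nrow(data), 2)][z1 != z2])
    stop("pair(s) with discordant zygosity: ", paste(bad, collapse = ", "))
  }
  rownames(data) <- NULL
  structure(data,
            trait_names = traits,
            covariate_names = covariates,
            class = c("twin_dataset", "data.frame"))
}

#' @export
print.twin_dataset <- function(x, ...) {
  cat(sprintf("Twin-pair dataset: %d pairs (%d MZ, %d DZ), %d individuals\n",
              nrow(x) / 2,
              sum(x$zygosity == "MZ") / 2, sum(x$zygosity == "DZ") / 2, nrow(x)))
  cat("  traits:    ", paste(attr(x, "trait_names"), collapse = ", "), "\n")
  cat("  covariates:", paste(attr(x, "covariate_names"), collapse = ", "), "\n")
  invisible(x)
}

n_pairs <- function(x) nrow(x) / 2L

#' Read a twin-pair dataset from CSV
#'
#' Reads a long-format CSV (RFC 4180, `.` decimal) with one row per individual
#' and validates the pairing structure. Column names can be remapped through
#' `schema`, e.g. `list(pair_id = "fam", twin_index = "member")`.
#'
#' @param path file path of the CSV.
#' @param schema optional named list mapping the canonical names `pair_id`,
#'   `twin_index`, `zygosity` (and optionally variables) to the column names
#'   used in the file.
#' @inheritParams twin_dataset
#' @return a validated [twin_dataset].
#' @export
read_twin_csv <- function(path, schema = NULL, traits = NULL,
                          covariates = c("age", "height")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      from <- schema[[canon]]
      if (!from %in% names(d)) stop("schema column '", from, "' not found in file")
      names(d)[names(d) == from] <- canon
    }
  }
  twin_dataset(d, traits = traits, covariates = covariates)
}

#' Write a twin-pair dataset to CSV
#'
#' @param x a [twin_dataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_twin_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Drop pairs with missing values in required variables
#'
#' Retains only pairs in which *both* members have non-missing values for all
#' variables in `required` (complete-pair deletion; the analysis-level
#' treatment of missingness throughout the package).
#'
#' @param x a [twin_dataset].
#' @param required character vector of variable names that must be observed.
#' @return the filtered [twin_dataset]; the number of pairs removed is in
#'   attribute `n_pairs_removed`.
#' @export
drop_incomplete_pairs <- function(x, required) {
  stopifnot(inherits(x, "twin_dataset"))
  absent <- setdiff(required, names(x))
  if (length(absent)) stop("required variables not in dataset: ", paste(absent, collapse = ", "))
  ok_row <- stats::complete.cases(as.data.frame(x)[, required, drop = FALSE])
  ok_pair <- tapply(ok_row, x$pair_id, all)
  keep <- x$pair_id %in% names(ok_pair)[ok_pair]
  removed <- (nrow(x) - sum(keep)) / 2L
  if (!any(keep)) stop("no complete pairs for: ", paste(required, collapse = ", "))
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "trait_names") <- attr(x, "trait_names")
  attr(out, "covariate_names") <- attr(x, "covariate_names")
  attr(out, "standardization") <- attr(x, "standardization")
  class(out) <- class(x)
  attr(out, "n_pairs_removed") <- as.integer(removed)
  out
}

#' Standardize variables to mean zero, SD one
#'
#' Each listed variable is centred and scaled using its mean and SD over all
#' non-missing individuals in the dataset, pooling both zygosity groups and
#' both twins (the analysis-sample convention). The moments used are stored in
#' attribute `standardization` so the transform can be reported or inverted.
#'
#' @param x a [twin_dataset].
#' @param variables character vector of variables to standardize; defaults to
#'   all traits.
#' @return the transformed [twin_dataset].
#' @export
standardize_traits <- function(x, variables = attr(x, "trait_names")) {
  stopifnot(inherits(x, "twin_dataset"))
  absent <- setdiff(variables, names(x))
  if (length(absent)) stop("variables not in dataset: ", paste(absent, collapse = ", "))
  scaling <- attr(x, "standardization") %||% list()
  for (v in variables) {
    vals <- x[[v]]
    m <- mean(vals, na.rm = TRUE)
    s <- stats::sd(vals, na.rm = TRUE)
    if (!is.finite(s) || s == 0) stop("zero variance in variable '", v, "'")
    x[[v]] <- (vals - m) / s
    scaling[[v]] <- c(mean = m, sd = s)
  }
  attr(x, "standardization") <- scaling
  x
}

#' Build a double-entered regression table
#'
#' Expands complete twin pairs into the double-entry layout used by the
#' cross-pair cross-trait models: each individual appears once as "self" with
#' their own outcome (`y_self`), own exposure (`x_self`), their cotwin's
#' exposure (`x_cotwin`) and their own covariate values; the pair id is the
#' cluster id. Each pair therefore contributes exactly two rows and the two
#' rows swap `x_self` and `x_cotwin`.
#'
#' @param x a [twin_dataset].
#' @param outcome outcome variable name.
#' @param exposure exposure variable name (must differ from `outcome`).
#' @param covariates covariate names (self twin's own values).
#' @return a `regression_table` data frame with columns `y_self`, `x_self`,
#'   `x_cotwin`, the covariates, `cluster_id` and `zygosity`; consecutive row
#'   pairs belong to one cluster. Attributes record the variable roles.
#' @export
build_regression_table <- function(x, outcome, exposure,
                                   covariates = attr(x, "covariate_names")) {
  stopifnot(inherits(x, "twin_dataset"))
  if (outcome == exposure) stop("outcome and exposure must be distinct variables")
  vars <- c(outcome, exposure, covariates)
  absent <- setdiff(vars, names(x))
  if (length(absent)) stop("variables not in dataset: ", paste(absent, collapse = ", "))
  x <- drop_incomplete_pairs(x, vars)

  d <- as.data.frame(x)
  i1 <- seq(1, nrow(d), 2)  # twin 1 rows (data are pair/twin sorted)
  i2 <- i1 + 1L
  np <- length(i1)
  # interleave: rows (2k-1, 2k) are the two double-entry rows of pair k
  self <- integer(2 * np); self[seq(1, 2 * np, 2)] <- i1; self[seq(2, 2 * np, 2)] <- i2
  co   <- integer(2 * np); co[seq(1, 2 * np, 2)]   <- i2; co[seq(2, 2 * np, 2)]   <- i1

  out <- data.frame(
    y_self = d[[outcome]][self],
    x_self = d[[exposure]][self],
    x_cotwin = d[[exposure]][co],
    d[self, covariates, drop = FALSE],
    cluster_id = d$pair_id[self],
    zygosity = d$zygosity[self],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out,
            outcome_name = outcome, exposure_name = exposure,
            covariate_names = covariates,
            class = c("regression_table", "data.frame"))
}
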
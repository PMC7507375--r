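test_that("a minimal valid CSV round-trips through read/write", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tiny_twin_df(), f, row.names = FALSE)
  d <- read_twin_csv(f, traits = c("lean_mass", "bone"))
  expect_s3_class(d, "twin_dataset")
  expect_equal(nrow(d) / 2, 2)
  expect_setequal(attr(d, "trait_names"), c("lean_mass", "bone"))

  # generator output: write then read preserves values to 1e-12
  sim <- simulate_twins(null_scenario(n_mz = 20, n_dz = 10), seed = 4)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_twin_csv(sim, f2)
  back <- read_twin_csv(f2, traits = attr(sim, "trait_names"))
  for (v in c("age", "height", "exposure", "outcome"))
    expect_equal(back[[v]], sim[[v]], tolerance = 1e-12)
})

test_that("schema remapping and zygosity normalization work", {
  df <- tiny_twin_df()
  names(df)[1:3] <- c("fam", "member", "zyg")
  df$zyg <- tolower(df$zyg)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  d <- read_twin_csv(f, schema = list(pair_id = "fam", twin_index = "member",
                                      zygosity = "zyg"),
                     traits = c("lean_mass", "bone"))
  expect_setequal(unique(d$zygosity), c("MZ", "DZ"))
})

test_that("structural validation names the offending pairs", {
  df <- tiny_twin_df()
  expect_error(twin_dataset(df[-4, ], traits = "bone"), "p2")
  df2 <- tiny_twin_df(); df2$zygosity[3] <- "XX"
  expect_error(twin_dataset(df2, traits = "bone"), "XX")
  df3 <- tiny_twin_df(); df3$twin_index[2] <- 1L
  expect_error(twin_dataset(df3, traits = "bone"), "duplicated")
  df4 <- tiny_twin_df(); df4$zygosity[2] <- "DZ"
  expect_error(twin_dataset(df4, traits = "bone"), "discordant")
  df5 <- tiny_twin_df(); df5$bone[1] <- Inf
  expect_error(twin_dataset(df5, traits = "bone"), "bone")
})

test_that("drop_incomplete_pairs keeps exactly the fully observed pairs", {
  df <- tiny_twin_df(); df$bone[2] <- NA
  d <- twin_dataset(df, traits = c("lean_mass", "bone"))
  kept <- drop_incomplete_pairs(d, "bone")
  expect_equal(unique(kept$pair_id), "p2")
  expect_equal(attr(kept, "n_pairs_removed"), 1L)

  # identity when nothing is missing
  d0 <- tiny_twin_dataset()
  k0 <- drop_incomplete_pairs(d0, "bone")
  expect_equal(attr(k0, "n_pairs_removed"), 0L)
  attr(k0, "n_pairs_removed") <- NULL
  expect_equal(as.data.frame(k0), as.data.frame(d0))

  expect_error(drop_incomplete_pairs(d, "nope"), "nope")
  df_all <- tiny_twin_df(); df_all$bone <- NA_real_
  expect_error(drop_incomplete_pairs(twin_dataset(df_all, traits = "bone"), "bone"),
               "no complete pairs")
})

test_that("random blanking matches a brute-force count of affected pairs", {
  d <- simulate_twins(null_scenario(n_mz = 60, n_dz = 40), seed = 9)
  df <- as.data.frame(d)
  set.seed(31)
  hit <- sample(nrow(df), 10)
  df$outcome[hit] <- NA
  d2 <- twin_dataset(df, traits = c("exposure", "outcome"))
  expected_pairs <- length(unique(df$pair_id)) - length(unique(df$pair_id[hit]))
  kept <- drop_incomplete_pairs(d2, "outcome")
  expect_equal(nrow(kept) / 2, expected_pairs)
})

test_that("standardize_traits gives exact z-scores and records the moments", {
  df <- tiny_twin_df()
  df$bone <- c(1, 2, 3, 2)
  d <- twin_dataset(df, traits = c("lean_mass", "bone"))
  z <- standardize_traits(d, "bone")
  expect_equal(mean(z$bone), 0, tolerance = 1e-12)
  expect_equal(sd(z$bone), 1, tolerance = 1e-12)
  # against independent recomputation on the flattened vector
  expect_equal(z$bone, (df$bone - mean(df$bone)) / sd(df$bone), tolerance = 1e-12)
  expect_equal(unname(attr(z, "standardization")$bone["mean"]), mean(df$bone))

  # idempotence on already-standardized values
  z2 <- standardize_traits(z, "bone")
  expect_equal(z2$bone, z$bone, tolerance = 1e-12)

  df$bone <- 5
  expect_error(standardize_traits(twin_dataset(df, traits = "bone"), "bone"),
               "zero variance.*bone")
})

test_that("double entry swaps exposures within a pair and doubles the rows", {
  d <- tiny_twin_dataset()
  tab <- build_regression_table(d, "bone", "lean_mass")
  expect_equal(nrow(tab), 4)
  expect_equal(tab$x_self[1:2], rev(tab$x_cotwin[1:2]))
  expect_equal(tab$x_self[3:4], rev(tab$x_cotwin[3:4]))
  expect_equal(table(tab$cluster_id), table(c("p1", "p1", "p2", "p2")))
  expect_error(build_regression_table(d, "bone", "bone"), "distinct")
})

test_that("double-entered regression equals brute-force stacked assembly", {
  d <- simulate_twins(confounding_scenario(n_mz = 80, n_dz = 40), seed = 6)
  tab <- build_regression_table(d, "outcome", "exposure")
  # brute force: stack twin1-on-twin2 and twin2-on-twin1 by hand
  df <- as.data.frame(d)
  t1 <- df[df$twin_index == 1, ]; t2 <- df[df$twin_index == 2, ]
  y <- c(t1$outcome, t2$outcome)
  xc <- c(t2$exposure, t1$exposure)
  manual <- unname(coef(lm(y ~ xc)))
  via_table <- unname(coef(lm(y_self ~ x_cotwin, data = tab)))
  expect_equal(via_table, manual, tolerance = 1e-12)
})

test_that("relabelling twins within pairs leaves the double-entry rows invariant", {
  d <- simulate_twins(null_scenario(n_mz = 15, n_dz = 10), seed = 2)
  tab <- build_regression_table(d, "outcome", "exposure")
  df <- as.data.frame(d)
  df$twin_index <- ifelse(df$twin_index == 1L, 2L, 1L)
  d2 <- twin_dataset(df, traits = attr(d, "trait_names"))
  tab2 <- build_regression_table(d2, "outcome", "exposure")
  key <- function(t) {
    k <- t[order(t$cluster_id, t$x_self), c("y_self", "x_self", "x_cotwin")]
    rownames(k) <- NULL
    k
  }
  expect_equal(key(tab2), key(tab), tolerance = 1e-12)
})

test_that("standardizing before or after double entry commutes", {
  d <- simulate_twins(confounding_scenario(n_mz = 40, n_dz = 30), seed = 13)
  t_after <- build_regression_table(standardize_traits(d), "outcome", "exposure")
  t_before <- build_regression_table(d, "outcome", "exposure")
  m <- mean(d$exposure); s <- sd(d$exposure)
  expect_equal(t_after$x_self, (t_before$x_self - m) / s, tolerance = 1e-12)
  expect_equal(t_after$x_cotwin, (t_before$x_cotwin - m) / s, tolerance = 1e-12)
})
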
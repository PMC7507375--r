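test_that("stacked joint covariance blocks equal each model's own sandwich", {
  d <- simulate_twins(confounding_scenario(n_mz = 80, n_dz = 40), seed = 19)
  tab <- build_regression_table(d, "outcome", "exposure")
  ji <- joint_delta_inference(tab)
  offs <- cumsum(c(0, vapply(ji$fits, function(f) length(f$coefficients), 1L)))
  for (m in 1:3) {
    idx <- (offs[m] + 1):offs[m + 1]
    expect_equal(unname(ji$joint_vcov[idx, idx]), unname(ji$fits[[m]]$robust),
                 tolerance = 1e-10)
  }
})

test_that("a model contrasted with itself has delta 0, SE 0, p 1", {
  d <- simulate_twins(null_scenario(n_mz = 40, n_dz = 20), seed = 7)
  tab <- build_regression_table(d, "outcome", "exposure")
  ji <- joint_delta_inference(tab)
  i <- ji$index$m1_self
  v <- ji$joint_vcov[i, i] + ji$joint_vcov[i, i] - 2 * ji$joint_vcov[i, i]
  expect_equal(v, 0, tolerance = 1e-14)
  expect_equal(ji$estimates[i] - ji$estimates[i], 0)
  # the Wald rule at a zero-estimate, zero-SE contrast reports p = 1
  expect_equal(icefalcon:::wald_row(0, sqrt(max(v, 0)))[["p"]], 1)
})

test_that("delta estimates equal literal coefficient differences and are invariant to twin relabelling", {
  d <- simulate_twins(confounding_scenario(n_mz = 70, n_dz = 50), seed = 23)
  r <- run_ice_falcon(d, "exposure", "outcome")
  co <- r$coefficients
  expect_equal(co["delta_self", "estimate"],
               co["beta_self", "estimate"] - co["beta_self_adj", "estimate"],
               tolerance = 1e-12)
  expect_equal(co["delta_cotwin", "estimate"],
               co["beta_cotwin", "estimate"] - co["beta_cotwin_adj", "estimate"],
               tolerance = 1e-12)
  expect_true(all(co$p >= 0 & co$p <= 1))

  df <- as.data.frame(d)
  df$twin_index <- 3L - df$twin_index
  d2 <- twin_dataset(df, traits = attr(d, "trait_names"))
  r2 <- run_ice_falcon(d2, "exposure", "outcome")
  expect_equal(r2$coefficients$estimate, co$estimate, tolerance = 1e-10)
})

test_that("a purely causal exposure shows the attenuation signature", {
  sc <- causal_scenario(b = 0.4, n_mz = 2580, n_dz = 1420)  # 4000 pairs
  d <- simulate_twins(sc, seed = 101)
  r <- run_ice_falcon(d, "exposure", "outcome")
  co <- r$coefficients
  pop <- expected_coefficients(sc)
  pop <- pop[pop$group == "pooled", ]
  expect_equal(pop$beta_self, 0.4, tolerance = 1e-12)
  expect_equal(pop$beta_self_adj, 0.4, tolerance = 1e-12)
  expect_equal(pop$beta_cotwin_adj, 0, tolerance = 1e-12)
  # estimates within 3 model SEs of the population values
  expect_lt(abs(co["beta_self", "estimate"] - 0.4), 3 * co["beta_self", "se"])
  expect_lt(abs(co["beta_cotwin_adj", "estimate"]), 3 * co["beta_cotwin_adj", "se"])
  expect_lt(abs(co["beta_cotwin", "estimate"] - pop$beta_cotwin),
            3 * co["beta_cotwin", "se"])
  expect_equal(r$label, "consistent_with_causation")
})

test_that("an exposure unrelated to outcome and familial factors gives null patterns", {
  d <- simulate_twins(null_scenario(n_mz = 645, n_dz = 355), seed = 55)
  r <- run_ice_falcon(d, "exposure", "outcome")
  co <- r$coefficients[1:4, ]
  expect_true(all(abs(co$estimate) < 4 * co$se))
  expect_equal(r$label, "inconclusive")
})

test_that("classification implements the stated truth table", {
  lab <- function(pds, pdc, pca)
    classify_ice_falcon(list(p_delta_self = pds, p_delta_cotwin = pdc,
                             p_beta_cotwin_adj = pca))
  expect_equal(lab(0.5, 0.01, 0.5), "consistent_with_causation")
  expect_equal(lab(0.5, 0.5, 0.01), "consistent_with_familial_confounding")
  expect_equal(lab(0.5, 0.01, 0.01), "mixed")
  expect_equal(lab(0.5, 0.5, 0.5), "inconclusive")
  expect_equal(lab(0.01, 0.01, 0.5), "inconclusive")  # self coefficient moved too
  # reported familial-confounding pattern: cross-pair association unchanged
  # (0.162 -> 0.162, change p = 0.998) and significant after adjustment
  expect_equal(lab(0.5, 0.998, 0.001), "consistent_with_familial_confounding")
})

test_that("bootstrap delta SEs agree with stacked SEs on a regular dataset", {
  d <- simulate_twins(confounding_scenario(n_mz = 130, n_dz = 70), seed = 40)
  tab <- build_regression_table(d, "outcome", "exposure")
  st <- joint_delta_inference(tab)
  bt <- joint_delta_inference(tab, method = "bootstrap", n_boot = 400, seed = 1)
  ratio <- st$deltas["delta_cotwin", "se"] / bt$deltas["delta_cotwin", "se"]
  expect_gt(ratio, 0.75)
  expect_lt(ratio, 1.25)
  expect_error(joint_delta_inference(tab, method = "bootstrap", n_boot = 50),
               "at least 100")
})

test_that("degenerate inputs produce annotated errors and warnings", {
  d <- simulate_twins(null_scenario(n_mz = 30, n_dz = 20), seed = 3)
  df <- as.data.frame(d)
  df$exposure <- 1  # constant exposure: collinear with the intercept
  d2 <- twin_dataset(df, traits = c("exposure", "outcome"))
  expect_error(suppressWarnings(run_ice_falcon(d2, "exposure", "outcome")),
               "ICE FALCON model fitting failed")

  small <- simulate_twins(null_scenario(n_mz = 5, n_dz = 3), seed = 1)
  expect_error(run_ice_falcon(small, "exposure", "outcome"), "at least 10")

  df3 <- as.data.frame(d)
  df3$outcome <- df3$outcome + 5  # clearly not centred
  d3 <- twin_dataset(df3, traits = c("exposure", "outcome"))
  expect_warning(run_ice_falcon(d3, "exposure", "outcome"), "standardized")
})

test_that("ice_falcon_table flattens results into the reporting layout", {
  d <- simulate_twins(confounding_scenario(n_mz = 70, n_dz = 40), seed = 2)
  r <- run_ice_falcon(d, "exposure", "outcome")
  tab <- ice_falcon_table(r)
  expect_equal(nrow(tab), 1)
  expect_true(all(c("beta_cotwin", "beta_cotwin_adj", "change", "p_change",
                    "label") %in% names(tab)))
  expect_equal(tab$change, tab$beta_cotwin - tab$beta_cotwin_adj,
               tolerance = 1e-12)
})
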
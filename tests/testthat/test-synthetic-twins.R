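test_that("scenario validation enforces unit variance and parameter ranges", {
  expect_error(scenario_config(a_x = 1, c_x = 1, e_x = 0), "summing to 1")
  expect_error(scenario_config(rho_a = 1.2), "rho_a")
  expect_error(scenario_config(n_mz = 0, n_dz = 0), "at least one pair")
  expect_s3_class(causal_scenario(b = 0.2), "scenario_config")
})

test_that("implied covariance follows the path rules", {
  # no causal path, no confounding: cross-trait block is exactly zero
  sc0 <- null_scenario()
  m <- implied_covariance(sc0, "MZ")$matrix
  expect_equal(unname(m[1:2, 3:4]), matrix(0, 2, 2))

  # additive-genetic exposure: cross-twin covariance halves from MZ to DZ
  expect_equal(implied_covariance(sc0, "MZ")$matrix["X1", "X2"], 0.79)
  expect_equal(implied_covariance(sc0, "DZ")$matrix["X1", "X2"], 0.395)

  # exchangeable under swapping twins 1 and 2
  sc <- scenario_config(b = 0.3, rho_a = 0.4, rho_c = 0.2,
                        a_x = sqrt(0.5), c_x = sqrt(0.2), e_x = sqrt(0.3),
                        a_y = sqrt(0.4), c_y = sqrt(0.3), e_y = sqrt(0.3))
  for (z in c("MZ", "DZ")) {
    mm <- implied_covariance(sc, z)$matrix
    perm <- c(2, 1, 4, 3)
    expect_equal(unname(mm[perm, perm]), unname(mm), tolerance = 1e-12)
    expect_symmetric_psd(mm)
  }
})

test_that("simulated moments match the implied covariance (mixed scenario with covariate effects)", {
  sc <- scenario_config(n_mz = 130000, n_dz = 70000, b = 0.2, rho_a = 0.3,
                        a_y = sqrt(0.6), c_y = sqrt(0.1), e_y = sqrt(0.3),
                        slopes = c(age_x = 0.15, age_y = 0.1,
                                   height_x = 0.2, height_y = 0.25))
  d <- simulate_twins(sc, seed = 71)
  df <- as.data.frame(d)
  for (z in c("MZ", "DZ")) {
    sub <- df[df$zygosity == z, ]
    w <- cbind(X1 = sub$exposure[sub$twin_index == 1],
               X2 = sub$exposure[sub$twin_index == 2],
               Y1 = sub$outcome[sub$twin_index == 1],
               Y2 = sub$outcome[sub$twin_index == 2])
    emp <- cov(w)
    th <- implied_covariance(sc, z)$matrix
    n <- nrow(w)
    # SE of a normal-theory covariance estimate; 4-SE bound as a family-wise
    # allowance over the 16 (correlated) matrix elements
    se <- sqrt((outer(diag(th), diag(th)) + th^2) / n)
    expect_true(all(abs(emp - th) < 4 * se))
  }
})

test_that("population coefficients follow the projection algebra", {
  # pure causal: conditional independence zeroes the adjusted cross-pair slope
  sc <- causal_scenario(b = 0.4)
  for (w in c("independence", "exchangeable")) {
    pop <- expected_coefficients(sc, working = w)
    expect_equal(pop$beta_self_adj, rep(0.4, 3), tolerance = 1e-10)
    expect_equal(pop$beta_cotwin_adj, rep(0, 3), tolerance = 1e-10)
  }
  # under working independence the marginal slopes are plain projections
  pop_i <- expected_coefficients(sc, working = "independence")
  r_mz <- implied_covariance(sc, "MZ")$matrix["X1", "X2"]
  expect_equal(pop_i$beta_self[pop_i$group == "MZ"], 0.4, tolerance = 1e-12)
  expect_equal(pop_i$beta_cotwin[pop_i$group == "MZ"], 0.4 * r_mz,
               tolerance = 1e-12)

  # pure genetic confounding: adjusted cross-pair slope stays away from zero,
  # matching an independent 2x2 normal-equations solve
  scc <- confounding_scenario(rho_a = 0.6)
  pop_c <- expected_coefficients(scc)
  m <- implied_covariance(scc, "MZ")$matrix
  manual <- solve(matrix(c(1, m["X1", "X2"], m["X1", "X2"], 1), 2),
                  c(m["X1", "Y1"], m["X2", "Y1"]))
  expect_equal(pop_c$beta_cotwin_adj[pop_c$group == "MZ"], manual[2],
               tolerance = 1e-10)
  expect_gt(abs(pop_c$beta_cotwin_adj[pop_c$group == "pooled"]), 0.1)

  # nothing linking the traits: every coefficient vanishes
  pop0 <- expected_coefficients(null_scenario())
  expect_equal(unlist(pop0[-1]), unlist(pop0[-1]) * 0, tolerance = 1e-12)
})

test_that("all-unique-environment exposure kills the cross-pair slope even with b > 0", {
  sc <- scenario_config(a_x = 0, c_x = 0, e_x = 1, b = 0.5,
                        a_y = 0, c_y = 0, e_y = 1)
  pop <- expected_coefficients(sc)
  expect_equal(pop$beta_cotwin, rep(0, 3), tolerance = 1e-12)
  expect_equal(pop$beta_self, rep(0.5, 3), tolerance = 1e-12)
})

test_that("MZ cross-twin exposure covariance dominates DZ whenever genes matter", {
  for (a2 in c(0.2, 0.5, 0.79)) {
    sc <- scenario_config(a_x = sqrt(a2), c_x = sqrt(0.1), e_x = sqrt(0.9 - a2))
    expect_gt(implied_covariance(sc, "MZ")$matrix["X1", "X2"],
              implied_covariance(sc, "DZ")$matrix["X1", "X2"])
  }
})

test_that("simulation is deterministic in the seed and honours pair counts", {
  sc <- confounding_scenario(n_mz = 25, n_dz = 15)
  d1 <- simulate_twins(sc, seed = 5)
  d2 <- simulate_twins(sc, seed = 5)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- simulate_twins(sc, seed = 6)
  expect_false(identical(d1$exposure, d3$exposure))
  expect_equal(sum(d1$zygosity == "MZ"), 50)
  expect_equal(sum(d1$zygosity == "DZ"), 30)
})

test_that("large-sample GEE fits recover the population coefficients end to end", {
  sc <- confounding_scenario(n_mz = 2580, n_dz = 1420)
  d <- simulate_twins(sc, seed = 202)
  r <- run_ice_falcon(d, "exposure", "outcome")
  pop <- expected_coefficients(sc)
  pop <- pop[pop$group == "pooled", ]
  co <- r$coefficients
  for (nm in c("beta_self", "beta_cotwin", "beta_self_adj", "beta_cotwin_adj")) {
    expect_lt(abs(co[nm, "estimate"] - pop[[nm]]), 3.5 * co[nm, "se"])
  }
})
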
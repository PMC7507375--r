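# Small deterministic fixtures built in code.

# hand-written 2-pair dataset with known values
tiny_twin_df <- function() {
  data.frame(
    pair_id = c("p1", "p1", "p2", "p2"),
    twin_index = c(1L, 2L, 1L, 2L),
    zygosity = c("MZ", "MZ", "DZ", "DZ"),
    age = c(50, 50, 60, 60),
    height = c(160, 162, 158, 165),
    lean_mass = c(40, 42, 38, 45),
    bone = c(2.1, 2.3, 1.9, 2.6),
    stringsAsFactors = FALSE
  )
}

tiny_twin_dataset <- function() {
  twin_dataset(tiny_twin_df(), traits = c("lean_mass", "bone"))
}

# merge the trait columns of two simulated cohorts sharing the pair structure
merge_cohorts <- function(d1, d2) {
  stopifnot(nrow(d1) == nrow(d2), all(d1$pair_id == d2$pair_id))
  tr2 <- attr(d2, "trait_names")
  d <- as.data.frame(d1)
  for (v in tr2) d[[v]] <- d2[[v]]
  twin_dataset(d, traits = c(attr(d1, "trait_names"), tr2))
}

expect_symmetric_psd <- function(m, tol = 1e-10) {
  expect_lt(max(abs(m - t(m))), tol)
  expect_gt(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values), -tol)
}
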
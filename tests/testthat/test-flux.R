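test_that("atom percent and enrichment follow the printed formulas", {
  expect_equal(atom_percent(1, 99), 1)
  expect_equal(atom_percent(0, 5), 0)
  expect_equal(atom_percent(0.366, 99.634), 0.366)
  expect_error(atom_percent(0, 0), "zero")

  expect_equal(as.numeric(enrichment(0.366, 0.366)), 0)
  expect_equal(as.numeric(enrichment(0.466, 0.366)), 0.001)
  expect_equal(as.numeric(enrichment(10, 0.366)), 0.09634)

  # below control within tolerance clips to zero; beyond flags
  near <- enrichment(0.36595, 0.366, tol = 1e-4)
  expect_equal(as.numeric(near), 0)
  expect_false(attr(near, "flagged"))
  far <- enrichment(0.300, 0.366, tol = 1e-4)
  expect_true(attr(far, "flagged"))
  expect_lt(as.numeric(far), 0)
})

test_that("nitrogen quantities scale as DW x N% x E", {
  expect_equal(n_quantities(100, 5, 0), list(qty_n_mg = 5, qty_n15_mg = 0))
  expect_equal(n_quantities(200, 4, 0.001),
               list(qty_n_mg = 8, qty_n15_mg = 0.008))
  expect_equal(n_quantities(100, 0, 0.5)$qty_n_mg, 0)
  q <- n_quantities(c(50, 80), c(3, 2), c(0.01, 0.02))
  expect_true(all(q$qty_n15_mg <= q$qty_n_mg))
  expect_error(n_quantities(-1, 5, 0), "positive")
})

test_that("partition fractions reproduce HI and the allocation ratios", {
  sym <- data.frame(organ = c("rosette", "stem", "seeds"),
                    dw_mg = 30, qty_n_mg = 1, qty_n15_mg = 0.1)
  pf <- partition_fractions(sym)
  expect_equal(pf$hi, 1 / 3)
  expect_equal(unname(pf$n_alloc), rep(1 / 3, 3))
  expect_equal(unname(pf$n15_alloc), rep(1 / 3, 3))
  expect_equal(pf$nhi, 1 / 3)

  asym <- data.frame(organ = c("rosette", "stem", "seeds"),
                     dw_mg = c(50, 30, 20), qty_n_mg = c(1, 1, 2),
                     qty_n15_mg = c(0.2, 0.3, 0.5))
  pf2 <- partition_fractions(asym)
  expect_equal(pf2$hi, 0.2)
  expect_equal(pf2$nhi, 0.5)
  expect_equal(pf2$nhi15, 0.5)
  expect_equal(sum(pf2$n_alloc), 1, tolerance = 1e-9)
  expect_equal(sum(pf2$n15_alloc), 1, tolerance = 1e-9)

  expect_error(partition_fractions(asym[1:2, ]), "rosette, stem, seeds")
})

test_that("NRE is the seed tracer share over the harvest index", {
  expect_equal(remobilization_efficiency(0.3, 0.3), 1)
  expect_equal(remobilization_efficiency(0.6, 0.3), 2)
  expect_error(remobilization_efficiency(0.5, 0), "HI")
})

test_that("NUpE is pulse N per unit biomass and is scale invariant", {
  q <- c(rosette = 0.3, stem = 0.1, seeds = 0.1)
  dw <- c(rosette = 500, stem = 300, seeds = 200)
  expect_equal(uptake_efficiency(q, dw, e_solution = 0.10), 5)
  expect_equal(uptake_efficiency(2 * q, 2 * dw, e_solution = 0.10), 5)
  expect_equal(uptake_efficiency(0 * q, dw, e_solution = 0.10), 0)
  # root excluded by default, included on request
  q2 <- c(q, root = 0.5); dw2 <- c(dw, root = 1000)
  expect_equal(uptake_efficiency(q2, dw2, e_solution = 0.10), 5)
  expect_equal(uptake_efficiency(q2, dw2, e_solution = 0.10,
                                 include_root = TRUE), 5)
  expect_error(uptake_efficiency(q, dw, e_solution = 0), "E_solution")
})

test_that("translocation profile is the per-organ tracer share", {
  all_root <- translocation_profile(c(root = 0.4, rosette = 0, silique = 0))
  expect_equal(as.numeric(all_root), c(1, 0, 0))
  four <- translocation_profile(c(root = 1, rosette = 1, stem = 1, silique = 1))
  expect_equal(as.numeric(four), rep(0.25, 4))
  none <- translocation_profile(c(root = 0, rosette = 0))
  expect_true(all(is.na(none)))
  expect_equal(attr(none, "flagged"), "zero_total_tracer")
})

test_that("allocations conserve mass and are scale invariant per plant", {
  sim <- simulate_labeling_dataset(n_plants = 12, seed = 401)
  fs <- flux_summary(sim$samples)
  a_sum <- fs$n_alloc_rosette + fs$n_alloc_stem + fs$n_alloc_seeds
  a15_sum <- fs$n15_alloc_rosette + fs$n15_alloc_stem + fs$n15_alloc_seeds
  expect_equal(a_sum, rep(1, nrow(fs)), tolerance = 1e-9)
  expect_equal(a15_sum, rep(1, nrow(fs)), tolerance = 1e-9)

  scaled <- sim$samples
  lab <- scaled$experiment != "control"
  scaled$dw_mg[lab] <- scaled$dw_mg[lab] * 3.7
  fs2 <- flux_summary(scaled)
  expect_equal(fs2$hi, fs$hi, tolerance = 1e-12)
  expect_equal(fs2$nhi15, fs$nhi15, tolerance = 1e-12)
  expect_equal(fs2$nre, fs$nre, tolerance = 1e-12)
})

test_that("zero enrichment flags NRE undefined instead of propagating NaN", {
  sim <- simulate_labeling_dataset(n_plants = 3, bio_cv = 0, meas_cv = 0,
                                   tracer_total_mg = 0, seed = 5)
  # every organ sits at the control atom percent
  expect_true(all(abs(sim$samples$a15n_pct - 0.366) < 1e-12))
  fs <- flux_summary(sim$samples)
  expect_true(all(is.na(fs$nre)))
  expect_true(all(is.na(fs$nhi15)))
  expect_true(all(grepl("zero_total_tracer", fs$flags)))
  expect_false(any(is.nan(unlist(fs[sapply(fs, is.numeric)]))))
})

test_that("NRE recovery: 18-plant cohorts average near truth at CV 10%", {
  set.seed(123)
  nre <- replicate(60, {
    sim <- simulate_labeling_dataset(n_plants = 18)
    mean(flux_summary(sim$samples)$nre)
  })
  expect_lt(abs(mean(nre) - 2), 0.1)
  expect_gt(mean(abs(nre - 2) <= 0.2), 0.9)
})
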
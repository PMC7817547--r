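test_that("identical seeds give byte-identical simulated tables", {
  map <- sim_marker_map(10)
  a <- simulate_progeny_genotypes(map, 50, seed = 99)
  b <- simulate_progeny_genotypes(map, 50, seed = 99)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$extra_genotypes, b$extra_genotypes)

  la <- simulate_labeling_dataset(n_plants = 5, seed = 7)
  lb <- simulate_labeling_dataset(n_plants = 5, seed = 7)
  expect_identical(la$samples, lb$samples)
  expect_identical(la$truth, lb$truth)
})

test_that("zero map distance produces zero recombinants at any sample size", {
  map <- sim_marker_map(12)
  sim <- simulate_progeny_genotypes(map, 300, cm_per_mb = 0, seed = 5)
  expect_length(detect_recombinants(sim$genotypes, map), 0L)
})

test_that("simulated recombination fraction matches the Haldane closed form", {
  # two loci at d = 0.1 Morgan: r = (1 - exp(-0.2)) / 2 = 0.0906346
  d_mb <- 0.1 * 100 / 3  # Mb giving 0.1 Morgan at 3 cM/Mb
  map <- marker_map(c("l", "r"), "1", round(c(1e6, 1e6 + d_mb * 1e6)))
  sim <- simulate_progeny_genotypes(map, 5000, cm_per_mb = 3, seed = 2024)
  frac <- mean(sim$truth$crossovers[, 1])   # 10,000 gametes
  r <- (1 - exp(-0.2)) / 2
  expect_lt(abs(frac - r), 3 * sqrt(r * (1 - r) / 10000))
  # large-distance limit approaches one half
  far <- marker_map(c("l", "r"), "1", c(1e6, 5e9))
  simfar <- simulate_progeny_genotypes(far, 3000, cm_per_mb = 3, seed = 1)
  expect_lt(abs(mean(simfar$truth$crossovers[, 1]) - 0.5), 0.03)
})

test_that("phenotype model is additive in B dosage with Gaussian noise", {
  ph <- simulate_phenotypes(c(0L, 1L, 2L), effect_size = 0.2, noise_sd = 0,
                            baseline = 0.2)
  expect_equal(ph, c(0.2, 0.3, 0.4))

  # no effect, no association
  set.seed(3)
  dos <- sample(c(0L, 2L), 1000, replace = TRUE)
  ph0 <- simulate_phenotypes(dos, effect_size = 0, noise_sd = 0.05)
  expect_lt(abs(coef(lm(ph0 ~ dos))[2]), 0.01)

  # power at the campaign settings: homozygote classes separate at alpha 0.05
  hits <- replicate(100, {
    a <- simulate_phenotypes(rep(0L, 12), 0.2, 0.05)
    b <- simulate_phenotypes(rep(2L, 12), 0.2, 0.05)
    progeny_test(a, b)$verdict == "segregating"
  })
  expect_gte(mean(hits), 0.99)
})

test_that("labeling generator is the exact inverse of the flux pipeline", {
  sim <- simulate_labeling_dataset(n_plants = 6, bio_cv = 0, meas_cv = 0,
                                   seed = 13)
  fs <- flux_summary(sim$samples)
  expect_equal(fs$nre, sim$truth$nre, tolerance = 1e-12)
  expect_equal(fs$hi, sim$truth$hi, tolerance = 1e-12)
  expect_equal(fs$nhi15, sim$truth$nhi15, tolerance = 1e-12)
  # generated control samples carry zero enrichment
  ctrl <- sim$samples[sim$samples$experiment == "control", ]
  expect_equal(as.numeric(enrichment(ctrl$a15n_pct, 0.366)),
               rep(0, nrow(ctrl)))
  # tracer never exceeds total N before noise
  q <- n_quantities(sim$samples$dw_mg, sim$samples$n_pct,
                    pmax(as.numeric(enrichment(sim$samples$a15n_pct, 0.366)), 0))
  expect_true(all(q$qty_n15_mg <= q$qty_n_mg + 1e-12))
})

test_that("a simulated campaign recovers the causal position", {
  camp <- run_finemap_campaign(seed = 4242)
  expect_true(camp$covered)
  expect_gt(length(camp$recombinants), 30)
  expect_true(all(camp$calls$verdict %in%
                    c("segregating", "non_segregating")))
  # candidate bounds are marker positions
  map <- sim_marker_map()
  expect_true(all(camp$candidate$intervals$start_bp %in% map$pos_bp))
  expect_true(all(camp$candidate$intervals$end_bp %in% map$pos_bp))
})
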
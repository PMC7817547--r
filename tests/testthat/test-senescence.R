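test_that("senescent leaf fraction is yellow over total at bolting", {
  expect_equal(senescent_leaf_fraction(5, 20), 0.25)
  expect_equal(senescent_leaf_fraction(0, 15), 0)
  expect_equal(senescent_leaf_fraction(15, 15), 1)
  expect_error(senescent_leaf_fraction(16, 15), "exceed")
  expect_error(senescent_leaf_fraction(1, 0), ">= 1")
})

test_that("leaf ranks partition into the four fixed groups", {
  expect_equal(as.character(assign_leaf_group(c(1, 10))), c("OL", "OL"))
  expect_equal(as.character(assign_leaf_group(c(11, 20))), c("ML", "ML"))
  expect_equal(as.character(assign_leaf_group(c(21, 30))), c("YL", "YL"))
  expect_equal(as.character(assign_leaf_group(c(31, 44))), c("NL", "NL"))
  # every rank belongs to exactly one group
  g <- assign_leaf_group(1:60)
  expect_false(anyNA(g))
  expect_error(assign_leaf_group(0), "positive")
})

test_that("onset detection follows the sustained-drop rule", {
  das <- seq(20, 80, by = 4)
  # strictly increasing series: no onset
  up <- detect_senescence_onset(das, seq_along(das), flower_bud_das = 52)
  expect_true(is.na(up$onset_das))
  expect_equal(up$phase, "none")

  # rise to a max at 40, decline from 44: onset 44, before bud emergence
  chl <- c(10, 12, 14, 16, 18, 20, 15, 12, 9, 7, 5, 4, 3, 2, 1, 1)
  res <- detect_senescence_onset(das, chl, flower_bud_das = 52)
  expect_equal(res$onset_das, 44)
  expect_equal(res$phase, "sequential")
  # same decline after bud emergence is monocarpic
  expect_equal(detect_senescence_onset(das, chl, flower_bud_das = 30)$phase,
               "monocarpic")

  # a single shallow dip below threshold does not trigger
  dip <- c(10, 12, 14, 16, 18, 20, 19.8, 20, 20, 20, 20, 20, 20, 20, 20, 20)
  expect_true(is.na(detect_senescence_onset(das, dip, 52,
                                            drop_threshold = 0.05)$onset_das))
  expect_error(detect_senescence_onset(c(1, 2), c(3, 2), 52), "3 observations")
})

test_that("onset is invariant under uniform rescaling of the index", {
  sim <- simulate_chlorophyll_kinetics(n_plants = 1, leaf_ranks = c(5, 15),
                                       noise_sd = 0.02, seed = 9)
  for (s in split(sim$series,
                  interaction(sim$series$plant_id, sim$series$leaf_rank,
                              drop = TRUE))) {
    o1 <- detect_senescence_onset(s$das, s$chl_index, s$flower_bud_das[1])
    o2 <- detect_senescence_onset(s$das, 100 * s$chl_index, s$flower_bud_das[1])
    expect_identical(o1, o2)
  }
})

test_that("zero-noise generator onsets are recovered exactly at every rank", {
  sim <- simulate_chlorophyll_kinetics(n_plants = 2,
                                       leaf_ranks = c(3, 8, 14, 20),
                                       noise_sd = 0, seed = 31)
  key <- interaction(sim$series$plant_id, sim$series$leaf_rank, drop = TRUE)
  tkey <- interaction(sim$truth$plant_id, sim$truth$leaf_rank, drop = TRUE)
  for (k in levels(key)) {
    s <- sim$series[key == k, ]
    got <- detect_senescence_onset(s$das, s$chl_index, s$flower_bud_das[1])
    expect_equal(got$onset_das, sim$truth$onset_das[tkey == k])
  }
})

test_that("genotype onset shift is recovered within one sampling interval", {
  set.seed(61)
  diffs <- replicate(30, {
    ref <- simulate_chlorophyll_kinetics(n_plants = 2, leaf_ranks = c(5, 10),
                                         noise_sd = 0.02)
    early <- simulate_chlorophyll_kinetics(n_plants = 2, leaf_ranks = c(5, 10),
                                           genotype_shift = -8,
                                           noise_sd = 0.02, genotype = "early")
    onset_mean <- function(sim) {
      key <- interaction(sim$series$plant_id, sim$series$leaf_rank, drop = TRUE)
      mean(vapply(split(sim$series, key), function(s)
        detect_senescence_onset(s$das, s$chl_index,
                                s$flower_bud_das[1])$onset_das, numeric(1)))
    }
    onset_mean(early) - onset_mean(ref)
  })
  expect_gte(mean(abs(diffs - (-8)) <= 4), 0.95)
})
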
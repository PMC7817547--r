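test_that("refinement matches the brute-force oracle on the spec geometry", {
  map <- marker_map(paste0("m", 1:5), "4", (1:5) * 1e6)

  # one segregating, one non-segregating line
  lines <- data.frame(line_id = c("L1", "L2"),
                      start_bp = c(2e6, 3e6), end_bp = c(4e6, 5e6),
                      verdict = c("segregating", "non_segregating"))
  got <- refine_candidate_interval(lines, map, prior = c(1e6, 5e6))
  expect_equal(got$intervals$start_bp, 2e6)
  expect_equal(got$intervals$end_bp, 3e6)
  expect_true(refine_matches_oracle(
    list(map = map, pos = map$pos_bp, lines = lines, prior = c(1e6, 5e6))))

  # two segregating lines intersect
  lines2 <- data.frame(line_id = c("L1", "L2"),
                       start_bp = c(2e6, 3e6), end_bp = c(4e6, 5e6),
                       verdict = c("segregating", "segregating"))
  got2 <- refine_candidate_interval(lines2, map, prior = c(1e6, 5e6))
  expect_equal(got2$intervals$start_bp, 3e6)
  expect_equal(got2$intervals$end_bp, 4e6)
})

test_that("published marker positions reproduce the printed interval widths", {
  map <- published_map()
  prior <- c(7180000, 13079020)
  expect_equal(prior[2] - prior[1], 5899020)  # the 5.9-Mb screen region

  first <- refine_candidate_interval(
    published_lines()[1, ], map, prior = prior)
  expect_equal(first$intervals$width_bp, 117552)  # the 117.5-kb interval

  final <- refine_candidate_interval(published_lines(), map, prior = prior)
  expect_equal(final$intervals$start_bp, 8290453)
  expect_equal(final$intervals$end_bp, 8298328)
  expect_equal(final$intervals$width_bp, 7875)
  expect_length(final$conflicts, 0L)
})

test_that("open-interior subtraction keeps shared bound markers and splits", {
  map <- marker_map(paste0("m", 1:5), "4", (1:5) * 1e6)
  # subtracting an interior interval splits the candidate in two
  lines <- data.frame(line_id = c("S", "N"),
                      start_bp = c(1e6, 2e6), end_bp = c(5e6, 4e6),
                      verdict = c("segregating", "non_segregating"))
  got <- refine_candidate_interval(lines, map, prior = c(1e6, 5e6))
  expect_equal(got$intervals$start_bp, c(1e6, 4e6))
  expect_equal(got$intervals$end_bp, c(2e6, 5e6))

  # a shared bound marker survives as a zero-width candidate
  lines2 <- data.frame(line_id = c("S", "N"),
                       start_bp = c(2e6, 2e6), end_bp = c(4e6, 5e6),
                       verdict = c("segregating", "non_segregating"))
  got2 <- refine_candidate_interval(lines2, map, prior = c(1e6, 5e6))
  expect_equal(got2$intervals$start_bp, 2e6)
  expect_equal(got2$intervals$width_bp, 0)
})

test_that("contradictory calls raise an inconsistency error naming lines", {
  map <- marker_map(paste0("m", 1:5), "4", (1:5) * 1e6)
  lines <- data.frame(line_id = c("L1", "L2"),
                      start_bp = c(1e6, 1e6), end_bp = c(2e6, 3e6),
                      verdict = c("segregating", "non_segregating"))
  # seg wants [1,2] Mb; non-seg interior (1,3) Mb leaves only the 1-Mb bound
  got <- refine_candidate_interval(lines, map, prior = c(1e6, 5e6))
  expect_equal(got$intervals$start_bp, 1e6)
  expect_equal(got$intervals$width_bp, 0)

  lines2 <- data.frame(line_id = c("L1", "L2"),
                       start_bp = c(1e6, 3e6), end_bp = c(2e6, 5e6),
                       verdict = c("segregating", "segregating"))
  err <- tryCatch(refine_candidate_interval(lines2, map, prior = c(1e6, 5e6)),
                  error = function(e) e)
  expect_s3_class(err, "hifflux_inconsistency_error")
  expect_match(conditionMessage(err), "L1")
  expect_match(conditionMessage(err), "L2")
})

test_that("refinement equals the oracle on random instances", {
  set.seed(202)
  for (k in 1:200) {
    inst <- random_refine_instance()
    expect_true(refine_matches_oracle(inst))
  }
})

test_that("adding a line never enlarges the candidate region", {
  set.seed(77)
  total_width <- function(ci) sum(ci$intervals$width_bp)
  cover <- function(ci, x) any(ci$intervals$start_bp <= x &
                                 ci$intervals$end_bp >= x)
  for (k in 1:50) {
    inst <- random_refine_instance(max_lines = 8)
    if (nrow(inst$lines) < 2) next
    sub <- inst$lines[-nrow(inst$lines), , drop = FALSE]
    full <- tryCatch(refine_candidate_interval(inst$lines, inst$map, inst$prior),
                     hifflux_inconsistency_error = function(e) NULL)
    part <- tryCatch(refine_candidate_interval(sub, inst$map, inst$prior),
                     hifflux_inconsistency_error = function(e) NULL)
    if (is.null(full)) next  # empty is the smallest region: monotone
    expect_false(is.null(part))
    expect_lte(total_width(full), total_width(part))
    # every surviving marker of the full set survives in the subset result
    for (p in inst$pos) {
      if (cover(full, p)) expect_true(cover(part, p))
    }
  }
})
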
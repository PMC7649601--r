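worked_series <- c(A = 10, B = 9, C = 5, D = 4)

test_that("contribution ratio and difference follow the last/A rules", {
  expect_equal(contribution_ratio(worked_series), 0.4)
  expect_equal(contribution_ratio(c(A = 7, B = 7, C = 7)), 1.0)
  expect_equal(contribution_difference(worked_series), 6)
  expect_equal(contribution_difference(c(A = 7, B = 7, C = 7)), 0)
  # single-test plant (no whorls in soil): neutral by convention
  expect_equal(contribution_ratio(c(A = 5)), 1)
  expect_equal(contribution_difference(c(A = 5)), 0)
  expect_length(whorl_ratios(c(A = 5)), 0L)

  expect_error(contribution_ratio(c(A = 10, C = 4)),
               class = "braceroot_contiguity_error")
  expect_error(contribution_ratio(c(A = -1, B = 2)),
               class = "braceroot_domain_error")
  # label order in the vector must not matter
  expect_equal(contribution_ratio(worked_series[c(3, 1, 4, 2)]), 0.4)
})

test_that("per-whorl ratios are adjacent-label ratios numbered from the soil", {
  wr <- whorl_ratios(worked_series)
  expect_equal(wr, c(Whorl1 = 0.8, Whorl2 = 5 / 9, Whorl3 = 0.9))
  expect_equal(prod(wr), contribution_ratio(worked_series))
  expect_equal(whorl_ratios(c(A = 8, B = 6)), c(Whorl1 = 0.75))
})

test_that("telescoping and scale invariance hold over randomized series", {
  set.seed(2024)
  for (i in 1:300) {
    n <- sample(2:4, 1)
    s <- stats::setNames(rlnorm(n, meanlog = 3, sdlog = 0.6), LETTERS[seq_len(n)])
    r <- contribution_ratio(s)
    expect_equal(prod(whorl_ratios(s)), r, tolerance = 1e-12)
    expect_equal(contribution_difference(s), s[["A"]] * (1 - r),
                 tolerance = 1e-12)
    # scale invariance
    c0 <- runif(1, 0.1, 10)
    expect_equal(contribution_ratio(c0 * s), r, tolerance = 1e-12)
    expect_equal(whorl_ratios(c0 * s), whorl_ratios(s), tolerance = 1e-12)
    expect_equal(contribution_difference(c0 * s),
                 c0 * contribution_difference(s), tolerance = 1e-12)
  }
})

test_that("ratio is scale-free in the generating slope", {
  set.seed(7)
  for (i in 1:50) {
    k <- runif(1, 1, 100)
    r <- runif(1, 0.05, 1.5)
    expect_equal(contribution_ratio(c(A = k, B = k * r)), r, tolerance = 1e-12)
  }
})

test_that("beam-length correction maps the pure-geometry null to one", {
  # ((0.64 - 0.032)/0.64)^3 computed directly
  g <- (0.608 / 0.64)^3
  expect_equal(g, 0.857375)
  expect_equal(beam_corrected_ratio(0.857375, 0.64, 0.032), 1.0,
               tolerance = 1e-12)
  # zero attachment height: correction is the identity
  expect_identical(beam_corrected_ratio(0.7, 0.64, 0), 0.7)
  # alternative direction multiplies instead
  expect_equal(beam_corrected_ratio(1, 0.64, 0.032, direction = "multiply"),
               0.857375)
  # missing attachment height: not computable, skip signal
  expect_true(is.na(beam_corrected_ratio(0.7, 0.64, NA_real_)))
  expect_error(beam_corrected_ratio(0.7, 0.64, 0.64),
               class = "braceroot_geometry_error")
  expect_error(beam_corrected_ratio(-1, 0.64, 0.01),
               class = "braceroot_domain_error")
})

test_that("simulated pure beam lengthening closes the loop with the correction", {
  p0 <- protocol_config(noise_sd_N = 0)
  for (a in c(0.015, 0.032)) {
    s <- simulate_pure_beam_lengthening(1, 0.64, a, p0, seed = 1)
    slopes <- vapply(s$traces, function(t) fit_slope_full(t)$slope_N_per_m,
                     numeric(1))
    r <- contribution_ratio(slopes)
    expect_equal(r, ((0.64 - a) / 0.64)^3, tolerance = 1e-9)
    expect_equal(beam_corrected_ratio(r, 0.64, a), 1, tolerance = 1e-9)
  }
})

test_that("contribution_result bundles the pieces consistently", {
  res <- contribution_result(worked_series, load_height_m = 0.64,
                             attachment_height_m = 0.02)
  expect_s3_class(res, "contribution_result")
  expect_equal(res$ratio, 0.4)
  expect_equal(res$difference, 6)
  expect_equal(prod(res$whorl_ratios), res$ratio)
  expect_equal(res$corrected_ratio,
               beam_corrected_ratio(0.4, 0.64, 0.02))
  expect_true(is.na(contribution_result(worked_series)$corrected_ratio))
})
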
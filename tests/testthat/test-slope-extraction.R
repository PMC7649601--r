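test_that("rotation converts to radians and deflection by the device equations", {
  expect_equal(degrees_to_radians(180), pi)
  expect_equal(degrees_to_radians(0), 0)
  expect_equal(degrees_to_radians(90), pi / 2)
  expect_equal(rotation_to_deflection(0, 0.64), 0)
  expect_equal(rotation_to_deflection(pi / 2, 1.0), 1.0)
  # protocol angle at the standard load height, against direct evaluation
  expect_equal(rotation_to_deflection(degrees_to_radians(15), 0.64),
               0.16564418886561327, tolerance = 1e-12)
  expect_error(degrees_to_radians(NaN), class = "braceroot_domain_error")
  expect_error(rotation_to_deflection(0.1, 0), class = "braceroot_domain_error")
})

test_that("conversion chain is monotone in angle and load height", {
  th <- seq(0, pi / 2, length.out = 50)
  d1 <- rotation_to_deflection(th, 0.6)
  expect_true(all(diff(d1) > 0))
  expect_true(all(rotation_to_deflection(th[-1], 0.64) >
                    rotation_to_deflection(th[-1], 0.60)))
})

test_that("cycle parser finds triangle-wave loading legs and applies both filters", {
  tr <- linear_trace(50) # 3 cycles, 50 points/leg, peak 15 deg (~0.166 m)
  fd <- trace_deflection(tr)
  cyc <- parse_loading_cycles(fd)
  expect_equal(nrow(cyc), 3L)
  # generator oracle: each loading leg is points_per_leg + 1 samples
  expect_equal(cyc$end - cyc$start + 1L, rep(51L, 3))
  expect_true(all(cyc$span_m > 0.15))

  # spans below the 0.02 m floor are rejected
  small <- simulate_trace(50, protocol_config(noise_sd_N = 0, max_angle_deg = 0.9),
                          seed = 1)
  expect_equal(nrow(parse_loading_cycles(trace_deflection(small))), 0L)

  # a 9-point monotone rise is one short of a cycle
  d9 <- seq(0, 0.1, length.out = 9)
  expect_equal(nrow(parse_loading_cycles(d9)), 0L)
  expect_equal(nrow(parse_loading_cycles(seq(0, 0.1, length.out = 10))), 1L)

  expect_equal(nrow(parse_loading_cycles(numeric(0))), 0L)
  expect_error(parse_loading_cycles(d9, min_run = 1),
               class = "braceroot_parameter_error")
})

test_that("cycles are disjoint, ordered, and stable under truncation", {
  tr <- simulate_trace(42, protocol_config(noise_sd_N = 0.4), seed = 5)
  fd <- trace_deflection(tr)
  cyc <- parse_loading_cycles(fd)
  expect_gt(nrow(cyc), 0L)
  expect_true(all(diff(cyc$start) > 0))
  if (nrow(cyc) > 1L) expect_true(all(cyc$start[-1] > cyc$end[-nrow(cyc)]))
  # dropping trailing samples cannot alter earlier cycles
  cut <- fd[seq_len(cyc$end[nrow(cyc)] - 5L), ]
  cyc2 <- parse_loading_cycles(cut)
  keep <- seq_len(nrow(cyc) - 1L)
  expect_equal(cyc2[keep, ], cyc[keep, ])
})

test_that("full fit is OLS over everything, matching an independent slope oracle", {
  tr <- linear_trace(50)
  est <- fit_slope_full(tr)
  expect_equal(est$slope_N_per_m, 50, tolerance = 1e-12)
  expect_equal(est$r_squared, 1, tolerance = 1e-12)
  expect_identical(est$method, "full")

  two <- data.frame(deflection_m = c(0, 0.1), force_N = c(0, 5))
  expect_equal(fit_slope_full(two)$slope_N_per_m, 50)

  fd <- hysteretic_fd(50, 40)
  est2 <- fit_slope_full(fd)
  expect_gt(est2$slope_N_per_m, 40)
  expect_lt(est2$slope_N_per_m, 50)
  expect_equal(est2$slope_N_per_m, oracle_slope(fd$deflection_m, fd$force_N),
               tolerance = 1e-12)

  flat <- data.frame(deflection_m = rep(0.1, 5), force_N = 1:5)
  expect_error(fit_slope_full(flat), class = "braceroot_degenerate_fit")
})

test_that("loading-only fit isolates the loading legs of a hysteretic trace", {
  p <- protocol_config(noise_sd_N = 0, hysteresis_factor = 0.8)
  tr <- simulate_trace(50, p, seed = 1)
  fd <- trace_deflection(tr)
  cyc <- parse_loading_cycles(fd)
  est <- fit_slope_loading(fd, cyc)
  expect_equal(est$slope_N_per_m, 50, tolerance = 1e-9)
  expect_identical(est$method, "loading")
  expect_equal(est$cycles_used, 3L)
  # oracle: OLS restricted to the loading rows only
  rows <- unlist(Map(seq, cyc$start, cyc$end))
  expect_equal(est$slope_N_per_m,
               oracle_slope(fd$deflection_m[rows], fd$force_N[rows]),
               tolerance = 1e-12)
  # on a pure linear trace it agrees with the full fit
  lin <- trace_deflection(linear_trace(31))
  expect_equal(fit_slope_loading(lin)$slope_N_per_m,
               fit_slope_full(lin)$slope_N_per_m, tolerance = 1e-9)
  expect_error(fit_slope_loading(fd, cyc[0, ]), class = "braceroot_no_cycle")
})

test_that("loading slope dominates the full slope under loading-biased hysteresis", {
  set.seed(99)
  for (s in 1:5) {
    p <- protocol_config(noise_sd_N = 0.1,
                         hysteresis_factor = runif(1, 0.6, 0.95))
    tr <- simulate_trace(runif(1, 20, 80), p, seed = 100 + s)
    fd <- trace_deflection(tr)
    expect_gte(fit_slope_loading(fd)$slope_N_per_m,
               fit_slope_full(fd)$slope_N_per_m)
  }
})

test_that("RANSAC recovers the line, is seeded, and rejects the contaminated cycle", {
  tr <- linear_trace(50)
  fd <- trace_deflection(tr)
  est <- fit_slope_ransac(fd, seed = 42)
  expect_equal(est$slope_N_per_m, 50, tolerance = 1e-9)
  expect_equal(est$cycles_used, 1L) # tie among clean cycles -> earliest

  est2 <- fit_slope_ransac(fd, seed = 42)
  expect_identical(est, est2)

  # burst contamination in cycle 2: selection must avoid it
  cyc <- parse_loading_cycles(fd)
  fd2 <- fd
  c2 <- seq(cyc$start[2], cyc$end[2])
  burst <- c2[10:24] # 15 of 51 points (~30%) knocked far off the line
  fd2$force_N[burst] <- fd2$force_N[burst] + 25
  est3 <- fit_slope_ransac(fd2, residual_threshold_N = 0.5, seed = 7)
  expect_false(est3$cycles_used == 2L)
  expect_equal(est3$slope_N_per_m, 50, tolerance = 1e-6)

  expect_error(fit_slope_ransac(fd, cycles = cyc[0, ]),
               class = "braceroot_no_cycle")
})

test_that("RANSAC ignores appended outlier samples beyond the consensus", {
  tr <- linear_trace(64)
  fd <- trace_deflection(tr)
  base <- fit_slope_ransac(fd, seed = 3)
  # append a short wild tail: too short to form a cycle, far off the line
  tail_df <- data.frame(index = max(fd$index) + 1:5,
                        deflection_m = seq(0.01, 0.05, length.out = 5),
                        force_N = c(90, 4, 77, 12, 60))
  aug <- fit_slope_ransac(rbind(fd, tail_df), seed = 3)
  expect_equal(aug$slope_N_per_m, base$slope_N_per_m, tolerance = 1e-9)
})

test_that("all three methods recover a noise-free proportional trace to 0.1%", {
  for (k in c(12.5, 40, 97)) {
    tr <- linear_trace(k)
    fd <- trace_deflection(tr)
    ests <- c(fit_slope_full(fd)$slope_N_per_m,
              fit_slope_loading(fd)$slope_N_per_m,
              fit_slope_ransac(fd, seed = 1)$slope_N_per_m)
    expect_true(all(abs(ests - k) / k < 1e-3))
  }
})

test_that("extract_slope falls back to the full fit on wind-killed traces", {
  p <- protocol_config(noise_sd_N = 0.2,
                       wind_burst = list(prob = 1, magnitude_N = 4,
                                         magnitude_deg = 25, duration = 300))
  tr <- simulate_trace(40, p, seed = 8)
  expect_equal(nrow(parse_loading_cycles(trace_deflection(tr))), 0L)
  est <- extract_slope(tr, method = "loading")
  expect_identical(est$method, "full")
  expect_true(est$fallback)
  expect_error(extract_slope(tr, method = "loading", fallback_to_full = FALSE),
               class = "braceroot_no_cycle")
})

test_that("compare_methods returns a symmetric unit-diagonal matrix", {
  traces <- lapply(c(20, 35, 50, 65), linear_trace)
  m <- compare_methods(traces)
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_equal(m, t(m))
  expect_true(all(m > 0.999)) # methods coincide on noise-free lines
  expect_error(compare_methods(traces[1:2]),
               class = "braceroot_sample_size_error")
})
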
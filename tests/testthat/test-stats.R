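test_that("pearson matches known limits and validates input", {
  x <- 1:20
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  set.seed(123)
  a <- rnorm(1e4); b <- rnorm(1e4)
  expect_lt(abs(pearson(a, b)$r), 0.05)
  expect_error(pearson(1:2, 1:2), class = "braceroot_sample_size_error")
  expect_error(pearson(rep(1, 5), 1:5), class = "braceroot_degenerate_error")
})

test_that("one-way ANOVA handles degenerate and limiting shapes", {
  g0 <- list(a = c(1, 1), b = c(1, 1))
  expect_true(one_way_anova(g0)$degenerate)
  g1 <- list(a = c(0, 0), b = c(1, 1))
  res <- one_way_anova(g1)
  expect_identical(res$F, Inf)
  expect_identical(res$p, 0)
  # agrees with the standard machinery on regular data
  set.seed(1)
  g <- list(a = rnorm(10), b = rnorm(10, 1), c = rnorm(10, 2))
  res2 <- one_way_anova(g)
  ref <- summary(stats::aov(v ~ f, data.frame(v = unlist(g),
                                              f = rep(names(g), each = 10))))[[1]]
  expect_equal(res2$F, ref[["F value"]][1])
  expect_equal(res2$p, ref[["Pr(>F)"]][1])
  expect_error(one_way_anova(list(a = 1, b = 1:3)),
               class = "braceroot_sample_size_error")
})

test_that("two-group Tukey HSD reduces to the pooled-variance t-test", {
  set.seed(21)
  g <- list(a = rnorm(12, 0), b = rnorm(10, 0.8))
  tk <- tukey_hsd(g)
  tt <- stats::t.test(g$b, g$a, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-9)
  expect_equal(tk$diff, mean(g$b) - mean(g$a))
})

test_that("Tukey HSD rows permute with group labels and values survive", {
  set.seed(4)
  g <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2))
  t1 <- tukey_hsd(g)
  t2 <- tukey_hsd(g[c("c", "a", "b")])
  m1 <- t1$p_adj[order(t1$pair)]
  # re-express t2 pairs in sorted-label form before comparing
  canon <- function(tk) {
    parts <- strsplit(tk$pair, "-", fixed = TRUE)
    key <- vapply(parts, function(p) paste(sort(p), collapse = "-"), "")
    stats::setNames(tk$p_adj, key)[order(key)]
  }
  expect_equal(unname(canon(t2)), unname(canon(t1)), tolerance = 1e-9)
})

test_that("shifted group carries the smallest adjusted p", {
  set.seed(11)
  g <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20, 2))
  tk <- tukey_hsd(g)
  involved <- grepl("c", tk$pair)
  expect_lt(max(tk$p_adj[involved]), min(tk$p_adj[!involved]))
  # direct studentized-range evaluation as oracle for one pair
  df <- data.frame(v = unlist(g), f = rep(names(g), each = 20))
  msw <- summary(stats::aov(v ~ f, df))[[1]][["Mean Sq"]][2]
  q <- abs(mean(g$c) - mean(g$a)) / sqrt(msw / 20)
  p_or <- stats::ptukey(q, nmeans = 3, df = 57, lower.tail = FALSE)
  expect_equal(tk$p_adj[tk$pair == "c-a"], p_or, tolerance = 1e-9)
})

test_that("ANOVA and Tukey p-value ordering matches a permutation oracle", {
  set.seed(31)
  g <- list(a = rnorm(5, 0), b = rnorm(5, 1.2), c = rnorm(5, 2.6))
  y <- unlist(g); f <- rep(names(g), each = 5)
  a_obs <- one_way_anova(g)
  perm_F <- replicate(1500, {
    fp <- sample(f)
    one_way_anova(split(y, fp))$F
  })
  p_perm <- mean(perm_F >= a_obs$F)
  expect_lt(abs(p_perm - a_obs$p), 0.05)
  # pairwise: permutation p ordering equals Tukey's adjusted-p ordering
  tk <- tukey_hsd(g)
  pairs <- strsplit(tk$pair, "-", fixed = TRUE)
  p_pair <- vapply(pairs, function(pr) {
    yy <- c(g[[pr[1]]], g[[pr[2]]]); ff <- rep(pr, each = 5)
    d_obs <- abs(diff(tapply(yy, ff, mean)))
    mean(replicate(1500, {
      fs <- sample(ff)
      abs(diff(tapply(yy, fs, mean)))
    }) >= d_obs - 1e-12)
  }, numeric(1))
  expect_equal(order(p_pair), order(tk$p_adj))
})

test_that("repeatability recovers canonical variance-component structure", {
  # zero within-group variance
  y <- rep(c(1, 2, 3), each = 3)
  r <- repeatability(y, rep(1:3, each = 3), n_boot = 50, n_perm = 50, seed = 1)
  expect_equal(r$R, 1)
  # pure noise: R near 0 and inside its own bootstrap CI of 0
  set.seed(5)
  y0 <- rnorm(150)
  r0 <- repeatability(y0, rep(1:3, each = 50), n_boot = 300, seed = 2)
  expect_lt(r0$R, 0.15)
  expect_lte(r0$ci_low, max(r0$R, 0.01))
  expect_gt(r0$p_value, 0.05)
  expect_error(repeatability(1:4, rep(1, 4)),
               class = "braceroot_sample_size_error")
})

test_that("variance components agree with lme4 REML on balanced data", {
  skip_if_not_installed("lme4")
  set.seed(42)
  k <- 20; n <- 4
  b <- rnorm(k, 0, 3)
  y <- 10 + rep(b, each = n) + rnorm(k * n, 0, 1.5)
  g <- rep(seq_len(k), each = n)
  est <- braceroot:::vc_components(y, g)
  fit <- lme4::lmer(y ~ 1 + (1 | g), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2g_ref <- vc$vcov[vc$grp == "g"]
  s2e_ref <- vc$vcov[vc$grp == "Residual"]
  expect_equal(est$s2_group, s2g_ref, tolerance = 1e-4)
  expect_equal(est$s2_resid, s2e_ref, tolerance = 1e-4)
  expect_equal(est$R, s2g_ref / (s2g_ref + s2e_ref), tolerance = 1e-4)
})

test_that("repeatability is invariant to affine transforms of the data", {
  set.seed(6)
  y <- rnorm(60, 40, 8) + rep(rnorm(20, 0, 5), each = 3)
  g <- rep(1:20, each = 3)
  r1 <- repeatability(y, g, n_boot = 50, n_perm = 50, seed = 3)
  r2 <- repeatability(3.7 * y - 120, g, n_boot = 50, n_perm = 50, seed = 3)
  expect_equal(r1$R, r2$R, tolerance = 1e-12)
})

test_that("ladder of powers recovers identity and log transforms", {
  set.seed(14)
  # strongly right-skewed: log should be recovered near lambda = 0
  x_ln <- exp(rnorm(200, 1, 0.6))
  tr_ln <- tukey_ladder(x_ln)
  expect_lt(abs(tr_ln$lambda), 0.35)
  # already-normal data with real relative spread: lambda near 1
  x_n <- rnorm(200, 10, 3); x_n <- x_n[x_n > 0.5]
  tr_n <- tukey_ladder(x_n)
  expect_lt(abs(tr_n$lambda - 1), 0.5)
  # the grid includes 1, so W never falls below the raw-data W
  expect_gte(tr_n$W + 1e-12, stats::shapiro.test(x_n)$statistic)
  expect_gte(tr_ln$W + 1e-12, stats::shapiro.test(x_ln)$statistic)
  # transform at lambda = 1 is the identity
  expect_equal(braceroot:::ladder_transform(x_n, 1), x_n)
  expect_error(tukey_ladder(c(-1, 1, 2, 3)), class = "braceroot_domain_error")
})

test_that("normality gate transforms only on the configured side", {
  set.seed(15)
  x_skew <- exp(rnorm(100, 0, 0.8))
  x_norm <- rnorm(100, 20, 2)
  expect_true(normalize_if_nonnormal(x_skew)$applied)
  expect_false(normalize_if_nonnormal(x_norm)$applied)
  # literal workflow reading: transforms the already-normal sample instead
  expect_true(normalize_if_nonnormal(x_norm, gate = "p_ge")$applied)
  expect_false(normalize_if_nonnormal(x_skew, gate = "p_ge")$applied)
})

test_that("two-predictor regression is exact on noiseless data and flags collinearity", {
  set.seed(16)
  x1 <- rnorm(20); x2 <- rnorm(20)
  y <- 3 + 2 * x1 - x2
  fit <- suppressWarnings(two_predictor_regression(y, x1, x2))
  expect_equal(unname(fit$coefficients), c(3, 2, -1), tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_error(two_predictor_regression(y, x1, x1),
               class = "braceroot_singular_design")
  expect_error(two_predictor_regression(y[1:3], x1[1:3], x2[1:3]),
               class = "braceroot_sample_size_error")
})

test_that("opposing effect signs are recovered on correlated line means", {
  hits <- 0L
  for (i in 1:200) {
    lm_df <- simulate_line_means(seed = 1000 + i)
    fit <- two_predictor_regression(lm_df$slope, lm_df$dts, lm_df$ph)
    if (fit$coefficients[["b1"]] > 0 && fit$coefficients[["b2"]] < 0) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / 200, 0.95)
})

test_that("two-way additive ANOVA reports both main effects", {
  set.seed(17)
  f1 <- rep(c("am", "noon", "pm"), each = 20)
  f2 <- rep(rep(c("A", "B"), each = 10), 3)
  y <- rnorm(60) + c(am = 0, noon = -1, pm = -2)[f1]
  res <- two_way_anova(y, f1, f2)
  expect_lt(res$p[["f1"]], 0.001)
  expect_gt(res$p[["f2"]], 0.05)
})
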
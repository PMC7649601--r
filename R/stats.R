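# Statistical layer: wrappers with validated contracts around the standard
# base-R machinery (cor.test, aov, TukeyHSD, shapiro.test, lm), plus the
# variance-components repeatability estimator and the ladder-of-powers
# normalization used in field-biomechanics workflows.

as_group_list <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  if (!is.list(groups) || length(groups) < 2L) {
    abort_br("need a named list (or value/group data frame) with >= 2 groups",
             "braceroot_sample_size_error")
  }
  if (any(lengths(groups) < 2L)) {
    abort_br("every group needs >= 2 values", "braceroot_sample_size_error")
  }
  groups
}

stack_groups <- function(groups) {
  nm <- names(groups) %||% as.character(seq_along(groups))
  data.frame(value = unlist(groups, use.names = FALSE),
             group = factor(rep(nm, lengths(groups))))
}

#' Pearson correlation with t-test p-value
#'
#' @param x,y numeric vectors of equal length (>= 3) with non-zero
#'   variance.
#' @return List with `r`, `p`, `n`, and the 95% confidence interval
#'   `conf_int`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort_br("x and y must have equal length >= 3", "braceroot_sample_size_error")
  }
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) {
    abort_br("fewer than 3 complete pairs", "braceroot_sample_size_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_br("zero variance in x or y", "braceroot_degenerate_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       conf_int = if (!is.null(ct$conf.int)) as.numeric(ct$conf.int) else c(NA, NA))
}

#' One-way analysis of variance
#'
#' Between/within mean-square F test across groups. Two degenerate shapes
#' are signalled rather than computed: all values identical (F undefined,
#' `degenerate = TRUE`) and zero within-group variance with distinct means
#' (`F = Inf`, `p = 0`).
#'
#' @param groups named list of numeric vectors (>= 2 groups of >= 2
#'   values), or a data frame with columns `value` and `group`.
#' @return List with `F`, `p`, `df` (numerator, denominator), the `aov`
#'   summary `table` when defined, and `degenerate`.
#' @export
one_way_anova <- function(groups) {
  groups <- as_group_list(groups)
  df <- stack_groups(groups)
  k <- nlevels(df$group); N <- nrow(df)
  gm <- tapply(df$value, df$group, mean)
  ssw <- sum((df$value - gm[df$group])^2)
  ssb <- sum(tapply(df$value, df$group, length) * (gm - mean(df$value))^2)
  if (ssw <= 0 && ssb <= 0) {
    return(list(F = NA_real_, p = NA_real_, df = c(k - 1L, N - k),
                table = NULL, degenerate = TRUE))
  }
  if (ssw <= 0) {
    return(list(F = Inf, p = 0, df = c(k - 1L, N - k),
                table = NULL, degenerate = FALSE))
  }
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1L]]
  list(F = tab[["F value"]][1L], p = tab[["Pr(>F)"]][1L],
       df = c(k - 1L, N - k), table = tab, degenerate = FALSE)
}

#' Two-way additive analysis of variance
#'
#' Main-effects-only two-factor ANOVA (`value ~ f1 + f2`), as used to test
#' e.g. a time-of-day effect alongside a plot-replicate effect.
#'
#' @param values numeric response.
#' @param f1,f2 factors (coerced) of the same length as `values`.
#' @return List with per-factor `F` and `p` (named by factor) and the
#'   `aov` summary `table`.
#' @export
two_way_anova <- function(values, f1, f2) {
  stopifnot(length(values) == length(f1), length(values) == length(f2))
  df <- data.frame(value = values, f1 = factor(f1), f2 = factor(f2))
  if (nlevels(df$f1) < 2L || nlevels(df$f2) < 2L) {
    abort_br("both factors need >= 2 levels", "braceroot_sample_size_error")
  }
  fit <- stats::aov(value ~ f1 + f2, data = df)
  tab <- summary(fit)[[1L]]
  eff <- rownames(tab)
  keep <- trimws(eff) %in% c("f1", "f2")
  list(F = stats::setNames(tab[["F value"]][keep], c("f1", "f2")),
       p = stats::setNames(tab[["Pr(>F)"]][keep], c("f1", "f2")),
       table = tab)
}

#' Tukey honest significant difference post hoc test
#'
#' All pairwise group comparisons with p-values from the studentized-range
#' distribution, via [stats::TukeyHSD()].
#'
#' @inheritParams one_way_anova
#' @param conf_level family-wise confidence level.
#' @return Data frame with columns `pair`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(groups, conf_level = 0.95) {
  groups <- as_group_list(groups)
  df <- stack_groups(groups)
  if (stats::var(df$value) == 0) {
    abort_br("all values identical; pairwise comparisons undefined",
             "braceroot_degenerate_error")
  }
  fit <- stats::aov(value ~ group, data = df)
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$group
  out <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Searle's ANOVA variance-components estimator for a one-way random-effects
# layout (unbalanced allowed); the negative-component estimate truncates at 0.
vc_components <- function(values, group) {
  g <- factor(group)
  k <- nlevels(g); N <- length(values)
  ni <- tabulate(g)
  gm <- as.vector(rowsum(values, g)) / ni
  mu <- mean(values)
  ssb <- sum(ni * (gm - mu)^2)
  ssw <- sum((values - gm[as.integer(g)])^2)
  msb <- ssb / (k - 1L)
  msw <- ssw / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1L)
  s2g <- max(0, (msb - msw) / n0)
  R <- if (s2g + msw <= 0) NA_real_ else s2g / (s2g + msw)
  list(mu = mu, s2_group = s2g, s2_resid = msw, R = R, ni = ni, k = k)
}

#' Repeatability (intraclass correlation) with parametric bootstrap
#'
#' Repeatability is the fraction of total variance attributable to
#' between-group (e.g. between-plant) variance,
#' `R = s2_group / (s2_group + s2_resid)`, estimated from one-way ANOVA
#' variance components (negative component truncated at 0). The standard
#' error and confidence interval come from a parametric bootstrap
#' (resampling from the fitted Gaussian components and re-estimating R);
#' the p-value against R = 0 from a permutation test of group labels.
#'
#' @param values numeric measurements.
#' @param group grouping identifier per value (>= 2 groups of >= 2
#'   values).
#' @param n_boot parametric bootstrap replicates (default 1000).
#' @param n_perm label permutations for the p-value.
#' @param conf_level central bootstrap interval level.
#' @param seed RNG seed for bootstrap and permutation.
#' @return An object of class `repeatability_result`: list with `R`, `SE`,
#'   `ci_low`, `ci_high`, `p_value`, `n_boot`, and the fitted variance
#'   components `s2_group`, `s2_resid`.
#' @export
repeatability <- function(values, group, n_boot = 1000L, n_perm = 1000L,
                          conf_level = 0.95, seed = NULL) {
  g <- factor(group)
  if (nlevels(g) < 2L || any(tabulate(g) < 2L)) {
    abort_br("need >= 2 groups with >= 2 values each", "braceroot_sample_size_error")
  }
  stopifnot(length(values) == length(g), n_boot >= 1L)
  est <- vc_components(values, g)
  alpha <- (1 - conf_level) / 2
  with_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(i) {
      b <- stats::rnorm(est$k, 0, sqrt(est$s2_group))
      y <- est$mu + rep(b, est$ni) +
        stats::rnorm(length(values), 0, sqrt(est$s2_resid))
      vc_components(y, rep(seq_len(est$k), est$ni))$R
    }, numeric(1))
    perms <- vapply(seq_len(n_perm), function(i) {
      vc_components(values, sample(as.integer(g)))$R
    }, numeric(1))
    ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE)
    structure(
      list(R = est$R, SE = stats::sd(boots, na.rm = TRUE),
           ci_low = ci[1L], ci_high = ci[2L],
           p_value = (1 + sum(perms >= est$R, na.rm = TRUE)) / (n_perm + 1),
           n_boot = as.integer(n_boot),
           s2_group = est$s2_group, s2_resid = est$s2_resid),
      class = "repeatability_result"
    )
  })
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("Repeatability R = %.3f, SE = %.4f, CI [%.3f, %.3f], p = %.3g (n_boot = %d)\n",
              x$R, x$SE, x$ci_low, x$ci_high, x$p_value, x$n_boot))
  invisible(x)
}

ladder_transform <- function(x, lambda) {
  if (lambda > 0) x^lambda else if (lambda == 0) log(x) else -(x^lambda)
}

#' Tukey's ladder of powers
#'
#' Searches a grid of power-transform exponents and returns the one whose
#' transformed sample maximizes the Shapiro-Wilk W statistic. The
#' transform is order-preserving: `x^lambda` for `lambda > 0`, `log(x)`
#' for `lambda = 0`, `-(x^lambda)` for `lambda < 0`.
#'
#' @param x positive numeric vector, length 3..5000.
#' @param lambda_grid exponents to search (default -2 to 2 in steps of
#'   0.025; includes 1, so the chosen W never falls below that of the raw
#'   data).
#' @return An object of class `transform_result`: list with `lambda`,
#'   `transformed`, `W`, and the full `grid` data frame (lambda, W).
#' @export
tukey_ladder <- function(x, lambda_grid = seq(-2, 2, by = 0.025)) {
  if (length(x) < 3L || length(x) > 5000L) {
    abort_br("Shapiro-Wilk requires 3..5000 values", "braceroot_sample_size_error")
  }
  if (any(!is.finite(x))) abort_br("x must be finite", "braceroot_domain_error")
  if (any(x <= 0)) {
    abort_br("x must be positive for power transforms; shift the values first",
             "braceroot_domain_error")
  }
  W <- vapply(lambda_grid, function(l) {
    t <- ladder_transform(x, l)
    if (stats::sd(t) == 0 || any(!is.finite(t))) return(NA_real_)
    tryCatch(stats::shapiro.test(t)$statistic, error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(W))) abort_br("no usable transform on the grid", "braceroot_degenerate_error")
  best <- which.max(W)
  structure(
    list(lambda = lambda_grid[best],
         transformed = ladder_transform(x, lambda_grid[best]),
         W = W[best],
         grid = data.frame(lambda = lambda_grid, W = W)),
    class = "transform_result"
  )
}

#' Normality-gated normalization
#'
#' Tests `x` with Shapiro-Wilk and applies [tukey_ladder()] depending on
#' the gate: `"p_lt"` (default) transforms when normality is rejected
#' (p < alpha); `"p_ge"` reproduces the literal published workflow of
#' transforming when p >= alpha.
#'
#' @param x positive numeric vector.
#' @param alpha normality-test significance level.
#' @param gate `"p_lt"` or `"p_ge"`.
#' @return List with `transformed`, `lambda` (`NA` when untransformed),
#'   `applied`, and `shapiro_p_raw`.
#' @export
normalize_if_nonnormal <- function(x, alpha = 0.05, gate = c("p_lt", "p_ge")) {
  gate <- match.arg(gate)
  p_raw <- stats::shapiro.test(x)$p.value
  apply_it <- if (gate == "p_lt") p_raw < alpha else p_raw >= alpha
  if (!apply_it) {
    return(list(transformed = x, lambda = NA_real_, applied = FALSE,
                shapiro_p_raw = p_raw))
  }
  tr <- tukey_ladder(x)
  list(transformed = tr$transformed, lambda = tr$lambda, applied = TRUE,
       shapiro_p_raw = p_raw)
}

#' Two-predictor multiple regression
#'
#' OLS of `y` on two predictors with per-coefficient t-test p-values --
#' the final model shape used for regressing stiffness on flowering time
#' and plant height.
#'
#' @param y response.
#' @param x1,x2 predictors, same length as `y` (>= 4); the design must be
#'   full rank.
#' @return List with `coefficients` (b0, b1, b2), `p_values`, `r_squared`,
#'   and the fitted `lm` object as `fit`.
#' @export
two_predictor_regression <- function(y, x1, x2) {
  n <- length(y)
  if (length(x1) != n || length(x2) != n || n < 4L) {
    abort_br("y, x1, x2 must have equal length >= 4", "braceroot_sample_size_error")
  }
  X <- cbind(1, x1, x2)
  if (qr(X)$rank < 3L) {
    abort_br("design matrix is rank deficient (collinear predictors)",
             "braceroot_singular_design")
  }
  fit <- stats::lm(y ~ x1 + x2)
  sm <- summary(fit)
  cf <- stats::coef(sm)
  list(coefficients = stats::setNames(cf[, "Estimate"], c("b0", "b1", "b2")),
       p_values = stats::setNames(cf[, "Pr(>|t|)"], c("b0", "b1", "b2")),
       r_squared = sm$r.squared,
       fit = fit)
}
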
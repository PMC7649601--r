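#' Convert device rotation to radians and to horizontal deflection
#'
#' The footplate IMU reports rotation in degrees; the load point sits at
#' height `h` on the stalk, so a rotation of `theta` radians displaces it
#' horizontally by `h * sin(theta)`. Full machine-precision `pi` is used in
#' the degree conversion.
#'
#' @param deg rotation in degrees (vectorised).
#' @return Radians.
#' @export
degrees_to_radians <- function(deg) {
  if (!is.numeric(deg) || any(!is.finite(deg))) {
    abort_br("rotation must be finite numeric degrees", "braceroot_domain_error")
  }
  deg * pi / 180
}

#' @rdname degrees_to_radians
#' @param theta_rad rotation in radians (vectorised).
#' @param load_height_m height of the applied load in meters (> 0).
#' @return Horizontal deflection of the load point, meters.
#' @export
rotation_to_deflection <- function(theta_rad, load_height_m) {
  if (!is_scalar_number(load_height_m) || load_height_m <= 0) {
    abort_br("load_height_m must be a positive number", "braceroot_domain_error")
  }
  if (!is.numeric(theta_rad) || any(!is.finite(theta_rad))) {
    abort_br("theta_rad must be finite numeric", "braceroot_domain_error")
  }
  load_height_m * sin(theta_rad)
}

#' Force-deflection view of a trace
#'
#' @param trace an [force_rotation_trace()] object.
#' @return Data frame with columns `index`, `deflection_m`, `force_N`,
#'   paired 1:1 with the trace samples.
#' @export
trace_deflection <- function(trace) {
  stopifnot(inherits(trace, "frt_trace"))
  s <- trace$samples
  data.frame(
    index = s$index,
    deflection_m = rotation_to_deflection(degrees_to_radians(s$rotation_deg),
                                          trace$load_height_m),
    force_N = s$force_N
  )
}

#' Segment a deflection sequence into loading cycles
#'
#' A loading cycle is a maximal run of strictly increasing deflection of at
#' least `min_run` samples whose deflection span (max minus min within the
#' run) is at least `min_span_m`. Shorter or flatter runs -- typically
#' wind-shaken segments -- are discarded. Defaults are 10 consecutive
#' increasing samples and a 0.02 m span.
#'
#' @param deflections data frame as returned by [trace_deflection()] (only
#'   `deflection_m` is used), or a numeric vector of deflections.
#' @param min_run minimum number of consecutively increasing samples
#'   (>= 2).
#' @param min_span_m minimum deflection span of an accepted cycle, meters.
#' @return Data frame with one row per accepted cycle: `start`, `end`
#'   (1-based sample positions, inclusive) and `span_m`, in index order.
#'   Cycles are disjoint by construction.
#' @export
parse_loading_cycles <- function(deflections, min_run = 10L, min_span_m = 0.02) {
  if (!is_scalar_number(min_run) || min_run < 2) {
    abort_br("min_run must be >= 2", "braceroot_parameter_error")
  }
  d <- if (is.data.frame(deflections)) deflections$deflection_m else deflections
  empty <- data.frame(start = integer(), end = integer(), span_m = numeric())
  n <- length(d)
  if (n == 0L) return(empty)
  if (n == 1L) return(empty)
  inc <- diff(d) > 0
  r <- rle(inc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= (min_run - 1L))
  if (length(keep) == 0L) return(empty)
  out <- data.frame(
    start = starts[keep],           # position of first sample in the run
    end = ends[keep] + 1L,          # run over diffs: +1 recovers sample count
    span_m = d[ends[keep] + 1L] - d[starts[keep]]
  )
  out <- out[out$span_m >= min_span_m, , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_slope_estimate <- function(slope, method, n_points, r_squared,
                               cycles_used = NA_integer_, fallback = FALSE) {
  structure(
    list(slope_N_per_m = slope, method = method, n_points = as.integer(n_points),
         r_squared = r_squared, cycles_used = as.integer(cycles_used),
         fallback = isTRUE(fallback)),
    class = "slope_estimate"
  )
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf("<slope estimate> %.4g N/m (method %s%s, n = %d, r^2 = %.4f)\n",
              x$slope_N_per_m, x$method, if (x$fallback) ", fallback" else "",
              x$n_points, x$r_squared))
  invisible(x)
}

as_fd_pairs <- function(trace) {
  if (inherits(trace, "frt_trace")) trace_deflection(trace) else {
    stopifnot(is.data.frame(trace),
              all(c("deflection_m", "force_N") %in% names(trace)))
    trace
  }
}

#' Force-deflection slope from the complete trace
#'
#' Ordinary least squares of force on deflection over every sample --
#' loading and unloading legs of all cycles. An intercept is included; the
#' slope is the quantity of interest.
#'
#' @param trace an [force_rotation_trace()] or a force-deflection data frame
#'   (columns `deflection_m`, `force_N`).
#' @return A `slope_estimate` (`method = "full"`).
#' @export
fit_slope_full <- function(trace) {
  fd <- as_fd_pairs(trace)
  fit <- ols_line(fd$deflection_m, fd$force_N)
  new_slope_estimate(fit$slope, "full", nrow(fd), fit$r_squared)
}

#' Force-deflection slope from loading cycles only
#'
#' OLS of force on deflection pooled over the samples inside the accepted
#' loading cycles; unloading legs are excluded.
#'
#' @inheritParams fit_slope_full
#' @param cycles accepted cycles from [parse_loading_cycles()]; parsed from
#'   the trace with default thresholds when omitted.
#' @return A `slope_estimate` (`method = "loading"`).
#' @export
fit_slope_loading <- function(trace, cycles = NULL) {
  fd <- as_fd_pairs(trace)
  if (is.null(cycles)) cycles <- parse_loading_cycles(fd)
  if (nrow(cycles) == 0L) {
    abort_br("no accepted loading cycles; consider the full-trace fit",
             "braceroot_no_cycle")
  }
  rows <- unlist(lapply(seq_len(nrow(cycles)), function(i) {
    seq.int(cycles$start[i], cycles$end[i])
  }))
  fit <- ols_line(fd$deflection_m[rows], fd$force_N[rows])
  new_slope_estimate(fit$slope, "loading", length(rows), fit$r_squared,
                     cycles_used = nrow(cycles))
}

#' Force-deflection slope by per-cycle RANSAC
#'
#' Fits a random-sample-consensus line to each accepted loading cycle and
#' keeps the slope from the cycle whose consensus set has the longest run
#' of consecutive inlier samples (ties go to the earliest cycle), so a
#' cycle disturbed mid-way loses to a clean one. The inlier threshold
#' defaults to 1.5 times the median absolute residual of a preliminary
#' full-trace fit (with a small floor so noise-free data are not rejected).
#' Deterministic for a given `seed`.
#'
#' @inheritParams fit_slope_loading
#' @param n_iter random 2-point hypotheses per cycle.
#' @param min_samples points drawn per hypothesis.
#' @param residual_threshold_N inlier threshold in newtons; `NULL` for the
#'   adaptive default.
#' @param seed RNG seed (required for reproducibility; `NULL` uses the
#'   current stream).
#' @return A `slope_estimate` (`method = "ransac"`).
#' @export
fit_slope_ransac <- function(trace, cycles = NULL, n_iter = 200L,
                             min_samples = 2L, residual_threshold_N = NULL,
                             seed = NULL) {
  fd <- as_fd_pairs(trace)
  if (is.null(cycles)) cycles <- parse_loading_cycles(fd)
  if (nrow(cycles) == 0L) {
    abort_br("no accepted loading cycles; consider the full-trace fit",
             "braceroot_no_cycle")
  }
  if (is.null(residual_threshold_N)) {
    pre <- ols_line(fd$deflection_m, fd$force_N)
    residual_threshold_N <- max(1.5 * stats::median(abs(pre$residuals)), 1e-8)
  }
  with_seed(seed, {
    per_cycle <- lapply(seq_len(nrow(cycles)), function(i) {
      rows <- seq.int(cycles$start[i], cycles$end[i])
      ransac_line(fd$deflection_m[rows], fd$force_N[rows], n_iter,
                  min_samples, residual_threshold_N)
    })
    ok <- !vapply(per_cycle, is.null, logical(1))
    if (!any(ok)) {
      abort_br("RANSAC found no consensus in any cycle", "braceroot_degenerate_fit")
    }
    runs <- vapply(per_cycle, function(p) if (is.null(p)) -1L else p$longest_run,
                   integer(1))
    best <- which.max(runs) # ties resolved to the earliest cycle
    p <- per_cycle[[best]]
    new_slope_estimate(p$slope, "ransac", p$n_inliers, p$r_squared,
                       cycles_used = best)
  })
}

# classic RANSAC for a line on one cycle; returns NULL when degenerate
ransac_line <- function(x, y, n_iter, min_samples, threshold) {
  n <- length(x)
  if (n < max(2L, min_samples)) return(NULL)
  best_inliers <- NULL
  best_count <- -1L
  for (i in seq_len(n_iter)) {
    idx <- sample.int(n, min_samples)
    xs <- x[idx]; ys <- y[idx]
    if (diff(range(xs)) <= 0) next
    if (min_samples == 2L) {
      b <- (ys[2L] - ys[1L]) / (xs[2L] - xs[1L])
      a <- ys[1L] - b * xs[1L]
    } else {
      cf <- stats::lm.fit(cbind(1, xs), ys)$coefficients
      a <- cf[1L]; b <- cf[2L]
    }
    inl <- abs(y - (a + b * x)) <= threshold
    cnt <- sum(inl)
    if (cnt > best_count) {
      best_count <- cnt
      best_inliers <- inl
    }
  }
  if (is.null(best_inliers) || best_count < 2L ||
      stats::sd(x[best_inliers]) == 0) {
    return(NULL)
  }
  fit <- ols_line(x[best_inliers], y[best_inliers])
  list(slope = fit$slope, r_squared = fit$r_squared,
       n_inliers = best_count, longest_run = longest_true_run(best_inliers))
}

#' Extract a force-deflection slope from a trace by a chosen method
#'
#' Runs the conversion chain (degrees to radians to deflection), segments
#' loading cycles, and fits by the requested method. When the cycle parser
#' finds no usable cycle (e.g. a wind-corrupted trace) and
#' `fallback_to_full` is `TRUE`, the complete-trace fit is returned with
#' its `fallback` flag set -- the unbiased default when loading data cannot
#' be identified automatically.
#'
#' @param trace an [force_rotation_trace()] object.
#' @param method `"full"`, `"loading"`, or `"ransac"`.
#' @param min_run,min_span_m cycle-parser thresholds
#'   ([parse_loading_cycles()]).
#' @param ransac list of RANSAC options passed to [fit_slope_ransac()]
#'   (`n_iter`, `min_samples`, `residual_threshold_N`, `seed`).
#' @param fallback_to_full fall back to the full-trace fit when no cycle is
#'   found?
#' @return A `slope_estimate`.
#' @export
extract_slope <- function(trace, method = c("full", "loading", "ransac"),
                          min_run = 10L, min_span_m = 0.02,
                          ransac = list(), fallback_to_full = TRUE) {
  method <- match.arg(method)
  fd <- as_fd_pairs(trace)
  if (method == "full") return(fit_slope_full(fd))
  cycles <- parse_loading_cycles(fd, min_run = min_run, min_span_m = min_span_m)
  fit <- tryCatch(
    switch(method,
           loading = fit_slope_loading(fd, cycles),
           ransac = do.call(fit_slope_ransac,
                            c(list(trace = fd, cycles = cycles), ransac))),
    braceroot_no_cycle = function(e) e
  )
  if (inherits(fit, "condition")) {
    if (!fallback_to_full) stop(fit)
    fit <- fit_slope_full(fd)
    fit$fallback <- TRUE
  }
  fit
}

#' Pairwise agreement of the three slope-extraction methods
#'
#' Extracts the slope of every trace by all three methods and returns the
#' pairwise Pearson correlation matrix of the resulting slope vectors --
#' the standard check that method choice does not drive downstream results.
#'
#' @param traces list of [force_rotation_trace()] objects (>= 3 for which
#'   all methods succeed).
#' @param min_run,min_span_m,ransac as in [extract_slope()].
#' @return A symmetric 3x3 correlation matrix with unit diagonal and
#'   dimnames `full`, `loading`, `ransac`, with the slope table attached as
#'   attribute `"slopes"`.
#' @export
compare_methods <- function(traces, min_run = 10L, min_span_m = 0.02,
                            ransac = list(seed = 1L)) {
  slopes <- vapply(traces, function(tr) {
    fd <- as_fd_pairs(tr)
    cycles <- parse_loading_cycles(fd, min_run, min_span_m)
    res <- tryCatch({
      c(full = fit_slope_full(fd)$slope_N_per_m,
        loading = fit_slope_loading(fd, cycles)$slope_N_per_m,
        ransac = do.call(fit_slope_ransac,
                         c(list(trace = fd, cycles = cycles), ransac))$slope_N_per_m)
    }, braceroot_error = function(e) c(full = NA_real_, loading = NA_real_,
                                       ransac = NA_real_))
    res
  }, numeric(3))
  ok <- colSums(is.na(slopes)) == 0
  if (sum(ok) < 3L) {
    abort_br("need at least 3 traces for which all three methods succeed",
             "braceroot_sample_size_error")
  }
  m <- stats::cor(t(slopes[, ok, drop = FALSE]))
  structure(m, slopes = t(slopes))
}
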
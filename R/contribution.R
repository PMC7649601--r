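# Contribution statistics operate on a named slope vector: names are the
# test labels A..last (A = all brace roots intact, last = all soil-entering
# whorls excised), values are force-deflection slopes in N/m.

check_series_slopes <- function(slopes, require_positive = TRUE) {
  if (inherits(slopes, "removal_series")) {
    slopes <- vapply(slopes$traces, function(t) {
      if (inherits(t, "slope_estimate")) t$slope_N_per_m
      else abort_br("series traces must hold slope estimates; run extraction first",
                    "braceroot_format_error")
    }, numeric(1))
  }
  if (!is.numeric(slopes) || is.null(names(slopes)) || length(slopes) < 1L) {
    abort_br("slopes must be a named numeric vector keyed by test label",
             "braceroot_format_error")
  }
  labs <- names(slopes)
  expected <- LETTERS[seq_along(slopes)]
  if (!setequal(labs, expected)) {
    abort_br(sprintf("test labels {%s} must be contiguous from A",
                     paste(sort(labs), collapse = ",")),
             "braceroot_contiguity_error")
  }
  slopes <- slopes[order(labs)]
  if (require_positive && any(slopes <= 0)) {
    abort_br("all slopes must be positive", "braceroot_domain_error")
  }
  slopes
}

#' Brace-root contribution ratio
#'
#' The ratio of the force-deflection slope with all soil-entering whorls
#' excised to the slope with all brace roots intact: `slope(last) /
#' slope(A)` (D/A for a three-whorl plant, C/A for a two-whorl plant). A
#' lower value indicates a higher brace-root contribution to anchorage. A
#' single-test series (no whorls in the soil) returns 1 by convention.
#'
#' @param slopes named numeric vector of slopes keyed by test label
#'   (`A`..last, contiguous), or a `removal_series` whose traces have been
#'   replaced by slope estimates.
#' @return Dimensionless ratio in (0, Inf).
#' @examples
#' contribution_ratio(c(A = 10, B = 9, C = 5, D = 4)) # 0.4
#' @export
contribution_ratio <- function(slopes) {
  s <- check_series_slopes(slopes)
  unname(s[length(s)] / s[1L])
}

#' Brace-root contribution difference
#'
#' The absolute counterpart of [contribution_ratio()]: `slope(A) -
#' slope(last)` in N/m. Can legitimately be negative when technical
#' variation makes a post-excision measurement exceed the intact one.
#'
#' @inheritParams contribution_ratio
#' @return Difference in N/m.
#' @export
contribution_difference <- function(slopes) {
  s <- check_series_slopes(slopes, require_positive = FALSE)
  unname(s[1L] - s[length(s)])
}

#' Per-whorl contribution ratios
#'
#' Adjacent-test ratios attributing the slope change to individual whorls,
#' numbered from the soil upward: for a three-whorl plant `Whorl1 = D/C`,
#' `Whorl2 = C/B`, `Whorl3 = B/A`. Their product telescopes to the overall
#' [contribution_ratio()].
#'
#' @inheritParams contribution_ratio
#' @return Named numeric vector `Whorl1`..`WhorlK` (empty for a
#'   single-test series).
#' @export
whorl_ratios <- function(slopes) {
  s <- check_series_slopes(slopes)
  n <- length(s)
  if (n < 2L) return(stats::setNames(numeric(0), character(0)))
  i <- seq_len(n - 1L)
  stats::setNames(unname(s[n - i + 1L] / s[n - i]), paste0("Whorl", i))
}

#' Beam-length-corrected contribution ratio
#'
#' Brace roots anchor the stalk at their attachment height `a`, so excising
#' them moves the effective cantilever base from `a` down to the soil
#' surface, lengthening the beam from `h - a` to `h` (load applied at
#' height `h`). For a tip-loaded cantilever the force-deflection slope
#' scales as `1/L^3`, so if removal changed nothing but the beam length the
#' raw ratio would equal `((h - a)/h)^3`. The corrected ratio divides this
#' pure-geometry factor out: `corrected = ratio / ((h - a)/h)^3`, which
#' maps the geometry-only null to exactly 1. Values below 1 after
#' correction indicate anchorage lost beyond what beam lengthening alone
#' explains. The alternative reading (multiplying by the factor) is
#' selectable via `direction`.
#'
#' @param ratio raw contribution ratio (> 0).
#' @param load_height_m load height `h` in meters.
#' @param attachment_height_m attachment height `a` of the highest
#'   soil-entering whorl, meters (`0 <= a < h`); `NA` returns `NA` (the
#'   correction is not computable for plants without this measurement).
#' @param direction `"divide"` (default, null maps to 1) or `"multiply"`.
#' @return Corrected dimensionless ratio, or `NA_real_` when
#'   `attachment_height_m` is missing.
#' @examples
#' beam_corrected_ratio(0.857375, load_height_m = 0.64,
#'                      attachment_height_m = 0.032) # exactly 1
#' @export
beam_corrected_ratio <- function(ratio, load_height_m, attachment_height_m,
                                 direction = c("divide", "multiply")) {
  direction <- match.arg(direction)
  if (!is_scalar_number(ratio) || ratio <= 0) {
    abort_br("ratio must be a positive number", "braceroot_domain_error")
  }
  if (!is_scalar_number(load_height_m) || load_height_m <= 0) {
    abort_br("load_height_m must be a positive number", "braceroot_domain_error")
  }
  if (length(attachment_height_m) != 1L || is.na(attachment_height_m)) {
    return(NA_real_)
  }
  if (!is_scalar_number(attachment_height_m) || attachment_height_m < 0 ||
      attachment_height_m >= load_height_m) {
    abort_br("need 0 <= attachment_height_m < load_height_m", "braceroot_geometry_error")
  }
  g <- ((load_height_m - attachment_height_m) / load_height_m)^3
  if (direction == "divide") ratio / g else ratio * g
}

#' Full contribution summary for one removal series
#'
#' Bundles [contribution_ratio()], [contribution_difference()],
#' [whorl_ratios()] and, when the attachment height is available,
#' [beam_corrected_ratio()].
#'
#' @inheritParams contribution_ratio
#' @inheritParams beam_corrected_ratio
#' @return An object of class `contribution_result`: a list with elements
#'   `ratio`, `difference`, `whorl_ratios`, `corrected_ratio`.
#' @export
contribution_result <- function(slopes, load_height_m = NA_real_,
                                attachment_height_m = NA_real_,
                                direction = c("divide", "multiply")) {
  direction <- match.arg(direction)
  s <- check_series_slopes(slopes)
  ratio <- contribution_ratio(s)
  corrected <- if (!is.na(load_height_m)) {
    beam_corrected_ratio(ratio, load_height_m, attachment_height_m, direction)
  } else NA_real_
  structure(
    list(ratio = ratio,
         difference = contribution_difference(s),
         whorl_ratios = whorl_ratios(s),
         corrected_ratio = corrected),
    class = "contribution_result"
  )
}

#' @export
print.contribution_result <- function(x, ...) {
  cat(sprintf("<brace-root contribution> ratio %.4g, difference %.4g N/m\n",
              x$ratio, x$difference))
  if (length(x$whorl_ratios) > 0L) {
    cat("  per-whorl:",
        paste(sprintf("%s=%.4g", names(x$whorl_ratios), x$whorl_ratios),
              collapse = ", "), "\n")
  }
  if (!is.na(x$corrected_ratio)) {
    cat(sprintf("  beam-length corrected ratio %.4g\n", x$corrected_ratio))
  }
  invisible(x)
}
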
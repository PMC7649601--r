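# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards, so seeded simulation
#' helpers do not disturb the global random stream. A `NULL` seed evaluates
#' the expression under the current stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # materialise a stream to save
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# stop() with a condition class so callers can distinguish failure modes
abort_br <- function(msg, class) {
  stop(structure(
    class = c(class, "braceroot_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# single uppercase letter test labels, e.g. "A".."Z"
is_test_label <- function(x) {
  is.character(x) && length(x) == 1L && grepl("^[A-Z]$", x)
}

# longest run of TRUE in a logical vector (0 when none)
longest_true_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

# intercept + slope OLS with r-squared; x must have spread
ols_line <- function(x, y) {
  if (length(x) < 2L || stats::sd(x) == 0) {
    abort_br("cannot fit a line: fewer than 2 points or zero spread in deflection",
             "braceroot_degenerate_fit")
  }
  fit <- stats::lm.fit(cbind(intercept = 1, x = x), y)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  list(
    intercept = unname(fit$coefficients[1L]),
    slope     = unname(fit$coefficients[2L]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    residuals = fit$residuals
  )
}
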
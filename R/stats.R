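#' Simple ordinary least squares with R² and adjusted R²
#'
#' Closed-form one-predictor least squares: slope `cov(x, y)/var(x)`,
#' intercept through the means, `R²` equal to the squared Pearson
#' correlation, and adjusted `R² = 1 - (1 - R²)(n - 1)/(n - 2)` (one
#' predictor). When the response has zero variance the fit is the flat line
#' and `R²` is reported as 0.
#'
#' @param x Predictor vector (finite, `var(x) > 0`).
#' @param y Response vector of the same length.
#' @return An object of class `ols_fit` with elements `slope`, `intercept`,
#'   `r2`, `adjusted_r2` and `n`. [tidy()] gives a coefficient table,
#'   [glance()] a one-row summary.
#' @examples
#' fit <- ols_fit(1:5, 2 * (1:5) + 1)
#' glance(fit)
#' @export
ols_fit <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) abort("x and y must have the same length")
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("x and y must be finite")
  n <- length(x)
  if (n < 3) abort("at least 3 points are required")
  vx <- var(x)
  if (vx == 0) abort("zero variance in the predictor: slope undefined")
  slope <- stats::cov(x, y) / vx
  intercept <- mean(y) - slope * mean(x)
  vy <- var(y)
  r2 <- if (vy == 0) 0 else stats::cor(x, y)^2
  structure(
    list(
      slope = slope,
      intercept = intercept,
      r2 = r2,
      adjusted_r2 = 1 - (1 - r2) * (n - 1) / (n - 2),
      n = n
    ),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf(
    "OLS fit: slope %.4f, intercept %.4f, R^2 %.4f (adjusted %.4f), N = %d\n",
    x$slope, x$intercept, x$r2, x$adjusted_r2, x$n
  ))
  invisible(x)
}

#' @rdname ols_fit
#' @param x An `ols_fit` object.
#' @param ... Unused.
#' @export
tidy.ols_fit <- function(x, ...) {
  tibble(
    term = c("(Intercept)", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname ols_fit
#' @export
glance.ols_fit <- function(x, ...) {
  tibble(
    slope = x$slope, intercept = x$intercept,
    r2 = x$r2, adjusted_r2 = x$adjusted_r2, n = x$n
  )
}

#' Sample skewness (adjusted Fisher-Pearson)
#'
#' The third standardized sample moment `g1 = m3 / m2^{3/2}` with the
#' small-sample adjustment `G1 = g1 * sqrt(n(n - 1))/(n - 2)` — the
#' spreadsheet `SKEW` convention — by default; the unadjusted `g1` is
#' available with `adjusted = FALSE` for sensitivity checks. Positive values
#' indicate a long right tail.
#'
#' @param x Numeric vector, `n >= 3`, non-constant, finite.
#' @param adjusted Apply the Fisher-Pearson small-sample factor? Default TRUE.
#' @return An object of class `skewness_result` with elements `skewness`,
#'   `n`, `mean`, `sd` and `adjusted`.
#' @examples
#' skewness(c(1, 2, 3, 10))
#' @export
skewness <- function(x, adjusted = TRUE) {
  stopifnot(is.numeric(x))
  if (!all(is.finite(x))) abort("x must be finite")
  n <- length(x)
  if (n < 3) abort("at least 3 values are required")
  s <- sd(x)
  if (s == 0) abort("zero variance: skewness undefined")
  d <- x - mean(x)
  m2 <- mean(d^2)
  m3 <- mean(d^3)
  g1 <- m3 / m2^1.5
  structure(
    list(
      skewness = if (adjusted) g1 * sqrt(n * (n - 1)) / (n - 2) else g1,
      n = n,
      mean = mean(x),
      sd = s,
      adjusted = adjusted
    ),
    class = "skewness_result"
  )
}

#' @export
print.skewness_result <- function(x, ...) {
  cat(sprintf(
    "Sample skewness (%s): %.4f (N = %d, mean %.4f, sd %.4f)\n",
    if (x$adjusted) "adjusted Fisher-Pearson" else "g1",
    x$skewness, x$n, x$mean, x$sd
  ))
  invisible(x)
}

#' @rdname skewness
#' @param ... Unused.
#' @export
glance.skewness_result <- function(x, ...) {
  tibble(skewness = x$skewness, n = x$n, mean = x$mean, sd = x$sd, adjusted = x$adjusted)
}
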
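#' Normalized Higuchi curve lengths
#'
#' For each lag `k = 1..max_k` the curve length is the sum of absolute
#' differences between series values `k` apart, normalized by `1/k^2` and by
#' the end-effect factor `(N - 1)/(N - k)`:
#' \deqn{L(k) = \frac{N-1}{k^2 (N-k)} \sum_{i=k+1}^{N} |x_i - x_{i-k}|.}
#' The first `k` circular-shift differences are discarded (end effects), so
#' exactly `N - k` terms enter the sum at lag `k`.
#'
#' @param x Numeric series (or a nucleotide string, encoded on the fly with
#'   `map`).
#' @param max_k Largest lag, an integer in `[2, length(x) - 1]`. Default 7.
#' @param map Encoding map used when `x` is a character string.
#' @return A tibble with columns `k` and `L` (`max_k` rows) and attributes
#'   `n` (series length) and `max_k`.
#' @examples
#' curve_lengths(0:5, max_k = 3) # unit ramp: L(k) = (N - 1)/k
#' @seealso [higuchi_fd()]
#' @export
curve_lengths <- function(x, max_k = 7, map = default_encoding_map()) {
  if (is.character(x)) x <- encode_atomic(x, map)
  stopifnot(is.numeric(x))
  if (anyNA(x) || !all(is.finite(x))) abort("series contains non-finite values")
  n <- length(x)
  max_k <- as.integer(max_k)
  if (is.na(max_k) || max_k < 2) abort("max_k must be an integer >= 2")
  if (max_k >= n) abort(sprintf("max_k (%d) must be smaller than the series length (%d)", max_k, n))
  L <- vapply(seq_len(max_k), function(k) {
    s <- sum(abs(x[(k + 1):n] - x[1:(n - k)]))
    s / k / k * (n - 1) / (n - k)
  }, numeric(1))
  out <- tibble(k = seq_len(max_k), L = L)
  attr(out, "n") <- n
  attr(out, "max_k") <- max_k
  out
}

#' Higuchi fractal dimension of a numeric series
#'
#' Fits ordinary least squares of `log L(k)` on `log(1/k)` over the unit-step
#' lag grid `k = 1..max_k`; the slope is the fractal dimension. Values near 2
#' indicate a highly irregular series, values near 1 a smooth one; a strictly
#' linear ramp gives exactly 1. Natural logarithms are used (the slope is
#' invariant to the base as long as both axes share it).
#'
#' @inheritParams curve_lengths
#' @return An object of class `higuchi_fd` with elements `fd`, `intercept`,
#'   `curve_lengths` (the [curve_lengths()] tibble), `n` and `max_k`.
#'   [tidy()] returns the per-lag table, [glance()] the one-row fit summary.
#' @examples
#' higuchi_fd(cumsum(rnorm(500)))$fd # Brownian-like: about 1.5
#' higuchi_fd("ACGTTGCAACGT", max_k = 3)
#' @export
higuchi_fd <- function(x, max_k = 7, map = default_encoding_map()) {
  cl <- curve_lengths(x, max_k = max_k, map = map)
  if (any(cl$L <= 0)) {
    abort("degenerate series: fractal dimension undefined (some L(k) = 0)")
  }
  # direct normal equations: the lag grid may hold as few as 2 points
  # (max_k = 2), which the general-purpose ols_fit refuses
  lx <- log(1 / cl$k)
  ly <- log(cl$L)
  slope <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  structure(
    list(
      fd = slope,
      intercept = mean(ly) - slope * mean(lx),
      curve_lengths = cl,
      n = attr(cl, "n"),
      max_k = attr(cl, "max_k")
    ),
    class = "higuchi_fd"
  )
}

#' @export
print.higuchi_fd <- function(x, ...) {
  cat(sprintf(
    "Higuchi fractal dimension: %.4f (intercept %.4f, N = %d, max k = %d)\n",
    x$fd, x$intercept, x$n, x$max_k
  ))
  invisible(x)
}

#' @rdname higuchi_fd
#' @param x A `higuchi_fd` object.
#' @param ... Unused.
#' @export
tidy.higuchi_fd <- function(x, ...) {
  dplyr::mutate(x$curve_lengths, log_inv_k = log(1 / .data$k), log_L = log(.data$L))
}

#' @rdname higuchi_fd
#' @export
glance.higuchi_fd <- function(x, ...) {
  tibble(fd = x$fd, intercept = x$intercept, n = x$n, max_k = x$max_k)
}

# fd of one residue string; returns list(fd=, intercept=, error=) without
# aborting, so batch callers can record per-record failures
fd_safely <- function(residues, max_k, map) {
  tryCatch(
    {
      h <- higuchi_fd(residues, max_k = max_k, map = map)
      list(fd = h$fd, intercept = h$intercept, error = NA_character_)
    },
    error = function(e) list(fd = NA_real_, intercept = NA_real_, error = conditionMessage(e))
  )
}
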
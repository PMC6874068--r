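#' Local polynomial (LOESS) smoothing
#'
#' Classical LOESS evaluated at explicit query points: at each grid point
#' the `ceiling(span * n)` nearest observations by |x - x0| form the local
#' window, weighted by the tricube kernel
#' `w = (1 - (d / d_max)^3)^3`, and a weighted polynomial of the stated
#' degree is fitted and evaluated at the point. No robustness iterations
#' are applied.
#'
#' @param x,y numeric vectors of equal length (the scatter to smooth).
#' @param span fraction of the data in each local window, in (0, 1].
#' @param degree local polynomial degree, 1 or 2.
#' @param grid query points; default 100 equispaced points over the range
#'   of `x`.
#' @return A `"trend_curve"`: list with `grid_x`, `smoothed_y`, `span`,
#'   `degree` and `source` (label, default `"y"`).
#' @examples
#' set.seed(1)
#' x <- sort(runif(60, 0, 10)); y <- sin(x) + rnorm(60, 0, 0.1)
#' curve <- loess_smooth(x, y, span = 0.5, degree = 2)
#' @export
loess_smooth <- function(x, y, span = 0.75, degree = 2, grid = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("validation error: non-finite values in x or y")
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  if (!degree %in% c(1, 2)) stop("degree must be 1 or 2")
  n <- length(x)
  need <- max(10, ceiling(degree * 3 / span))
  if (n < need)
    stop("too few points for LOESS: need at least ", need, ", got ", n)
  if (is.null(grid)) grid <- seq(min(x), max(x), length.out = 100)
  if (is.unsorted(grid, strictly = TRUE))
    grid <- sort(unique(grid))
  q <- ceiling(span * n)
  smoothed <- vapply(grid, function(x0) {
    d <- abs(x - x0)
    idx <- order(d)[seq_len(q)]
    dmax <- d[idx[q]]
    w <- if (dmax <= 0) rep(1, q) else {
      u <- pmin(d[idx] / dmax, 1)
      (1 - u^3)^3
    }
    pos <- w > 0
    xi <- x[idx][pos] - x0
    X <- cbind(1, xi)
    if (degree == 2) X <- cbind(X, xi^2)
    fit <- stats::lm.wfit(X, y[idx][pos], w[pos])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    beta[1]
  }, numeric(1))
  structure(list(source = "y", grid_x = grid, smoothed_y = smoothed,
                 span = span, degree = degree),
            class = "trend_curve")
}

#' @export
print.trend_curve <- function(x, ...) {
  cat("trend_curve '", x$source, "': ", length(x$grid_x),
      " grid points, span ", x$span, ", degree ", x$degree, "\n", sep = "")
  invisible(x)
}
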
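#' LOESS trend curves of per-source RMS against expression
#'
#' For each source of a fitted decomposition, smooths the per-feature RMS
#' values against mean log2 expression with [loess_smooth()], all sources
#' evaluated on one common grid so the curves are pointwise comparable
#' (the analogue of the published RMS-vs-expression comparison figures).
#'
#' @param fit a [nano_vca()] object.
#' @param span,degree LOESS settings (defaults 0.75 and 2, the conventional
#'   LOESS defaults).
#' @param grid_points number of grid points.
#' @param trim central fraction of the mean-expression distribution spanned
#'   by the grid (default 0.98, trimming the unstable 1% tails on each
#'   side).
#' @param bias_correct divide each source's per-feature RMS by the
#'   chi-distribution mean factor `c4(df) = sqrt(2/df) *
#'   gamma((df+1)/2) / gamma(df/2)` before smoothing (default `TRUE`).
#'   A root-mean-square on `df` degrees of freedom underestimates the
#'   underlying standard deviation by this factor (0.798 at 1 df, 0.994 at
#'   40 df), so curves from terms with different df are only pointwise
#'   comparable after the correction: without it a technical source with no
#'   true effect would sit visibly below the residual curve instead of
#'   coinciding with it.
#' @return A `"trend_curves"` list of `"trend_curve"` objects, one per
#'   source, sharing `grid_x`.
#' @examples
#' sim <- simulate_log2(synthetic_config(n_features = 100, seed = 1))
#' curves <- trend_curves(nano_vca(sim$matrix, "scan1"))
#' names(curves)
#' @export
trend_curves <- function(fit, span = 0.75, degree = 2, grid_points = 100,
                         trim = 0.98, bias_correct = TRUE) {
  stopifnot(inherits(fit, "nano_vca"))
  if (!nrow(fit$rms)) stop("empty decomposition table")
  lo <- (1 - trim) / 2
  qs <- stats::quantile(fit$mean_expression, c(lo, 1 - lo), names = FALSE)
  grid <- seq(qs[1], qs[2], length.out = grid_points)
  curves <- lapply(fit$sources, function(src) {
    y <- fit$rms[, src]
    if (bias_correct) y <- y / c4_factor(fit$df[[src]])
    cv <- loess_smooth(fit$mean_expression, y,
                       span = span, degree = degree, grid = grid)
    cv$source <- src
    cv
  })
  names(curves) <- fit$sources
  structure(curves, class = "trend_curves")
}

## Mean of sqrt(chi2_df / df): the finite-df bias of an RMS as an
## estimate of its standard deviation (the control-chart c4 constant).
c4_factor <- function(df) {
  sqrt(2 / df) * exp(lgamma((df + 1) / 2) - lgamma(df / 2))
}

#' Export trend curves as TSV and figure
#'
#' @param curves a `"trend_curves"` list (or any list of `"trend_curve"`
#'   objects sharing a grid).
#' @param path output TSV path (`grid_x` plus one column per source); a
#'   companion figure is written with the same stem and `.png` extension
#'   unless `plot = FALSE`.
#' @param plot whether to also write the PNG figure.
#' @return `path`, invisibly.
#' @export
export_curves <- function(curves, path, plot = TRUE) {
  tab <- curves_table(curves)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (plot) {
    png_path <- paste0(tools::file_path_sans_ext(path), ".png")
    grDevices::png(png_path, width = 800, height = 600)
    on.exit(grDevices::dev.off())
    plot_curves(curves)
  }
  invisible(path)
}

curves_table <- function(curves) {
  if (!length(curves)) stop("export error: empty curve list")
  grid <- curves[[1]]$grid_x
  for (cv in curves) {
    if (!isTRUE(all.equal(cv$grid_x, grid)))
      stop("export error: curves do not share a common grid")
  }
  tab <- data.frame(grid_x = grid)
  for (cv in curves) tab[[cv$source]] <- cv$smoothed_y
  tab
}

plot_curves <- function(curves, main = "RMS trend curves", ...) {
  tab <- curves_table(curves)
  cols <- c("blue", "red", "darkgreen", "black", "purple", "orange")
  graphics::matplot(tab$grid_x, as.matrix(tab[-1]), type = "l", lty = 1,
                    lwd = 2, col = cols[seq_len(ncol(tab) - 1)],
                    xlab = "mean log2 expression", ylab = "RMS",
                    main = main, ...)
  graphics::legend("topright", legend = names(tab)[-1], lty = 1, lwd = 2,
                   col = cols[seq_len(ncol(tab) - 1)], bty = "n")
  invisible(tab)
}

#' @export
print.trend_curves <- function(x, ...) {
  cat("trend_curves:", length(x), "sources (",
      paste(names(x), collapse = ", "), ") on",
      length(x[[1]]$grid_x), "grid points\n")
  invisible(x)
}
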
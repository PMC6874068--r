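#' ANOVA model specifications for the platform comparison
#'
#' Builds one of the three per-feature ANOVA layouts used to partition
#' expression variability on the standard design:
#' \describe{
#'   \item{`"scan1"`}{first-scan observations of all four cartridges
#'     (48 obs): PrepStation generation `P` (2 levels, 1 df), scanner
#'     generation `S` (2 levels, 1 df), biological sample `B` (6 levels,
#'     5 df), residual 40 df.}
#'   \item{`"scan2"`}{second-scan observations (48 obs): the prep+scanner
#'     sum `PS` as a 3-level factor (\{A\} = both second generation,
#'     \{B\} = both first, \{C, D\} = mixed; 2 df), the cartridge contrast
#'     `Cart` (C vs D within the mixed level, 1 df), sample `B` (5 df),
#'     residual 39 df.}
#'   \item{`"both_scans"`}{cartridges A and B at both scans (48 obs):
#'     `PS` (A vs B, 1 df), scan time `T` (1 df), sample `B` (5 df),
#'     residual 40 df.}
#' }
#' Terms are fitted sequentially in the listed order; on the balanced
#' standard design they are mutually orthogonal, so the sums of squares are
#' order-independent.
#'
#' @param model `"scan1"`, `"scan2"` or `"both_scans"`.
#' @return An `"anova_model_spec"`: list with `model`, `filter` (function of
#'   a lane-annotation data frame returning the observation mask), `terms`
#'   (named list of functions building each term's design columns), and
#'   `df` (expected df per term).
#' @export
anova_model_spec <- function(model = c("scan1", "scan2", "both_scans")) {
  model <- match.arg(model)
  spec <- switch(model,
    scan1 = list(
      filter = function(ann) ann$scan == 1L,
      n_obs = 48L,
      terms = list(
        P = function(ann) dummy_cols(factor(ann$prep)),
        S = function(ann) dummy_cols(factor(ann$scanner)),
        B = function(ann) dummy_cols(factor(ann$sample))
      ),
      df = c(P = 1L, S = 1L, B = 5L)
    ),
    scan2 = list(
      filter = function(ann) ann$scan == 2L,
      n_obs = 48L,
      terms = list(
        PS = function(ann) dummy_cols(ps_factor(ann)),
        Cart = function(ann)
          matrix((ann$cartridge == "C") - (ann$cartridge == "D"), ncol = 1),
        B = function(ann) dummy_cols(factor(ann$sample))
      ),
      df = c(PS = 2L, Cart = 1L, B = 5L)
    ),
    both_scans = list(
      filter = function(ann) ann$cartridge %in% c("A", "B"),
      n_obs = 48L,
      terms = list(
        PS = function(ann) dummy_cols(factor(ann$cartridge)),
        T = function(ann) dummy_cols(factor(ann$scan)),
        B = function(ann) dummy_cols(factor(ann$sample))
      ),
      df = c(PS = 1L, T = 1L, B = 5L)
    )
  )
  structure(c(list(model = model), spec), class = "anova_model_spec")
}

## Prep+scanner sum as a 3-level factor on the standard layout
ps_factor <- function(ann) {
  lev <- ifelse(ann$prep == ann$scanner,
                ifelse(ann$prep == "second", "both_second", "both_first"),
                "mixed")
  factor(lev)
}

## Treatment-coded dummy columns (drop first level)
dummy_cols <- function(f) {
  f <- droplevels(f)
  if (nlevels(f) < 2)
    return(matrix(numeric(length(f)), ncol = 1)[, 0, drop = FALSE])
  stats::model.matrix(~f)[, -1, drop = FALSE]
}

#' Per-feature ANOVA variance decomposition
#'
#' The core fit of the package: for every feature, partitions the
#' variability of its log2 expression across the model's 48 lane-scan
#' observations into the model's sources plus residual, by sequential
#' least-squares projection onto nested design subspaces. For each term the
#' fit records degrees of freedom, sum of squares, mean square
#' (`MS = SS / df`) and root-mean-square (`RMS = sqrt(MS)`), the scale on
#' which sources are compared across expression levels. The residual is
#' taken from the full-model fit and is driven by within-cartridge
#' duplicates. The per-feature mean expression over the same observations
#' is recorded as the x-axis for trend smoothing.
#'
#' @param x an `ncounter_matrix` with `scale = "log2"` containing all
#'   observations the model requires.
#' @param model `"scan1"`, `"scan2"` or `"both_scans"`, or an
#'   [anova_model_spec()].
#' @param design an [build_design()] supplying the cartridge -> generation
#'   maps; used to attach `prep` and `scanner` columns to the lane
#'   annotations when the matrix does not already carry them.
#' @return An object of class `"nano_vca"` with components `model`, `spec`,
#'   `sources` (term names plus `"residual"`), `df` (named df vector), `ss`,
#'   `ms`, `rms` (features x sources matrices), `mean_expression`,
#'   `n_obs`, and `features`.
#' @seealso [summary.nano_vca()], [trend_curves()], [truth_rms()]
#' @examples
#' sim <- simulate_log2(synthetic_config(n_features = 50, seed = 1))
#' fit <- nano_vca(sim$matrix, "scan1")
#' fit
#' head(coef(fit))
#' @export
nano_vca <- function(x, model = c("scan1", "scan2", "both_scans"),
                     design = build_design()) {
  stopifnot(inherits(x, "ncounter_matrix"))
  if (x$scale != "log2")
    stop("nano_vca expects a log2 matrix; run normalize_counts() first")
  spec <- if (inherits(model, "anova_model_spec")) model
          else anova_model_spec(model)
  if (!nrow(x$values)) stop("empty matrix: no features to decompose")

  lanes <- x$lanes
  if (is.null(lanes$prep))
    lanes$prep <- unname(design$prep[lanes$cartridge])
  if (is.null(lanes$scanner))
    lanes$scanner <- unname(design$scanner[lanes$cartridge])
  if (anyNA(lanes$prep) || anyNA(lanes$scanner))
    stop("design-mismatch error: matrix contains cartridges absent from ",
         "the design's generation maps")
  keep <- spec$filter(lanes)
  ann <- lanes[keep, , drop = FALSE]
  n <- nrow(ann)
  if (n != spec$n_obs)
    stop("design-mismatch error: model '", spec$model, "' requires ",
         spec$n_obs, " observations, found ", n,
         " (check cartridges/scans present in the matrix)")
  Y <- t(x$values[, keep, drop = FALSE])   # obs x features
  mean_expr <- colMeans(Y)
  ## centre each feature: the intercept is projected out exactly, so the
  ## sequential fitted sums of squares live on the corrected scale
  Yc <- sweep(Y, 2, mean_expr)

  ## Nested orthonormal bases: intercept, then + each term in order
  X <- matrix(1, n, 1)
  qr0 <- qr(X)
  fit_ss_prev <- 0
  rank_prev <- qr0$rank
  ss <- matrix(0, ncol(Y), length(spec$terms) + 1L,
               dimnames = list(colnames(Y), c(names(spec$terms),
                                              "residual")))
  df <- integer(length(spec$terms))
  names(df) <- names(spec$terms)
  for (k in seq_along(spec$terms)) {
    X <- cbind(X, spec$terms[[k]](ann))
    qrk <- qr(X)
    df[k] <- qrk$rank - rank_prev
    if (df[k] != spec$df[k])
      stop("rank error: term '", names(spec$terms)[k],
           "' contributes ", df[k], " df, expected ", spec$df[k],
           " (confounded with preceding terms on this design)")
    fit_ss <- proj_ss(qrk, Yc)
    ss[, k] <- pmax(fit_ss - fit_ss_prev, 0)
    fit_ss_prev <- fit_ss
    rank_prev <- qrk$rank
  }
  total_ss <- colSums(Yc^2)
  ss[, "residual"] <- pmax(total_ss - fit_ss_prev, 0)
  df_res <- n - rank_prev
  df_all <- c(df, residual = df_res)
  ms <- sweep(ss, 2, df_all, `/`)
  structure(
    list(model = spec$model, spec = spec,
         sources = colnames(ss), df = df_all,
         ss = ss, ms = ms, rms = sqrt(ms),
         mean_expression = mean_expr,
         n_obs = n, features = x$features),
    class = "nano_vca"
  )
}

## Squared norm of the projection of each column of Y onto the column
## space of the qr-decomposed design
proj_ss <- function(qrx, Y) {
  q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
  colSums(crossprod(q, Y)^2)
}

#' Fit one feature's ANOVA decomposition
#'
#' Single-feature convenience wrapper around [nano_vca()].
#'
#' @param values numeric vector of log2 expression per observation.
#' @param annotations lane-annotation data frame (`cartridge`, `scan`,
#'   `sample`, `replicate`, and for scan models also `prep`, `scanner` or a
#'   design to derive them from).
#' @param spec an [anova_model_spec()] or model name.
#' @param design an [build_design()] used to attach prep/scanner
#'   generations when `annotations` lacks them.
#' @return One-row data frame with `mean_expression` and `df`/`ss`/`ms`/
#'   `rms` per source.
#' @export
fit_feature_anova <- function(values, annotations, spec,
                              design = build_design()) {
  ann <- as.data.frame(annotations)
  if (is.null(ann$prep)) ann$prep <- unname(design$prep[ann$cartridge])
  if (is.null(ann$scanner))
    ann$scanner <- unname(design$scanner[ann$cartridge])
  m <- matrix(values, nrow = 1,
              dimnames = list("feature", NULL))
  x <- ncounter_matrix(m, ann[c("cartridge", "scan", "sample", "replicate")],
                       scale = "log2")
  x$lanes$prep <- ann$prep
  x$lanes$scanner <- ann$scanner
  fit <- nano_vca(x, spec)
  as.data.frame(fit)[1, , drop = FALSE]
}

#' Decompose every feature of a matrix
#'
#' Spreadsheet-style view of a [nano_vca()] fit: one row per feature with
#' mean expression and the per-source df/SS/MS/RMS columns.
#'
#' @param x an `ncounter_matrix` (log2) or a fitted `"nano_vca"`.
#' @param model model name, ignored when `x` is already a fit.
#' @return A data frame, one row per feature.
#' @export
decompose_matrix <- function(x, model = "scan1") {
  fit <- if (inherits(x, "nano_vca")) x else nano_vca(x, model)
  as.data.frame(fit)
}

#' @export
as.data.frame.nano_vca <- function(x, ...) {
  out <- data.frame(feature = rownames(x$ss),
                    mean_expression = unname(x$mean_expression))
  for (src in x$sources) {
    out[[paste0("df_", src)]] <- x$df[[src]]
    out[[paste0("ss_", src)]] <- unname(x$ss[, src])
    out[[paste0("ms_", src)]] <- unname(x$ms[, src])
    out[[paste0("rms_", src)]] <- unname(x$rms[, src])
  }
  rownames(out) <- NULL
  out
}

#' @export
print.nano_vca <- function(x, ...) {
  cat("Per-feature ANOVA variance decomposition (model:", x$model, ")\n")
  cat("  ", nrow(x$ss), "features,", x$n_obs, "observations; df:",
      paste(names(x$df), x$df, sep = "=", collapse = ", "), "\n")
  cat("  mean RMS by source:\n")
  print(round(colMeans(x$rms), 4))
  invisible(x)
}

#' Summarise a variance decomposition
#'
#' Reports per-source mean squares averaged over features and, where the
#' standard design gives a clean expectation, method-of-moments estimates of
#' the generating standard deviations: `sigma_b = sqrt((mean MS_B - mean
#' MS_E) / 8)` and, for the first-scan model, `sigma_p` and `sigma_s` from
#' `sqrt((mean MS - mean MS_E) / 12)` (negative moment differences are
#' truncated at zero).
#'
#' @param object a `"nano_vca"`.
#' @param ... ignored.
#' @return A `"summary.nano_vca"` list with `mean_ms`, `mean_rms` and
#'   `sigma_hat`.
#' @export
summary.nano_vca <- function(object, ...) {
  mean_ms <- colMeans(object$ms)
  res <- mean_ms[["residual"]]
  sigma_hat <- c()
  if ("B" %in% object$sources)
    sigma_hat["sigma_b"] <- sqrt(max(mean_ms[["B"]] - res, 0) / 8)
  if (object$model == "scan1") {
    sigma_hat["sigma_p"] <- sqrt(max(mean_ms[["P"]] - res, 0) / 12)
    sigma_hat["sigma_s"] <- sqrt(max(mean_ms[["S"]] - res, 0) / 12)
  }
  if (object$model == "both_scans")
    sigma_hat["sigma_t"] <- sqrt(max(mean_ms[["T"]] - res, 0) / 12)
  structure(list(model = object$model, n_features = nrow(object$ms),
                 df = object$df, mean_ms = mean_ms,
                 mean_rms = colMeans(object$rms), sigma_hat = sigma_hat),
            class = "summary.nano_vca")
}

#' @export
print.summary.nano_vca <- function(x, ...) {
  cat("Variance decomposition summary (model:", x$model, ",",
      x$n_features, "features)\n\nMean squares by source:\n")
  print(round(x$mean_ms, 5))
  if (length(x$sigma_hat)) {
    cat("\nMethod-of-moments effect-sd estimates (log2 units):\n")
    print(round(x$sigma_hat, 4))
  }
  invisible(x)
}

#' Per-feature RMS matrix
#'
#' @param object a `"nano_vca"`.
#' @param ... ignored.
#' @return Features x sources matrix of root-mean-squares.
#' @export
coef.nano_vca <- function(object, ...) object$rms

#' Plot RMS trend curves of a decomposition
#'
#' Smooths each source's per-feature RMS against mean log2 expression with
#' LOESS (see [trend_curves()]) and draws one line per source.
#'
#' @param x a `"nano_vca"`.
#' @param span,degree LOESS settings.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.nano_vca <- function(x, span = 0.75, degree = 2, ...) {
  curves <- trend_curves(x, span = span, degree = degree)
  plot_curves(curves, main = paste("RMS trends, model", x$model), ...)
}

#' Write a decomposition table
#'
#' @param fit a `"nano_vca"`.
#' @param path output TSV path; a JSON sidecar `<path>.json` echoes the
#'   model layout.
#' @return `path`, invisibly.
#' @export
write_vca_table <- function(fit, path) {
  utils::write.table(as.data.frame(fit), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(model = fit$model, n_obs = fit$n_obs,
         df = as.list(fit$df), sources = fit$sources),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
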
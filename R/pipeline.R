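#' Pipeline run configuration
#'
#' @param mode input mode: `"synthetic"` (simulate counts), `"rcc_dir"`
#'   (read and normalize RCC lane files) or `"matrix"` (read an already
#'   normalized annotated log2 matrix).
#' @param path input path for `"rcc_dir"`/`"matrix"` modes.
#' @param out output directory (created if missing).
#' @param synthetic a [synthetic_config()] (synthetic mode).
#' @param norm a [norm_config()].
#' @param span,degree,grid_points LOESS trend settings.
#' @param metric,linkage clustering settings.
#' @param high_expr_quantile features above this quantile of mean expression
#'   count as "high expression" in the report's RMS-ratio summaries
#'   (default 0.5, i.e. the medium-high half).
#' @param seed integer seed for the synthetic mode.
#' @return A `"run_config"` list.
#' @export
run_config <- function(mode = c("synthetic", "rcc_dir", "matrix"),
                       path = NULL, out = tempfile("nanocompare_run_"),
                       synthetic = NULL, norm = norm_config(),
                       span = 0.75, degree = 2, grid_points = 100,
                       metric = "euclidean", linkage = "average",
                       high_expr_quantile = 0.5, seed = 1L) {
  mode <- match.arg(mode)
  if (mode != "synthetic" && is.null(path))
    stop("configuration error: mode '", mode, "' requires an input path")
  if (mode == "synthetic" && is.null(synthetic))
    synthetic <- synthetic_config(seed = seed)
  structure(
    list(mode = mode, path = path, out = out, synthetic = synthetic,
         norm = norm, span = span, degree = degree,
         grid_points = grid_points, metric = metric, linkage = linkage,
         high_expr_quantile = high_expr_quantile, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()], [norm_config()] and
#' [synthetic_config()] (`synthetic:` block; design overrides via
#' `design: {prep: ..., scanner: ...}`).
#'
#' @param path YAML file.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(y$synthetic)) {
    s <- y$synthetic
    design <- if (!is.null(s$design))
      build_design(prep = unlist(s$design$prep),
                   scanner = unlist(s$design$scanner))
    else build_design()
    syn <- do.call(synthetic_config,
                   c(s[setdiff(names(s), "design")],
                     list(design = design)))
  }
  nc <- if (!is.null(y$norm)) do.call(norm_config, y$norm) else norm_config()
  args <- y[intersect(names(y),
                      c("mode", "path", "out", "span", "degree",
                        "grid_points", "metric", "linkage",
                        "high_expr_quantile", "seed"))]
  do.call(run_config, c(args, list(synthetic = syn, norm = nc)))
}

#' Run the full platform-comparison pipeline
#'
#' Executes ingest (or simulation), normalization when starting from raw
#' counts, two-way clustering with heatmap, all pairwise first-scan and
#' cross-scan lane concordances, the three per-feature ANOVA variance
#' decompositions, and LOESS RMS trend curves; writes every artifact under
#' the output directory plus a machine-readable JSON report and a MANIFEST.
#' Fully deterministic given the configuration (including seed): two runs
#' with the same config produce byte-identical reports.
#'
#' @param config a [run_config()].
#' @return The `"summary_report"` list (invisibly written as
#'   `report.json`): per comparison the PCC min/max, per model the median
#'   high-expression RMS ratio of each technical source versus residual,
#'   and the file inventory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  manifest <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(manifest, paste0("INCOMPLETE at stage: ", name)),
                 file.path(out, "MANIFEST"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(file) manifest <<- c(manifest, file)

  ## ingest -------------------------------------------------------------
  mat <- stage("ingest", switch(config$mode,
    synthetic = {
      sim <- simulate_counts(config$synthetic)
      lanes_to_matrix(sim$lanes)
    },
    rcc_dir = read_rcc_dir(config$path),
    matrix = read_annotated_matrix(config$path)
  ))

  ## normalization (raw counts only) ------------------------------------
  if (mat$scale == "linear_counts") {
    mat <- stage("normalize", normalize_counts(mat, config$norm))
    stage("normalize", {
      write_norm_report(mat, file.path(out, "normalization_report.tsv"))
      write_annotated_matrix(mat, file.path(out, "normalized_log2.tsv"))
    })
    emit("normalization_report.tsv")
    emit("normalized_log2.tsv")
  }
  endo <- mat[mat$features$code_class == "Endogenous", ]

  ## clustering ----------------------------------------------------------
  stage("cluster", cluster_heatmap(endo, file.path(out, "heatmap"),
                                   metric = config$metric,
                                   linkage = config$linkage))
  emit("heatmap.png"); emit("heatmap_reordered.tsv")

  ## concordance ---------------------------------------------------------
  carts <- sort(unique(endo$lanes$cartridge))
  pairs <- utils::combn(carts, 2, simplify = FALSE)
  pcc_section <- list()
  for (pr in pairs) {
    tab <- stage("concordance", pairwise_pcc(endo, pr, scan = 1L))
    f <- sprintf("pcc_%s_scan1.tsv", paste(pr, collapse = "_"))
    utils::write.table(tab, file.path(out, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit(f)
    r <- pcc_range(tab)
    pcc_section[[paste0(paste(pr, collapse = "-vs-"), "_scan1")]] <-
      list(min = r[["min"]], max = r[["max"]], n_lanes = nrow(tab))
  }
  cross <- intersect(carts,
                     unique(endo$lanes$cartridge[endo$lanes$scan == 2L]))
  cross <- intersect(cross, c("A", "B"))
  for (cart in cross) {
    tab <- stage("concordance", scanpair_pcc(endo, cart))
    f <- sprintf("pcc_%s_cross_scan.tsv", cart)
    utils::write.table(tab, file.path(out, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit(f)
    r <- pcc_range(tab)
    pcc_section[[paste0(cart, "_scan1-vs-scan2")]] <-
      list(min = r[["min"]], max = r[["max"]], n_lanes = nrow(tab))
  }

  ## variance decomposition + trends -------------------------------------
  models <- c("scan1", "scan2", "both_scans")
  vca_section <- list()
  for (m in models) {
    fit <- stage(paste0("decompose_", m), nano_vca(endo, m))
    write_vca_table(fit, file.path(out, sprintf("vca_%s.tsv", m)))
    emit(sprintf("vca_%s.tsv", m))
    curves <- stage(paste0("trend_", m),
                    trend_curves(fit, span = config$span,
                                 degree = config$degree,
                                 grid_points = config$grid_points))
    export_curves(curves, file.path(out, sprintf("curves_%s.tsv", m)))
    emit(sprintf("curves_%s.tsv", m)); emit(sprintf("curves_%s.png", m))
    hi <- fit$mean_expression >=
      stats::quantile(fit$mean_expression, config$high_expr_quantile)
    tech <- setdiff(fit$sources, c("B", "residual"))
    # df-bias-corrected RMS ratios, matching the trend-curve scale
    res_c <- fit$rms[hi, "residual"] /
      c4_factor(fit$df[["residual"]])
    ratios <- lapply(tech, function(src)
      stats::median((fit$rms[hi, src] / c4_factor(fit$df[[src]])) /
                      res_c))
    names(ratios) <- paste0("median_high_expr_rms_ratio_", tech)
    vca_section[[m]] <- c(
      list(n_features = nrow(fit$rms),
           mean_ms = as.list(colMeans(fit$ms))),
      ratios
    )
  }

  report <- list(
    mode = config$mode,
    seed = config$seed,
    n_features = nrow(endo$values),
    n_lanes = ncol(endo$values),
    pcc = pcc_section,
    variance_decomposition = vca_section,
    files = as.list(sort(manifest))
  )
  class(report) <- c("summary_report", class(report))
  jsonlite::write_json(unclass(report), file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(sort(manifest), "report.json", "COMPLETE"),
             file.path(out, "MANIFEST"))
  invisible(report)
}

#' @export
print.summary_report <- function(x, ...) {
  cat("nanocompare pipeline report (mode:", x$mode, ")\n")
  cat("  ", x$n_features, "features x", x$n_lanes, "lanes\n")
  cat("  PCC ranges:\n")
  for (nm in names(x$pcc))
    cat(sprintf("    %-22s %.4f - %.4f\n", nm,
                x$pcc[[nm]]$min, x$pcc[[nm]]$max))
  for (m in names(x$variance_decomposition)) {
    v <- x$variance_decomposition[[m]]
    rn <- grep("^median_high_expr_rms_ratio_", names(v), value = TRUE)
    cat("  model", m, "high-expression RMS ratios vs residual:",
        paste(sub("^median_high_expr_rms_ratio_", "", rn),
              vapply(v[rn], function(z) sprintf("%.3f", z), ""),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
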
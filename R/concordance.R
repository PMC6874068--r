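#' Per-lane Pearson concordance between two cartridges
#'
#' Pairs the lanes of two cartridges at a given scan by (sample, replicate)
#' position and computes, for each of the matched lane pairs (12 on the
#' standard design), the Pearson correlation of the two lanes' expression
#' across all retained features.
#'
#' @param x an `ncounter_matrix` with `scale = "log2"`.
#' @param pair character vector of two cartridge names, e.g. `c("A", "B")`.
#' @param scan scan index at which to compare, default 1.
#' @return A `"pcc_table"` data frame with columns `pair`, `scan`,
#'   `sample`, `replicate`, `pcc`, `n_features`.
#' @examples
#' sim <- simulate_log2(synthetic_config(n_features = 100, seed = 1))
#' tab <- pairwise_pcc(sim$matrix, c("A", "B"))
#' pcc_range(tab)
#' @export
pairwise_pcc <- function(x, pair, scan = 1L) {
  stopifnot(inherits(x, "ncounter_matrix"), length(pair) == 2)
  i1 <- lane_which(x, cartridge = pair[1], scan = scan)
  i2 <- lane_which(x, cartridge = pair[2], scan = scan)
  if (!length(i1) || !length(i2))
    stop("pairing error: cartridge ",
         pair[c(!length(i1), !length(i2))][1],
         " has no lanes at scan ", scan)
  key1 <- with(x$lanes[i1, ], paste(sample, replicate))
  key2 <- with(x$lanes[i2, ], paste(sample, replicate))
  if (!setequal(key1, key2))
    stop("pairing error: unmatched lane position(s): ",
         paste(c(setdiff(key1, key2), setdiff(key2, key1)), collapse = ", "))
  pcc_rows(x, i1[order(key1)], i2[order(key2)],
           label = paste(pair, collapse = "-vs-"),
           scan_label = as.character(scan))
}

#' Per-lane Pearson concordance between repeated scans
#'
#' Correlates the first- and second-scan columns of each physical lane of a
#' cartridge across all retained features.
#'
#' @param x an `ncounter_matrix` with `scale = "log2"`.
#' @param cartridge cartridge name.
#' @return A `"pcc_table"` data frame (one row per lane).
#' @export
scanpair_pcc <- function(x, cartridge) {
  stopifnot(inherits(x, "ncounter_matrix"))
  i1 <- lane_which(x, cartridge = cartridge, scan = 1L)
  i2 <- lane_which(x, cartridge = cartridge, scan = 2L)
  if (!length(i1) || !length(i2))
    stop("pairing error: cartridge ", cartridge,
         " is not present at both scans")
  key1 <- with(x$lanes[i1, ], paste(sample, replicate))
  key2 <- with(x$lanes[i2, ], paste(sample, replicate))
  if (!setequal(key1, key2))
    stop("pairing error: unmatched lane position(s) across scans: ",
         paste(c(setdiff(key1, key2), setdiff(key2, key1)), collapse = ", "))
  pcc_rows(x, i1[order(key1)], i2[order(key2)],
           label = paste0(cartridge, "-scan1-vs-scan2"),
           scan_label = "1-vs-2")
}

pcc_rows <- function(x, i1, i2, label, scan_label) {
  if (nrow(x$values) < 3)
    stop("need at least 3 shared features to correlate lanes")
  rows <- lapply(seq_along(i1), function(k) {
    a <- x$values[, i1[k]]
    b <- x$values[, i2[k]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      stop("undefined-correlation error: zero-variance lane column ",
           colnames(x$values)[c(i1[k], i2[k])[c(stats::sd(a) == 0,
                                                 stats::sd(b) == 0)]][1])
    data.frame(pair = label, scan = scan_label,
               sample = x$lanes$sample[i1[k]],
               replicate = x$lanes$replicate[i1[k]],
               pcc = stats::cor(a, b), n_features = nrow(x$values))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pcc_table", "data.frame")
  out
}

#' Range of a concordance table
#'
#' @param table a `"pcc_table"`.
#' @return Named numeric vector `c(min = ..., max = ...)`.
#' @export
pcc_range <- function(table) {
  if (is.null(table) || !nrow(table)) stop("empty PCC table")
  c(min = min(table$pcc), max = max(table$pcc))
}

#' Two-way hierarchical clustering with heatmap export
#'
#' Agglomerative clustering of features (rows) and lanes (columns) of a
#' log2 matrix, with a red/black/green heatmap (red high, green low,
#' symmetric about the matrix median) and the reordered matrix written to
#' disk.
#'
#' @param x an `ncounter_matrix` with at least 2 features and 2 lanes.
#' @param out output stem; writes `<out>.png` and `<out>_reordered.tsv`.
#'   `NULL` skips file output.
#' @param metric distance metric for [stats::dist()], default
#'   `"euclidean"`.
#' @param linkage agglomeration method for [stats::hclust()], default
#'   `"average"`.
#' @return A `"cluster_result"`: list with `row_order`, `col_order`,
#'   `row_heights`, `col_heights`, `row_hclust`, `col_hclust`, `metric`,
#'   `linkage`.
#' @export
cluster_heatmap <- function(x, out = NULL, metric = "euclidean",
                            linkage = "average") {
  stopifnot(inherits(x, "ncounter_matrix"))
  v <- x$values
  if (nrow(v) < 2 || ncol(v) < 2)
    stop("need at least 2 features and 2 lanes to cluster")
  hr <- stats::hclust(stats::dist(v, method = metric), method = linkage)
  hc <- stats::hclust(stats::dist(t(v), method = metric), method = linkage)
  reordered <- v[hr$order, hc$order, drop = FALSE]
  if (!is.null(out)) {
    utils::write.table(
      data.frame(feature = rownames(reordered), reordered,
                 check.names = FALSE),
      paste0(out, "_reordered.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    grDevices::png(paste0(out, ".png"), width = 900, height = 700)
    med <- stats::median(v)
    half <- max(abs(range(v - med)), .Machine$double.eps)
    pal <- grDevices::colorRampPalette(c("green", "black", "red"))(255)
    graphics::image(t(reordered)[, rev(seq_len(nrow(reordered))),
                                 drop = FALSE],
                    col = pal, zlim = c(med - half, med + half),
                    axes = FALSE,
                    main = "log2 expression (red high, green low)")
    grDevices::dev.off()
  }
  structure(
    list(row_order = hr$order, col_order = hc$order,
         row_heights = hr$height, col_heights = hc$height,
         row_hclust = hr, col_hclust = hc,
         metric = metric, linkage = linkage),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Two-way hierarchical clustering (", x$metric, "distance,",
      x$linkage, "linkage):", length(x$row_order), "features x",
      length(x$col_order), "lanes\n")
  invisible(x)
}
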
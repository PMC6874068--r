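#' Annotated expression matrix
#'
#' Light container for an nCounter expression matrix: a features x lanes
#' numeric matrix together with per-feature probe classes and per-lane
#' design annotations (cartridge, scan, sample, replicate). Values are
#' either linear molecule counts (`scale = "linear_counts"`) or log2
#' normalized expression (`scale = "log2"`).
#'
#' @param values numeric matrix, features in rows and lanes in columns.
#' @param lanes data frame with one row per column of `values` and columns
#'   `cartridge`, `scan`, `sample`, `replicate`.
#' @param code_class character vector of probe classes per feature, one of
#'   `"Endogenous"`, `"Positive"`, `"Negative"`, `"Housekeeping"`,
#'   `"Ligation"`, `"SpikeIn"`. Defaults to all-Endogenous.
#' @param scale `"linear_counts"` or `"log2"`.
#'
#' @return An object of class `"ncounter_matrix"`: a list with elements
#'   `values`, `features` (data frame `name`, `code_class`), `lanes`, and
#'   `scale`.
#' @export
ncounter_matrix <- function(values, lanes, code_class = NULL,
                            scale = c("log2", "linear_counts")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("feature_%04d", seq_len(nrow(values)))
  if (anyNA(values))
    stop("expression matrix must not contain missing values")
  if (scale == "linear_counts" && nrow(values) && any(values < 0))
    stop("linear counts must be non-negative")
  if (is.null(code_class)) code_class <- rep("Endogenous", nrow(values))
  code_class <- as.character(code_class)
  if (length(code_class) != nrow(values))
    stop("code_class must have one entry per feature")
  bad <- setdiff(unique(code_class), probe_classes())
  if (length(bad))
    stop("unknown probe class(es): ", paste(bad, collapse = ", "))
  lanes <- as.data.frame(lanes)
  need <- c("cartridge", "scan", "sample", "replicate")
  if (!all(need %in% names(lanes)))
    stop("lane annotations must have columns ",
         paste(need, collapse = ", "))
  if (nrow(lanes) != ncol(values))
    stop("lane annotations must have one row per matrix column")
  lanes$cartridge <- as.character(lanes$cartridge)
  lanes$scan <- as.integer(lanes$scan)
  lanes$sample <- as.integer(lanes$sample)
  lanes$replicate <- as.integer(lanes$replicate)
  key <- with(lanes, paste(cartridge, scan, sample, replicate))
  if (anyDuplicated(key))
    stop("duplicate lane annotation tuple: ", key[duplicated(key)][1])
  colnames(values) <- lane_labels(lanes)
  rownames(lanes) <- colnames(values)
  structure(
    list(values = values,
         features = data.frame(name = rownames(values),
                               code_class = code_class,
                               stringsAsFactors = FALSE),
         lanes = lanes,
         scale = scale),
    class = "ncounter_matrix"
  )
}

probe_classes <- function() {
  c("Endogenous", "Positive", "Negative", "Housekeeping",
    "Ligation", "SpikeIn")
}

lane_labels <- function(lanes) {
  make.unique(
    paste(lanes$sample, lanes$cartridge, lanes$scan, sep = "_"),
    sep = "."
  )
}

#' @export
print.ncounter_matrix <- function(x, ...) {
  cat("ncounter_matrix:", nrow(x$values), "features x", ncol(x$values),
      "lanes (scale:", x$scale, ")\n")
  cls <- table(x$features$code_class)
  cat("  probe classes:",
      paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  cat("  cartridges:",
      paste(sort(unique(x$lanes$cartridge)), collapse = ", "),
      "| scans:", paste(sort(unique(x$lanes$scan)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ncounter_matrix <- function(x) dim(x$values)

#' Subset an annotated expression matrix
#'
#' Row (feature) and column (lane) subsetting that keeps feature and lane
#' annotations in step with the value matrix.
#'
#' @param x an `ncounter_matrix`.
#' @param i feature index (integer, logical or character).
#' @param j lane index.
#' @param ... ignored.
#' @return An `ncounter_matrix`.
#' @export
`[.ncounter_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  out <- x
  out$values <- x$values[i, j, drop = FALSE]
  out$features <- x$features[i, , drop = FALSE]
  out$lanes <- x$lanes[j, , drop = FALSE]
  rownames(out$features) <- NULL
  out
}

## Columns (in matrix column order) matching a lane predicate
lane_which <- function(x, cartridge = NULL, scan = NULL) {
  keep <- rep(TRUE, nrow(x$lanes))
  if (!is.null(cartridge)) keep <- keep & x$lanes$cartridge %in% cartridge
  if (!is.null(scan)) keep <- keep & x$lanes$scan %in% scan
  which(keep)
}
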
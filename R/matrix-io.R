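#' Read an annotated log2 expression matrix
#'
#' Reads the tab- or comma-delimited text dialect used to distribute
#' normalized nCounter matrices: features in rows, lanes in columns, the
#' first column holding feature names and each column header encoding the
#' lane's sample number, cartridge name and scan index as delimiter-joined
#' tokens (default `"1_A_2"` = sample 1, cartridge A, scan 2).
#'
#' Because the header carries no technical-replicate token, the replicate
#' index is assigned by order of occurrence of each (sample, cartridge,
#' scan) triple across the columns: the first occurrence is replicate 1,
#' the second replicate 2, and so on.
#'
#' @param path input file.
#' @param sep field separator; `"\t"` (default) or `","`.
#' @param token_sep delimiter joining the header tokens, default `"_"`.
#' @param code_class optional per-feature probe classes (default Endogenous).
#' @return An `ncounter_matrix` with `scale = "log2"`.
#' @export
read_annotated_matrix <- function(path, sep = "\t", token_sep = "_",
                                  code_class = NULL) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, row.names = NULL,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (!ncol(raw))
    stop("matrix format error: no columns in ", path)
  headers <- colnames(raw)[-1]
  lanes <- parse_lane_headers(headers, token_sep)
  if (!nrow(raw)) {
    values <- matrix(numeric(0), nrow = 0, ncol = length(headers))
  } else {
    values <- vapply(raw[-1], function(col) {
      v <- suppressWarnings(as.numeric(col))
      if (anyNA(v))
        stop("matrix format error: non-numeric value in ", path)
      v
    }, numeric(nrow(raw)))
    if (nrow(raw) == 1L) values <- matrix(values, nrow = 1L)
    rownames(values) <- raw[[1]]
  }
  ncounter_matrix(values, lanes, code_class = code_class, scale = "log2")
}

#' Write an annotated log2 expression matrix
#'
#' Inverse of [read_annotated_matrix()]: emits a delimited text table with
#' feature names in the first column and `sample<sep>cartridge<sep>scan`
#' column headers, lanes ordered so that replicate 1 of each (sample,
#' cartridge, scan) triple precedes replicate 2.
#'
#' @param x an `ncounter_matrix` (any scale; values written as stored, full
#'   precision).
#' @param path output file.
#' @param sep field separator, default tab.
#' @param token_sep header token delimiter, default `"_"`.
#' @return `path`, invisibly.
#' @export
write_annotated_matrix <- function(x, path, sep = "\t", token_sep = "_") {
  stopifnot(inherits(x, "ncounter_matrix"))
  ord <- order(x$lanes$cartridge, x$lanes$scan, x$lanes$sample,
               x$lanes$replicate)
  lanes <- x$lanes[ord, , drop = FALSE]
  headers <- paste(lanes$sample, lanes$cartridge, lanes$scan,
                   sep = token_sep)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("Feature", headers), collapse = sep), con)
  if (nrow(x$values)) {
    vals <- x$values[, ord, drop = FALSE]
    body <- apply(format(vals, digits = 17, trim = TRUE, scientific = FALSE),
                  1, paste, collapse = sep)
    writeLines(paste(rownames(vals), body, sep = sep), con)
  }
  invisible(path)
}

parse_lane_headers <- function(headers, token_sep) {
  if (!length(headers))
    return(data.frame(cartridge = character(0), scan = integer(0),
                      sample = integer(0), replicate = integer(0)))
  toks <- strsplit(headers, token_sep, fixed = TRUE)
  n <- lengths(toks)
  if (any(n < 3))
    stop("annotation error: cannot parse lane header(s): ",
         paste(headers[n < 3], collapse = ", "))
  sample <- suppressWarnings(as.integer(vapply(toks, `[`, "", 1)))
  cartridge <- vapply(toks, `[`, "", 2)
  scan <- suppressWarnings(as.integer(vapply(toks, `[`, "", 3)))
  if (anyNA(sample) || anyNA(scan))
    stop("annotation error: non-integer sample or scan token in header(s): ",
         paste(headers[is.na(sample) | is.na(scan)], collapse = ", "))
  key <- paste(sample, cartridge, scan)
  replicate <- stats::ave(seq_along(key), key, FUN = seq_along)
  data.frame(cartridge = cartridge, scan = scan, sample = sample,
             replicate = as.integer(replicate))
}
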
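#' Read an RCC (Reporter Code Count) lane file
#'
#' Parses the vendor's tag-delimited RCC text layout: sections `Header`,
#' `Sample_Attributes`, `Lane_Attributes` and `Code_Summary`, the last
#' holding comma-separated `CodeClass,Name,Accession,Count` rows. Probe
#' classes outside the recognised set (Endogenous, Positive, Negative,
#' Housekeeping, Ligation, SpikeIn) are mapped to Endogenous with a warning.
#'
#' @param path path to an RCC file.
#' @return A `"lane_record"`: a list with `lane_id`, `cartridge`, `scan`,
#'   `sample`, `replicate`, `fov_count` and `probes`, a data frame with
#'   columns `code_class`, `name`, `accession`, `count` (integer counts).
#' @export
read_rcc <- function(path) {
  if (!file.exists(path)) stop("RCC file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  sections <- split_rcc_sections(lines)
  if (is.null(sections$Code_Summary))
    stop("RCC format error: missing Code_Summary section in ", path)

  sample_attr <- parse_kv(sections$Sample_Attributes)
  lane_attr <- parse_kv(sections$Lane_Attributes)

  body <- sections$Code_Summary
  probes <- empty_probes()
  if (length(body)) {
    header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
    data_rows <- body[-1]
    data_rows <- data_rows[nzchar(trimws(data_rows))]
    if (!identical(tolower(header[1:3]),
                   c("codeclass", "name", "accession")))
      stop("RCC format error: unexpected Code_Summary header: ", body[1])
    if (length(data_rows)) {
      parts <- strsplit(data_rows, ",", fixed = TRUE)
      nfield <- lengths(parts)
      if (any(nfield != 4))
        stop("RCC format error: Code_Summary row with ",
             nfield[nfield != 4][1], " fields: ",
             data_rows[nfield != 4][1])
      m <- matrix(unlist(parts), ncol = 4, byrow = TRUE)
      counts_chr <- m[, 4]
      ok <- grepl("^\\s*[0-9]+\\s*$", counts_chr)
      if (!all(ok))
        stop("RCC parse error: non-integer count in row: ",
             data_rows[!ok][1])
      cls <- m[, 1]
      unknown <- !(cls %in% probe_classes())
      if (any(unknown)) {
        warning("RCC: unknown code class(es) ",
                paste(unique(cls[unknown]), collapse = ", "),
                " mapped to Endogenous")
        cls[unknown] <- "Endogenous"
      }
      if (any(!nzchar(m[, 2])))
        stop("RCC parse error: empty probe name")
      if (anyDuplicated(m[, 2]))
        stop("RCC duplication error: duplicate probe name ",
             m[, 2][duplicated(m[, 2])][1])
      probes <- data.frame(code_class = cls, name = m[, 2],
                           accession = m[, 3],
                           count = as.integer(counts_chr),
                           stringsAsFactors = FALSE)
    }
  }

  structure(
    list(
      lane_id = sample_attr[["ID"]] %||% lane_attr[["ID"]] %||% NA_character_,
      cartridge = sample_attr[["CartridgeID"]] %||% NA_character_,
      scan = as_int_or_na(sample_attr[["ScanIndex"]]),
      sample = as_int_or_na(sample_attr[["SampleNumber"]]),
      replicate = as_int_or_na(sample_attr[["Replicate"]]),
      fov_count = as_int_or_na(lane_attr[["FovCount"]]),
      probes = probes
    ),
    class = "lane_record"
  )
}

#' Write an RCC lane file
#'
#' Emits the tag-delimited RCC layout read back by [read_rcc()]; the two are
#' exact inverses for the fields carried by a `lane_record`.
#'
#' @param lane a `"lane_record"` (see [read_rcc()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rcc <- function(lane, path) {
  p <- lane$probes
  lines <- c(
    "<Header>",
    "FileVersion,1.7",
    "SoftwareVersion,4.0.0.3",
    "</Header>",
    "<Sample_Attributes>",
    paste0("ID,", lane$lane_id %||% ""),
    paste0("CartridgeID,", lane$cartridge %||% ""),
    paste0("SampleNumber,", lane$sample %||% ""),
    paste0("Replicate,", lane$replicate %||% ""),
    paste0("ScanIndex,", lane$scan %||% ""),
    "</Sample_Attributes>",
    "<Lane_Attributes>",
    paste0("ID,", lane$lane_id %||% ""),
    paste0("FovCount,", lane$fov_count %||% ""),
    "</Lane_Attributes>",
    "<Code_Summary>",
    "CodeClass,Name,Accession,Count",
    if (nrow(p)) paste(p$code_class, p$name, p$accession, p$count, sep = ","),
    "</Code_Summary>"
  )
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.lane_record <- function(x, ...) {
  cat("RCC lane", x$lane_id, "- cartridge", x$cartridge,
      "scan", x$scan, "sample", x$sample, "replicate", x$replicate,
      "-", nrow(x$probes), "probes\n")
  invisible(x)
}

#' Assemble lane records into a count matrix
#'
#' Stacks a list of lane records (e.g. from [read_rcc()] over a directory)
#' into a linear-count `ncounter_matrix`. All lanes must share an identical
#' probe set.
#'
#' @param lanes list of `"lane_record"` objects.
#' @return An `ncounter_matrix` with `scale = "linear_counts"`.
#' @export
lanes_to_matrix <- function(lanes) {
  if (!length(lanes)) stop("no lane records supplied")
  ref <- lanes[[1]]$probes
  values <- vapply(lanes, function(l) {
    if (!identical(l$probes$name, ref$name))
      stop("lane ", l$lane_id, " has a different probe set")
    as.double(l$probes$count)
  }, numeric(nrow(ref)))
  if (nrow(ref) == 1L) values <- matrix(values, nrow = 1L)
  rownames(values) <- ref$name
  ann <- data.frame(
    cartridge = vapply(lanes, function(l) l$cartridge, ""),
    scan = vapply(lanes, function(l) as.integer(l$scan), 1L),
    sample = vapply(lanes, function(l) as.integer(l$sample), 1L),
    replicate = vapply(lanes, function(l) as.integer(l$replicate), 1L)
  )
  ncounter_matrix(values, ann, code_class = ref$code_class,
                  scale = "linear_counts")
}

#' Read a directory of RCC files into a count matrix
#'
#' @param dir directory containing `*.RCC`/`*.rcc` files.
#' @return An `ncounter_matrix` with `scale = "linear_counts"`.
#' @export
read_rcc_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.rcc$", ignore.case = TRUE,
                           full.names = TRUE))
  if (!length(files)) stop("no RCC files found in ", dir)
  lanes_to_matrix(lapply(files, read_rcc))
}

split_rcc_sections <- function(lines) {
  open <- grep("^<[A-Za-z_]+>$", lines)
  close <- grep("^</[A-Za-z_]+>$", lines)
  out <- list()
  for (i in seq_along(open)) {
    tag <- sub("^<([A-Za-z_]+)>$", "\\1", lines[open[i]])
    end <- close[close > open[i]]
    if (!length(end))
      stop("RCC format error: unterminated section <", tag, ">")
    out[[tag]] <- lines[seq(open[i] + 1L, end[1] - 1L)]
    if (end[1] == open[i] + 1L) out[[tag]] <- character(0)
  }
  out
}

parse_kv <- function(lines) {
  if (is.null(lines) || !length(lines)) return(list())
  parts <- strsplit(lines, ",", fixed = TRUE)
  keys <- vapply(parts, `[`, "", 1)
  vals <- vapply(parts, function(p)
    if (length(p) > 1) paste(p[-1], collapse = ",") else "", "")
  stats::setNames(as.list(vals), keys)
}

empty_probes <- function() {
  data.frame(code_class = character(0), name = character(0),
             accession = character(0), count = integer(0),
             stringsAsFactors = FALSE)
}

as_int_or_na <- function(x) {
  if (is.null(x) || !nzchar(x)) return(NA_integer_)
  suppressWarnings(as.integer(x))
}
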
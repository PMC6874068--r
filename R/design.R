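#' Experiment design for the four-cartridge platform comparison
#'
#' Builds the lane-level design of the two-generation nCounter comparison:
#' four 12-lane cartridges (A--D), each carrying 6 biological samples in
#' duplicate and scanned twice, with each cartridge assigned a PrepStation
#' generation and a Digital Analyzer (scanner) generation. The default
#' assignment is A = (second, second), B = (first, first), C = (second prep,
#' first scanner), D = (first prep, second scanner), giving 4 x 12 x 2 = 96
#' lane-scan observations.
#'
#' @param prep named character vector mapping cartridges to PrepStation
#'   generation (`"first"` or `"second"`). Defaults to the standard layout.
#' @param scanner named character vector mapping cartridges to scanner
#'   generation. Defaults to the standard layout.
#' @param cartridges character vector of cartridge names.
#' @param n_samples number of biological samples per cartridge (each run in
#'   duplicate).
#' @param n_replicates technical replicates of each sample within a cartridge.
#' @param scans number of repeated scans of every lane.
#'
#' @return An object of class `"ncounter_design"`: a list with elements
#'   `prep` and `scanner` (cartridge -> generation maps) and `obs`, a
#'   data frame with one row per lane-scan observation and columns
#'   `lane_id`, `cartridge`, `scan`, `sample`, `replicate`, `prep`,
#'   `scanner`, `fov`.
#'
#' @details The fields-of-view bookkeeping follows the instrument
#'   generations: 600 FOV on the first-generation scanner, 320 on the second.
#'   Overrides must keep the design balanced (every cartridge carries every
#'   sample in every replicate at every scan); unbalanced designs are
#'   rejected with an error naming the violated constraint.
#'
#' @examples
#' d <- build_design()
#' nrow(d$obs)     # 96 lane-scan observations
#' d$prep[["C"]]   # "second"
#' @export
build_design <- function(prep = NULL, scanner = NULL,
                         cartridges = c("A", "B", "C", "D"),
                         n_samples = 6L, n_replicates = 2L, scans = 2L) {
  default_prep <- c(A = "second", B = "first", C = "second", D = "first")
  default_scanner <- c(A = "second", B = "first", C = "first", D = "second")
  if (is.null(prep)) prep <- default_prep[cartridges]
  if (is.null(scanner)) scanner <- default_scanner[cartridges]
  names(prep) <- names(prep) %||% cartridges
  names(scanner) <- names(scanner) %||% cartridges

  if (!setequal(names(prep), cartridges) || anyNA(prep[cartridges]))
    stop("design error: `prep` must map every cartridge (",
         paste(cartridges, collapse = ", "), ") to a generation")
  if (!setequal(names(scanner), cartridges) || anyNA(scanner[cartridges]))
    stop("design error: `scanner` must map every cartridge to a generation")
  prep <- prep[cartridges]
  scanner <- scanner[cartridges]
  bad <- setdiff(unique(c(prep, scanner)), c("first", "second"))
  if (length(bad))
    stop("design error: unknown generation label(s): ",
         paste(bad, collapse = ", "))
  if (n_samples < 1L || n_replicates < 1L || scans < 1L)
    stop("design error: n_samples, n_replicates and scans must be positive")

  obs <- expand.grid(
    sample = seq_len(n_samples),
    replicate = seq_len(n_replicates),
    cartridge = cartridges,
    scan = seq_len(scans),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  pos <- (obs$replicate - 1L) * n_samples + obs$sample
  obs$lane_id <- sprintf("%s%02d", obs$cartridge, pos)
  obs$prep <- unname(prep[obs$cartridge])
  obs$scanner <- unname(scanner[obs$cartridge])
  obs$fov <- ifelse(obs$scanner == "first", 600L, 320L)
  obs <- obs[order(obs$scan, obs$cartridge, obs$replicate, obs$sample),
             c("lane_id", "cartridge", "scan", "sample", "replicate",
               "prep", "scanner", "fov")]
  rownames(obs) <- NULL

  design <- structure(
    list(prep = prep, scanner = scanner, obs = obs,
         cartridges = cartridges, n_samples = n_samples,
         n_replicates = n_replicates, scans = scans),
    class = "ncounter_design"
  )
  validate_design(design)
  design
}

validate_design <- function(design) {
  obs <- design$obs
  key <- with(obs, paste(cartridge, scan, sample, replicate))
  if (anyDuplicated(key))
    stop("design error: duplicated (cartridge, scan, sample, replicate) ",
         "observation")
  for (cart in design$cartridges) {
    for (sc in seq_len(design$scans)) {
      sub <- obs[obs$cartridge == cart & obs$scan == sc, ]
      want <- design$n_samples * design$n_replicates
      if (nrow(sub) != want)
        stop("design error: cartridge ", cart, " scan ", sc, " has ",
             nrow(sub), " lanes, expected ", want,
             " (", design$n_samples, " samples x ", design$n_replicates,
             " replicates)")
      tab <- table(sub$sample)
      if (length(tab) != design$n_samples ||
          any(tab != design$n_replicates))
        stop("design error: cartridge ", cart, " scan ", sc,
             " is unbalanced: every sample must appear in exactly ",
             design$n_replicates, " replicates")
    }
  }
  invisible(design)
}

#' @export
print.ncounter_design <- function(x, ...) {
  cat("nCounter comparison design:", length(x$cartridges), "cartridges x",
      x$n_samples, "samples x", x$n_replicates, "replicates x",
      x$scans, "scans =", nrow(x$obs), "lane-scan observations\n")
  map <- data.frame(cartridge = x$cartridges,
                    prep = unname(x$prep),
                    scanner = unname(x$scanner))
  print(map, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
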
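#' Normalization settings
#'
#' @param k_sd multiplier of the negative-control standard deviation in the
#'   background threshold (threshold = mean + k_sd * sd per lane). Default 2,
#'   the conventional nCounter background definition.
#' @param log_offset pseudo-count added before the log2 transform, default 1
#'   (zero counts map to 0).
#' @param background_rule how the per-lane background calls are combined into
#'   a single keep/remove decision per endogenous feature:
#'   `"majority_lanes"` (kept iff above threshold in at least 50% of lanes,
#'   the default), `"any_lane"`, or `"all_lanes"`.
#' @return A `"norm_config"` list.
#' @export
norm_config <- function(k_sd = 2, log_offset = 1,
                        background_rule = c("majority_lanes", "any_lane",
                                            "all_lanes")) {
  if (!is.numeric(k_sd) || length(k_sd) != 1 || k_sd < 0)
    stop("configuration error: k_sd must be a single non-negative number")
  if (!is.numeric(log_offset) || length(log_offset) != 1 || log_offset < 0)
    stop("configuration error: log_offset must be non-negative")
  background_rule <- match.arg(background_rule)
  structure(list(k_sd = k_sd, log_offset = log_offset,
                 background_rule = background_rule),
            class = "norm_config")
}

#' Positive-control efficiency factors
#'
#' Per-lane assay-efficiency correction from the spiked positive controls:
#' each lane's factor is the ratio of the across-lane arithmetic mean of the
#' per-lane geometric means of positive-control counts to that lane's own
#' geometric mean, so that factor * lane geomean is constant across lanes.
#'
#' @param x an `ncounter_matrix` of linear counts containing Positive probes.
#' @return Named numeric vector of per-lane factors.
#' @export
positive_factors <- function(x) {
  stopifnot(inherits(x, "ncounter_matrix"))
  if (x$scale != "linear_counts")
    stop("positive_factors expects linear counts")
  pos <- x$values[x$features$code_class == "Positive", , drop = FALSE]
  if (!nrow(pos))
    stop("configuration error: no Positive control probes in matrix")
  if (any(pos <= 0))
    stop("zero or negative positive-control count: geometric mean undefined")
  g <- exp(colMeans(log(pos)))
  mean(g) / g
}

#' Negative-control background thresholds
#'
#' Per-lane background level from the negative controls:
#' `mean(negatives) + k_sd * sd(negatives)` using the sample standard
#' deviation within each lane.
#'
#' @param x an `ncounter_matrix` of linear counts with >= 2 Negative probes.
#' @param k_sd standard-deviation multiplier.
#' @return Named numeric vector of per-lane thresholds (count units).
#' @export
background_thresholds <- function(x, k_sd = 2) {
  stopifnot(inherits(x, "ncounter_matrix"))
  neg <- x$values[x$features$code_class == "Negative", , drop = FALSE]
  if (nrow(neg) < 2)
    stop("need at least 2 Negative control probes to estimate background")
  colMeans(neg) + k_sd * apply(neg, 2, stats::sd)
}

#' Filter features at background noise level
#'
#' Removes endogenous features whose counts do not rise above the per-lane
#' background thresholds under the chosen rule. Control probes (Positive,
#' Negative, Housekeeping, Ligation, SpikeIn) are always retained; feature
#' order is preserved.
#'
#' @param x an `ncounter_matrix` of linear counts.
#' @param thresholds per-lane thresholds, as from [background_thresholds()].
#' @param rule `"majority_lanes"`, `"any_lane"` or `"all_lanes"`; a feature
#'   is kept iff its count strictly exceeds the lane threshold in >= 50% of
#'   lanes, in at least one lane, or in every lane, respectively.
#' @return The filtered `ncounter_matrix`, with attribute `"removed"` listing
#'   the dropped feature names.
#' @export
filter_background <- function(x, thresholds,
                              rule = c("majority_lanes", "any_lane",
                                       "all_lanes")) {
  stopifnot(inherits(x, "ncounter_matrix"))
  if (length(thresholds) != ncol(x$values))
    stop("thresholds must be defined for every lane")
  rule <- match.arg(rule)
  above <- sweep(x$values, 2, thresholds, `>`)
  frac <- rowMeans(above)
  keep_feature <- switch(rule,
    majority_lanes = frac >= 0.5,
    any_lane = frac > 0,
    all_lanes = frac >= 1
  )
  is_endo <- x$features$code_class == "Endogenous"
  keep <- !is_endo | keep_feature
  out <- x[keep, ]
  attr(out, "removed") <- x$features$name[!keep]
  out
}

#' Housekeeping median-normalization factors
#'
#' Per-lane scaling from the housekeeping probes: each lane's factor is the
#' across-lane arithmetic mean of the per-lane medians of housekeeping
#' counts divided by that lane's own housekeeping median.
#'
#' @param x an `ncounter_matrix` of linear counts with Housekeeping probes.
#' @return Named numeric vector of per-lane factors.
#' @export
housekeeping_factors <- function(x) {
  stopifnot(inherits(x, "ncounter_matrix"))
  hk <- x$values[x$features$code_class == "Housekeeping", , drop = FALSE]
  if (!nrow(hk))
    stop("configuration error: no Housekeeping probes in matrix")
  m <- apply(hk, 2, stats::median)
  if (any(m <= 0))
    stop("zero housekeeping median in lane ",
         colnames(x$values)[m <= 0][1])
  mean(m) / m
}

#' nCounter-style normalization to log2 expression
#'
#' Runs the three-step normalization in pipeline order: positive-control
#' efficiency correction, negative-control background filtering of
#' endogenous features, housekeeping median scaling; then transforms to
#' `log2(value + log_offset)`.
#'
#' @param x an `ncounter_matrix` of linear counts carrying Positive,
#'   Negative and Housekeeping probes.
#' @param config a [norm_config()].
#' @return An `ncounter_matrix` with `scale = "log2"` and attribute
#'   `"norm_report"`: a list with per-lane `positive_factor`,
#'   `housekeeping_factor`, `background_threshold`, the `removed` feature
#'   names, and the counts of features before/after filtering.
#' @examples
#' sim <- simulate_counts(synthetic_config(n_features = 50, seed = 1))
#' norm <- normalize_counts(lanes_to_matrix(sim$lanes), norm_config())
#' attr(norm, "norm_report")$n_removed
#' @export
normalize_counts <- function(x, config = norm_config()) {
  stopifnot(inherits(x, "ncounter_matrix"), inherits(config, "norm_config"))
  if (x$scale != "linear_counts")
    stop("normalize_counts expects linear counts")

  pf <- positive_factors(x)
  corrected <- x
  corrected$values <- sweep(x$values, 2, pf, `*`)

  thr <- background_thresholds(corrected, config$k_sd)
  filtered <- filter_background(corrected, thr, config$background_rule)
  removed <- attr(filtered, "removed")

  hf <- housekeeping_factors(filtered)
  filtered$values <- sweep(filtered$values, 2, hf, `*`)

  out <- filtered
  out$values <- log2(filtered$values + config$log_offset)
  out$scale <- "log2"
  attr(out, "removed") <- NULL
  attr(out, "norm_report") <- list(
    positive_factor = pf,
    housekeeping_factor = hf,
    background_threshold = thr,
    removed = removed,
    n_features_in = nrow(x$values),
    n_removed = length(removed),
    config = config
  )
  out
}

#' Write a normalization report
#'
#' @param x a normalized matrix from [normalize_counts()].
#' @param path output TSV path for the per-lane factor table; the removed
#'   feature list is written alongside with suffix `"_removed.txt"`.
#' @return `path`, invisibly.
#' @export
write_norm_report <- function(x, path) {
  rep <- attr(x, "norm_report")
  if (is.null(rep)) stop("matrix carries no normalization report")
  tab <- data.frame(lane = names(rep$positive_factor),
                    positive_factor = rep$positive_factor,
                    housekeeping_factor = rep$housekeeping_factor,
                    background_threshold = rep$background_threshold)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(rep$removed,
             paste0(tools::file_path_sans_ext(path), "_removed.txt"))
  invisible(path)
}
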
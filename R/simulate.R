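#' Configuration of the synthetic nCounter comparison dataset
#'
#' Parameters of the additive-effects generator that emulates the
#' 4-cartridge x 2-scan duplicate design. All effect standard deviations are
#' in log2 units. Per feature g, one draw of each effect is shared across
#' all of that feature's observations: sample effects b[g, 1..6] ~
#' N(0, sigma_b^2), a PrepStation effect p[g] ~ N(0, sigma_p^2) added when
#' the lane's prep generation is "second", a scanner effect s[g] ~
#' N(0, sigma_s^2) added when the scanner generation is "second", cartridge
#' effects c[g, A..D] ~ N(0, sigma_c^2), and a scan-time effect t[g] ~
#' N(0, sigma_t^2) added at the second scan. Residual noise is independent
#' per observation with an expression-dependent standard deviation
#' `sigma_e(mu) = noise_a + noise_b * 2^(-mu / noise_tau)`, a
#' decay-to-floor shape that reproduces the rise of technical noise at low
#' expression.
#'
#' @param n_features number of endogenous features (default 800, the size of
#'   the human mature-miRNA panel).
#' @param design an [build_design()] object; default the standard layout.
#' @param sigma_b,sigma_p,sigma_s,sigma_c,sigma_t effect standard deviations
#'   (log2 units) for biological sample, PrepStation, scanner, cartridge and
#'   scan time.
#' @param noise_a,noise_b,noise_tau residual-noise parameters: floor,
#'   low-expression amplitude, and decay constant (log2 units).
#' @param baseline_low,baseline_high range of the uniform per-feature
#'   baseline log2 expression.
#' @param seed integer seed; same (config, seed) gives bit-identical output.
#' @param control_spec list describing the control probes for count-level
#'   simulation: `n_positive`, `positive_top`, `positive_ratio` (geometric
#'   ladder of positive-control counts), `n_negative`, `negative_mean`
#'   (Poisson background), `n_housekeeping`, `hk_low`, `hk_high`
#'   (housekeeping baseline log2 range), `efficiency_sd` (log2 sd of the
#'   per-lane efficiency multiplier), `count_offset` (pseudo-count used in
#'   the count transform, matching the normalization `log_offset`).
#' @return A `"synthetic_config"` list.
#' @export
synthetic_config <- function(n_features = 800L,
                             design = build_design(),
                             sigma_b = 1, sigma_p = 0.02, sigma_s = 0.1,
                             sigma_c = 0.05, sigma_t = 0.02,
                             noise_a = 0.15, noise_b = 0.6, noise_tau = 2,
                             baseline_low = 1, baseline_high = 14,
                             seed = 1L,
                             control_spec = list()) {
  sig <- c(sigma_b = sigma_b, sigma_p = sigma_p, sigma_s = sigma_s,
           sigma_c = sigma_c, sigma_t = sigma_t)
  if (any(sig < 0))
    stop("validation error: effect standard deviations must be >= 0")
  if (noise_a <= 0)
    stop("validation error: noise_a (residual noise floor) must be > 0")
  if (baseline_low >= baseline_high)
    stop("validation error: baseline_low must be < baseline_high")
  if (n_features < 1) stop("validation error: n_features must be >= 1")
  stopifnot(inherits(design, "ncounter_design"))
  cs <- utils::modifyList(
    list(n_positive = 6L, positive_top = 8000, positive_ratio = 4,
         n_negative = 8L, negative_mean = 10,
         n_housekeeping = 10L, hk_low = 10, hk_high = 12,
         efficiency_sd = 0.1, count_offset = 1),
    control_spec
  )
  structure(
    list(n_features = as.integer(n_features), design = design,
         sigma_b = sigma_b, sigma_p = sigma_p, sigma_s = sigma_s,
         sigma_c = sigma_c, sigma_t = sigma_t,
         noise_a = noise_a, noise_b = noise_b, noise_tau = noise_tau,
         baseline_low = baseline_low, baseline_high = baseline_high,
         seed = as.integer(seed), control_spec = cs),
    class = "synthetic_config"
  )
}

noise_sd <- function(config, mu) {
  config$noise_a + config$noise_b * 2^(-mu / config$noise_tau)
}

## Evaluate expr with a local RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a log2 expression matrix with known variance components
#'
#' Draws the additive-effects model described in [synthetic_config()] on the
#' configured design and returns both the log2 matrix and the generating
#' truth (baselines and every effect draw) for recovery testing.
#'
#' @param config a [synthetic_config()].
#' @return A `"ncounter_sim"` list: `matrix` (an `ncounter_matrix`,
#'   `scale = "log2"`, endogenous features only) and `truth` (list with
#'   `baselines`, `sample_effects` [features x samples], `prep`, `scanner`,
#'   `scan_time` [per-feature vectors], `cartridge` [features x cartridges],
#'   and the `config` echo).
#' @examples
#' sim <- simulate_log2(synthetic_config(n_features = 20, seed = 7))
#' dim(sim$matrix)
#' @export
simulate_log2 <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, simulate_log2_impl(config))
}

simulate_log2_impl <- function(config) {
  G <- config$n_features
  obs <- config$design$obs
  n_obs <- nrow(obs)
  carts <- config$design$cartridges
  n_samp <- config$design$n_samples

  mu <- stats::runif(G, config$baseline_low, config$baseline_high)
  b <- matrix(stats::rnorm(G * n_samp, 0, config$sigma_b), G, n_samp)
  p <- stats::rnorm(G, 0, config$sigma_p)
  s <- stats::rnorm(G, 0, config$sigma_s)
  cc <- matrix(stats::rnorm(G * length(carts), 0, config$sigma_c),
               G, length(carts), dimnames = list(NULL, carts))
  tt <- stats::rnorm(G, 0, config$sigma_t)
  sde <- noise_sd(config, mu)

  values <- matrix(0, G, n_obs)
  for (j in seq_len(n_obs)) {
    values[, j] <- mu +
      b[, obs$sample[j]] +
      p * (obs$prep[j] == "second") +
      s * (obs$scanner[j] == "second") +
      cc[, obs$cartridge[j]] +
      tt * (obs$scan[j] == 2L) +
      stats::rnorm(G, 0, sde)
  }
  rownames(values) <- sprintf("mir-%04d", seq_len(G))

  mat <- ncounter_matrix(values,
                         obs[c("cartridge", "scan", "sample", "replicate")],
                         scale = "log2")
  structure(
    list(matrix = mat,
         truth = list(baselines = mu, sample_effects = b, prep = p,
                      scanner = s, cartridge = cc, scan_time = tt,
                      noise_sd = sde, config = config)),
    class = "ncounter_sim"
  )
}

#' Simulate raw RCC-style counts
#'
#' Count-level companion of [simulate_log2()]: endogenous counts are
#' `round(pmax(2^y - count_offset, 0) * efficiency)` with a log-normal
#' per-lane efficiency multiplier; positive controls follow a 6-step
#' geometric ladder scaled by the same lane efficiency; negatives are
#' Poisson around the configured background mean; housekeeping probes are
#' high-expression features without sample effects. The endogenous log2
#' signal uses the same seed as [simulate_log2()], so the two are directly
#' comparable.
#'
#' @param config a [synthetic_config()].
#' @return A `"ncounter_sim_counts"` list: `lanes` (list of
#'   `"lane_record"`), `log2` (the underlying [simulate_log2()] result) and
#'   `efficiency` (per lane-scan observation multipliers).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  sim <- simulate_log2(config)
  with_seed(config$seed + 1000003L, simulate_counts_impl(config, sim))
}

simulate_counts_impl <- function(config, sim) {
  cs <- config$control_spec
  obs <- config$design$obs
  n_obs <- nrow(obs)
  y <- sim$matrix$values

  eff <- 2^stats::rnorm(n_obs, 0, cs$efficiency_sd)
  ladder <- cs$positive_top / cs$positive_ratio^(seq_len(cs$n_positive) - 1)
  hk_mu <- stats::runif(cs$n_housekeeping, cs$hk_low, cs$hk_high)
  hk_sd <- noise_sd(config, hk_mu)

  lanes <- vector("list", n_obs)
  for (j in seq_len(n_obs)) {
    endo <- round(pmax(2^y[, j] - cs$count_offset, 0) * eff[j])
    pos <- round(ladder * eff[j])
    neg <- stats::rpois(cs$n_negative, cs$negative_mean)
    hk <- round(2^(hk_mu + stats::rnorm(cs$n_housekeeping, 0, hk_sd)) *
                  eff[j])
    probes <- data.frame(
      code_class = c(rep("Positive", cs$n_positive),
                     rep("Negative", cs$n_negative),
                     rep("Housekeeping", cs$n_housekeeping),
                     rep("Endogenous", nrow(y))),
      name = c(sprintf("POS_%s", LETTERS[seq_len(cs$n_positive)]),
               sprintf("NEG_%s", LETTERS[seq_len(cs$n_negative)]),
               sprintf("HK_%02d", seq_len(cs$n_housekeeping)),
               rownames(y)),
      accession = "synthetic",
      count = as.integer(c(pos, neg, hk, endo)),
      stringsAsFactors = FALSE
    )
    lanes[[j]] <- structure(
      list(lane_id = paste0(obs$lane_id[j], "_scan", obs$scan[j]),
           cartridge = obs$cartridge[j], scan = obs$scan[j],
           sample = obs$sample[j], replicate = obs$replicate[j],
           fov_count = obs$fov[j], probes = probes),
      class = "lane_record"
    )
  }
  structure(list(lanes = lanes, log2 = sim, efficiency = eff),
            class = "ncounter_sim_counts")
}

#' Write simulated lanes as an RCC fixture directory
#'
#' @param sim a `"ncounter_sim_counts"` from [simulate_counts()].
#' @param dir output directory (created if missing).
#' @return Character vector of written file paths, invisibly.
#' @export
write_rcc_dir <- function(sim, dir) {
  stopifnot(inherits(sim, "ncounter_sim_counts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(sim$lanes, function(l) {
    p <- file.path(dir, paste0(l$lane_id, ".RCC"))
    write_rcc(l, p)
    p
  }, "")
  invisible(paths)
}

#' Expected mean squares under the generating model
#'
#' Closed-form expectations of the per-feature ANOVA mean squares for the
#' standard design, averaged over the baseline distribution (the residual
#' variance depends on expression, so its mean over the uniform baseline
#' range is obtained by numerical integration). Under indicator effect
#' coding on the balanced layout the expectations are, with `s2` the mean
#' residual variance:
#' \itemize{
#'   \item first scan: `E[MS_P] = s2 + 12 (sigma_p^2 + sigma_c^2)`,
#'     `E[MS_S] = s2 + 12 (sigma_s^2 + sigma_c^2)`,
#'     `E[MS_B] = s2 + 8 sigma_b^2`, `E[MS_E] = s2 + 0.3 sigma_c^2`
#'     (at the first scan the four cartridges coincide with the four
#'     prep x scanner combinations, so cartridge effects load onto P, S and
#'     the 1-df interaction contrast inside the 40-df residual);
#'   \item second scan: `E[MS_PS] = s2 + 3 (sigma_p^2 + sigma_s^2) +
#'     12 sigma_c^2`, `E[MS_Cart] = s2 + 6 (sigma_p^2 + sigma_s^2) +
#'     12 sigma_c^2`, `E[MS_B] = s2 + 8 sigma_b^2`, `E[MS_E] = s2`;
#'   \item both scans (cartridges A and B): `E[MS_PS] = s2 +
#'     12 (sigma_p^2 + sigma_s^2 + 2 sigma_c^2)`,
#'     `E[MS_T] = s2 + 12 sigma_t^2`, `E[MS_B] = s2 + 8 sigma_b^2`,
#'     `E[MS_E] = s2`.
#' }
#' With `sigma_c = 0` these reduce to the familiar balanced-factor forms
#' (e.g. `E[MS_P] = s2 + 12 sigma_p^2` from 24 observations per prep level
#' in 48, and `E[MS_B] = s2 + 8 sigma_b^2` from 8 per sample).
#'
#' @param config a [synthetic_config()] using the standard design.
#' @param model `"scan1"`, `"scan2"` or `"both_scans"`.
#' @return Data frame with columns `source`, `df`, `expected_ms`,
#'   `expected_rms`.
#' @export
truth_rms <- function(config, model = c("scan1", "scan2", "both_scans")) {
  stopifnot(inherits(config, "synthetic_config"))
  model <- match.arg(model)
  d <- config$design
  if (!identical(d$cartridges, c("A", "B", "C", "D")) ||
      d$n_samples != 6L || d$n_replicates != 2L || d$scans != 2L ||
      !identical(unname(d$prep), c("second", "first", "second", "first")) ||
      !identical(unname(d$scanner), c("second", "first", "first", "second")))
    stop("unsupported design: truth_rms covers only the standard ",
         "4-cartridge layout")
  s2 <- mean_noise_var(config)
  vp <- config$sigma_p^2; vs <- config$sigma_s^2
  vb <- config$sigma_b^2; vc <- config$sigma_c^2; vt <- config$sigma_t^2
  tab <- switch(model,
    scan1 = data.frame(
      source = c("P", "S", "B", "residual"),
      df = c(1, 1, 5, 40),
      expected_ms = c(s2 + 12 * (vp + vc), s2 + 12 * (vs + vc),
                      s2 + 8 * vb, s2 + 0.3 * vc)),
    scan2 = data.frame(
      source = c("PS", "Cart", "B", "residual"),
      df = c(2, 1, 5, 39),
      expected_ms = c(s2 + 3 * (vp + vs) + 12 * vc,
                      s2 + 6 * (vp + vs) + 12 * vc,
                      s2 + 8 * vb, s2)),
    both_scans = data.frame(
      source = c("PS", "T", "B", "residual"),
      df = c(1, 1, 5, 40),
      expected_ms = c(s2 + 12 * (vp + vs + 2 * vc), s2 + 12 * vt,
                      s2 + 8 * vb, s2))
  )
  tab$expected_rms <- sqrt(tab$expected_ms)
  tab
}

## Mean of sigma_e(mu)^2 over mu ~ U[baseline_low, baseline_high]
mean_noise_var <- function(config) {
  stats::integrate(function(m) noise_sd(config, m)^2,
                   config$baseline_low, config$baseline_high,
                   rel.tol = 1e-10)$value /
    (config$baseline_high - config$baseline_low)
}
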
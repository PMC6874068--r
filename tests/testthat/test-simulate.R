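test_that("generator is deterministic in the seed and leaves the RNG alone", {
  cfg <- synthetic_config(n_features = 30, seed = 9)
  a <- simulate_log2(cfg)
  b <- simulate_log2(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth$sample_effects, b$truth$sample_effects)
  cfg2 <- synthetic_config(n_features = 30, seed = 10)
  expect_false(identical(a$matrix$values, simulate_log2(cfg2)$matrix$values))
  # caller's RNG stream is restored
  set.seed(77); before <- rnorm(3)
  set.seed(77); invisible(simulate_log2(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("degenerate all-zero-variance config collapses to the baselines", {
  cfg <- synthetic_config(n_features = 25, seed = 2,
                          sigma_b = 0, sigma_p = 0, sigma_s = 0,
                          sigma_c = 0, sigma_t = 0,
                          noise_a = 1e-6, noise_b = 0)
  sim <- simulate_log2(cfg)
  spread <- apply(sim$matrix$values, 1, function(r) max(abs(r - mean(r))))
  expect_lt(max(spread), 1e-4)
  expect_equal(unname(rowMeans(sim$matrix$values)),
               unname(sim$truth$baselines), tolerance = 1e-4)
})

test_that("sample-effect spread matches the generating sigma_b", {
  cfg <- synthetic_config(n_features = 800, seed = 3,
                          sigma_b = 1, sigma_p = 1e-3, sigma_s = 1e-3,
                          sigma_c = 1e-3, sigma_t = 1e-3,
                          noise_a = 0.05, noise_b = 0)
  sim <- simulate_log2(cfg)
  m <- sim$matrix
  # per-feature means over each sample's 16 observations
  sample_means <- vapply(1:6, function(s)
    rowMeans(m$values[, m$lanes$sample == s, drop = FALSE]),
    numeric(nrow(m$values)))
  # mean over features of the per-feature variance of the 6 sample means
  # estimates sigma_b^2 (plus a negligible noise share); its SE over 800
  # 5-df variance estimates is sigma_b^2 * sqrt(2 / 5 / 800)
  v <- mean(apply(sample_means, 1, var))
  se <- 1 * sqrt(2 / 5 / 800)
  expect_lt(abs(sqrt(v) - 1), 3 * se)
})

test_that("count companion inverts through the normalization module", {
  # lane efficiencies 2.0 vs 1.0: brighter lane gets the smaller factor
  vals <- rbind(c(50, 100), c(200, 400))
  x <- toy_count_matrix(vals, c("Positive", "Positive"))
  f <- positive_factors(x)
  expect_lt(f[2], f[1])

  cfg <- synthetic_config(n_features = 300, seed = 5)
  sim <- simulate_counts(cfg)
  counts <- lanes_to_matrix(sim$lanes)
  # positive ladder is deterministic: unit efficiency -> equal geomeans
  cfg0 <- synthetic_config(n_features = 10, seed = 5,
                           control_spec = list(efficiency_sd = 0))
  sim0 <- simulate_counts(cfg0)
  g <- vapply(sim0$lanes, function(l)
    exp(mean(log(l$probes$count[l$probes$code_class == "Positive"]))),
    numeric(1))
  expect_equal(diff(range(g)), 0)

  # full cycle: counts -> normalize -> log2 correlates with the generating
  # log2 signal per lane
  norm <- normalize_counts(counts, norm_config())
  endo <- norm[norm$features$code_class == "Endogenous", ]
  truth_mat <- sim$log2$matrix
  shared <- intersect(endo$features$name, truth_mat$features$name)
  key <- function(l) with(l, paste(cartridge, scan, sample, replicate))
  idx <- match(key(endo$lanes), key(truth_mat$lanes))
  pccs <- vapply(seq_len(ncol(endo$values)), function(j)
    cor(endo$values[shared, j], truth_mat$values[shared, idx[j]]),
    numeric(1))
  expect_gt(min(pccs), 0.99)
})

test_that("expected mean squares follow the closed-form layout", {
  # null model: all effect sigmas zero, constant residual sd 0.2
  cfg0 <- synthetic_config(sigma_b = 0, sigma_p = 0, sigma_s = 0,
                           sigma_c = 0, sigma_t = 0,
                           noise_a = 0.2, noise_b = 0, seed = 1)
  for (m in c("scan1", "scan2", "both_scans")) {
    tr <- truth_rms(cfg0, m)
    expect_equal(tr$expected_ms, rep(0.04, 4), tolerance = 1e-9)
  }
  # prep effect enters its own mean square with coefficient 12
  cfg1 <- synthetic_config(sigma_p = 0.5, sigma_b = 0, sigma_s = 0,
                           sigma_c = 0, sigma_t = 0,
                           noise_a = 0.2, noise_b = 0, seed = 1)
  tr1 <- truth_rms(cfg1, "scan1")
  expect_equal(tr1$expected_ms[tr1$source == "P"], 0.04 + 12 * 0.25)
  # biological mean square never drops below the residual expectation
  cfgb <- synthetic_config(sigma_b = 0.7, seed = 1)
  trb <- truth_rms(cfgb, "scan1")
  expect_gte(trb$expected_ms[trb$source == "B"],
             trb$expected_ms[trb$source == "residual"])
  expect_error(truth_rms(synthetic_config(design = build_design(
    prep = c(A = "first", B = "first", C = "second", D = "first"))),
    "scan1"), "unsupported design")
})

test_that("Monte-Carlo mean squares match truth_rms within 3 SE", {
  cfg <- synthetic_config(n_features = 5000, seed = 4,
                          sigma_b = 0.6, sigma_p = 0.3, sigma_s = 0.2,
                          sigma_c = 0.15, sigma_t = 0.1,
                          noise_a = 0.25, noise_b = 0)
  sim <- simulate_log2(cfg)
  for (m in c("scan1", "scan2", "both_scans")) {
    fit <- nano_vca(sim$matrix, m)
    tr <- truth_rms(cfg, m)
    for (i in seq_len(nrow(tr))) {
      src <- tr$source[i]
      got <- mean(fit$ms[, src])
      # MS is approximately a scaled chi-square with the term's df
      se <- tr$expected_ms[i] * sqrt(2 / tr$df[i] / cfg$n_features)
      expect_lt(abs(got - tr$expected_ms[i]), 3 * se,
                label = paste(m, src, "mean MS"))
    }
  }
})
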
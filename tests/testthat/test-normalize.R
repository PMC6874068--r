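test_that("positive-control factors scale lane geomeans to their mean", {
  # two lanes with positive geometric means 100 and 200 -> reference 150
  vals <- rbind(c(50, 100), c(200, 400))   # geomeans 100, 200
  x <- toy_count_matrix(vals, c("Positive", "Positive"))
  expect_equal(unname(positive_factors(x)), c(1.5, 0.75))

  # identical lanes -> all factors exactly 1
  x1 <- toy_count_matrix(rbind(c(80, 80), c(320, 320)),
                         c("Positive", "Positive"))
  expect_equal(unname(positive_factors(x1)), c(1, 1))

  # algebraic property: factor_l * geomean_l constant across lanes
  set.seed(501)
  for (i in 1:20) {
    K <- sample(3:8, 1)
    vals <- matrix(exp(rnorm(4 * K, 5, 1)), 4, K)
    x <- toy_count_matrix(vals, rep("Positive", 4),
                          lanes = data.frame(cartridge = "A", scan = 1L,
                                             sample = 1L,
                                             replicate = seq_len(K)))
    f <- positive_factors(x)
    g <- exp(colMeans(log(vals)))
    expect_equal(diff(range(f * g)), 0, tolerance = 1e-10)
  }

  # zero positive count -> geometric mean undefined
  xz <- toy_count_matrix(rbind(c(0, 10), c(5, 5)),
                         c("Positive", "Positive"))
  expect_error(positive_factors(xz), "geometric mean")
  # no positive probes at all
  xe <- toy_count_matrix(rbind(c(1, 2)), "Endogenous")
  expect_error(positive_factors(xe), "Positive")
})

test_that("background threshold is mean + k_sd * sd of negatives per lane", {
  vals <- rbind(c(10, 10), c(12, 12), c(14, 14))
  x <- toy_count_matrix(vals, rep("Negative", 3))
  expect_equal(unname(background_thresholds(x, k_sd = 2)), c(16, 16))
  expect_equal(unname(background_thresholds(x, k_sd = 0)), c(12, 12))
  # zero variance negatives -> threshold equals the common value
  x5 <- toy_count_matrix(rbind(c(5, 5), c(5, 5), c(5, 5)),
                         rep("Negative", 3))
  expect_equal(unname(background_thresholds(x5, 7)), c(5, 5))
  # fewer than 2 negatives: sd undefined
  x1 <- toy_count_matrix(rbind(c(5, 5)), "Negative")
  expect_error(background_thresholds(x1), "Negative")
})

test_that("background filtering applies the three keep rules correctly", {
  lanes4 <- data.frame(cartridge = "A", scan = 1L, sample = 1L,
                       replicate = 1:4)
  vals <- rbind(c(100, 100, 100, 100),   # above everywhere
                c(1, 1, 1, 1),           # below everywhere
                c(100, 100, 1, 1),       # above in exactly 2 of 4
                c(50, 50, 50, 50),       # negative control rows
                c(60, 60, 60, 60))
  x <- toy_count_matrix(vals, c("Endogenous", "Endogenous", "Endogenous",
                                "Negative", "Negative"), lanes = lanes4)
  thr <- rep(10, 4)
  kept <- function(rule)
    filter_background(x, thr, rule)$features$name
  n <- x$features$name
  expect_setequal(kept("majority_lanes"), n[c(1, 3, 4, 5)])
  expect_setequal(kept("any_lane"), n[c(1, 3, 4, 5)])
  expect_setequal(kept("all_lanes"), n[c(1, 4, 5)])
  # control probes always retained even below threshold
  thr_hi <- rep(1000, 4)
  expect_setequal(kept <- filter_background(x, thr_hi,
                                            "any_lane")$features$name,
                  n[4:5])
  expect_error(filter_background(x, thr[1:2]), "every lane")
})

test_that("filtering is monotone in k_sd", {
  sim <- simulate_counts(synthetic_config(n_features = 100, seed = 31))
  x <- lanes_to_matrix(sim$lanes)
  kept_at <- function(k) {
    thr <- background_thresholds(x, k)
    filter_background(x, thr, "majority_lanes")$features$name
  }
  ks <- c(0, 1, 2, 4)
  keeps <- lapply(ks, kept_at)
  for (i in seq_len(length(ks) - 1))
    expect_true(all(keeps[[i + 1]] %in% keeps[[i]]))
})

test_that("housekeeping factors scale lane medians to their mean", {
  vals <- rbind(c(40, 90), c(50, 100), c(60, 110))  # medians 50, 100
  x <- toy_count_matrix(vals, rep("Housekeeping", 3))
  expect_equal(unname(housekeeping_factors(x)), c(1.5, 0.75))
  x1 <- toy_count_matrix(rbind(c(50, 50)), "Housekeeping")
  expect_equal(unname(housekeeping_factors(x1)), c(1, 1))

  # scaling one lane's counts by c scales its factor by ~1/c
  set.seed(502)
  for (i in 1:10) {
    vals <- matrix(exp(rnorm(5 * 3, 5, 0.5)), 5, 3)
    cc <- runif(1, 0.5, 2)
    x <- toy_count_matrix(vals, rep("Housekeeping", 5),
                          lanes = data.frame(cartridge = "A", scan = 1L,
                                             sample = 1L, replicate = 1:3))
    scaled <- vals
    scaled[, 2] <- scaled[, 2] * cc
    xs <- toy_count_matrix(scaled, rep("Housekeeping", 5),
                           lanes = x$lanes)
    f <- housekeeping_factors(x)
    fs <- housekeeping_factors(xs)
    # ratio to lane 1 isolates the per-lane median scaling
    expect_equal((fs[2] / fs[1]) / (f[2] / f[1]), 1 / cc,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_error(housekeeping_factors(
    toy_count_matrix(rbind(c(1, 2)), "Endogenous")), "Housekeeping")
})

test_that("full normalization matches a hand-traced toy pipeline", {
  # Two lanes; positives geomeans 100/200 -> factors 1.5/0.75.
  # After positive correction both lanes carry identical counts, so
  # thresholds and housekeeping factors equalise and the log2 output is
  # log2(count * f + 1).
  vals <- rbind(c(50, 100), c(200, 400),        # positive (geomean 100/200)
                c(8, 16), c(10, 20), c(12, 24), # negatives
                c(500, 1000),                   # housekeeping
                c(300, 600),                    # endogenous, above bg
                c(4, 8))                        # endogenous, below bg
  cls <- c("Positive", "Positive", "Negative", "Negative", "Negative",
           "Housekeeping", "Endogenous", "Endogenous")
  x <- toy_count_matrix(vals, cls)
  out <- normalize_counts(x, norm_config(k_sd = 2, log_offset = 1))
  rep <- attr(out, "norm_report")
  expect_equal(unname(rep$positive_factor), c(1.5, 0.75))
  # corrected negatives are (12,15,18) in both lanes: mean 15, sd 3 -> 21
  expect_equal(unname(rep$background_threshold), c(21, 21))
  # corrected counts identical across lanes -> housekeeping factors 1
  expect_equal(unname(rep$housekeeping_factor), c(1, 1))
  # endogenous below background in both lanes is removed
  expect_equal(rep$removed, x$features$name[8])
  # hand-computed log2 values: corrected endogenous = 450 in both lanes
  expect_equal(unname(out$values[out$features$code_class == "Endogenous", ]),
               c(log2(451), log2(451)))
  expect_equal(out$scale, "log2")

  # identical lanes, all features above background -> log2(count + 1)
  vals2 <- rbind(c(100, 100), c(25, 25), c(10, 10), c(12, 12),
                 c(500, 500), c(300, 300))
  cls2 <- c("Positive", "Positive", "Negative", "Negative",
            "Housekeeping", "Endogenous")
  out2 <- normalize_counts(toy_count_matrix(vals2, cls2), norm_config())
  expect_equal(unname(out2$values), log2(vals2 + 1)[c(1:6), ])
})

test_that("lane factors depend only on relative lane differences", {
  sim <- simulate_counts(synthetic_config(n_features = 40, seed = 32))
  x <- lanes_to_matrix(sim$lanes)
  doubled <- x
  doubled$values <- x$values * 2
  expect_equal(positive_factors(doubled), positive_factors(x))
  expect_equal(housekeeping_factors(doubled), housekeeping_factors(x))
})

test_that("normalizing technically-clean data leaves only residual noise", {
  # baselines start at 5 log2 units so count rounding does not add
  # quantization noise on top of the generating residual
  cfg <- synthetic_config(n_features = 120, seed = 33,
                          sigma_p = 0, sigma_s = 0, sigma_c = 0,
                          sigma_t = 0, noise_b = 0, noise_a = 0.1,
                          baseline_low = 5,
                          control_spec = list(efficiency_sd = 0.2))
  sim <- simulate_counts(cfg)
  norm <- normalize_counts(lanes_to_matrix(sim$lanes), norm_config())
  endo <- norm[norm$features$code_class == "Endogenous", ]
  # per-sample replicate disagreement within a cartridge-scan
  l <- endo$lanes
  diffs <- unlist(lapply(split(seq_len(nrow(l)),
                               paste(l$cartridge, l$scan, l$sample)),
                         function(ix) endo$values[, ix[1]] - endo$values[, ix[2]]))
  # sd of a replicate difference is sqrt(2) * sigma_e; count rounding and
  # imperfect factor estimation add a little on top
  expect_lt(sd(diffs), sqrt(2) * 0.1 * 1.5)
  expect_gt(sd(diffs), sqrt(2) * 0.1 * 0.5)
})
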
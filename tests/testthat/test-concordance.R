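test_that("lane correlations honour identity and anti-correlation", {
  vals <- rbind(c(1, 1, 3), c(2, 2, 2.5), c(3, 3, 1))
  lanes <- data.frame(cartridge = c("A", "B", "B"), scan = 1L,
                      sample = 1L, replicate = c(1L, 1L, 2L))
  x <- ncounter_matrix(vals, lanes, scale = "log2")
  # identical copy of a lane -> pcc exactly 1
  self <- pcc_range(pairwise_pcc(x[, c(1, 2)], c("A", "B")))
  expect_equal(unname(self), c(1, 1))
  # exact anti-correlation: (1,2,3) vs (3,2.5,1) is not exactly -1; use
  # a strictly reversed column
  vals2 <- cbind(c(1, 2, 3), c(3, 2, 1))
  x2 <- ncounter_matrix(vals2, lanes[c(1, 2), ], scale = "log2")
  expect_equal(unname(pairwise_pcc(x2, c("A", "B"))$pcc), -1)
})

test_that("pairwise tables carry 12 matched rows on the standard design", {
  sim <- simulate_log2(synthetic_config(n_features = 120, seed = 41))
  x <- sim$matrix
  for (pr in list(c("A", "B"), c("C", "D"))) {
    tab <- pairwise_pcc(x, pr, scan = 1L)
    expect_equal(nrow(tab), 12L)
    expect_true(all(tab$n_features == 120L))
    expect_true(all(tab$pcc >= -1 & tab$pcc <= 1))
    expect_false(anyDuplicated(paste(tab$sample, tab$replicate)) > 0)
  }
  tabA <- scanpair_pcc(x, "A")
  expect_equal(nrow(tabA), 12L)
  # range extrema are attained by table entries
  r <- pcc_range(tabA)
  expect_lte(r[["min"]], r[["max"]])
  expect_true(all(c(r[["min"]], r[["max"]]) %in% tabA$pcc))
  expect_error(pcc_range(tabA[0, ]), "empty")
})

test_that("pcc is symmetric and invariant to positive affine transforms", {
  sim <- simulate_log2(synthetic_config(n_features = 60, seed = 42))
  x <- sim$matrix
  ab <- pairwise_pcc(x, c("A", "B"))
  ba <- pairwise_pcc(x, c("B", "A"))
  expect_equal(ab$pcc, ba$pcc, tolerance = 1e-12)
  # scale + shift one cartridge's lanes with positive slope
  y <- x
  ia <- which(y$lanes$cartridge == "A")
  y$values[, ia] <- 3.2 * y$values[, ia] + 5
  expect_equal(pairwise_pcc(y, c("A", "B"))$pcc, ab$pcc,
               tolerance = 1e-12)
})

test_that("cross-scan concordance is near-perfect without scan effects", {
  cfg <- synthetic_config(n_features = 800, seed = 43, sigma_t = 0)
  x <- simulate_log2(cfg)$matrix
  for (cart in c("A", "B"))
    expect_gt(pcc_range(scanpair_pcc(x, cart))[["min"]], 0.99)
})

test_that("concordance pairing and degeneracy errors are explicit", {
  sim <- simulate_log2(synthetic_config(n_features = 10, seed = 44))
  x <- sim$matrix
  noA2 <- x[, !(x$lanes$cartridge == "A" & x$lanes$scan == 2L)]
  expect_error(scanpair_pcc(noA2, "A"), "pairing error")
  dropped <- x[, -which(x$lanes$cartridge == "A" & x$lanes$sample == 3 &
                          x$lanes$replicate == 1 & x$lanes$scan == 1)[1]]
  expect_error(pairwise_pcc(dropped, c("A", "B")), "pairing error")
  flat <- ncounter_matrix(cbind(c(5, 5, 5), c(1, 2, 3)),
                          data.frame(cartridge = c("A", "B"), scan = 1L,
                                     sample = 1L, replicate = 1L),
                          scale = "log2")
  expect_error(pairwise_pcc(flat, c("A", "B")), "zero-variance")
})

test_that("clustering separates constructed sample groups", {
  # two sample groups 4 log2 units apart must split at the top of the
  # column dendrogram
  d <- build_design()
  ann <- d$obs[d$obs$scan == 1L & d$obs$cartridge %in% c("A", "B"), ]
  set.seed(45)
  G <- 40
  base <- matrix(rnorm(G * nrow(ann), 8, 0.1), G, nrow(ann))
  shift <- ifelse(ann$sample <= 3, 0, 4)
  vals <- base + matrix(shift, G, nrow(ann), byrow = TRUE)
  x <- ncounter_matrix(vals, ann[c("cartridge", "scan", "sample",
                                   "replicate")], scale = "log2")
  res <- cluster_heatmap(x)
  top_split <- stats::cutree(res$col_hclust, k = 2)
  expect_equal(length(unique(top_split[ann$sample <= 3])), 1L)
  expect_equal(length(unique(top_split[ann$sample > 3])), 1L)
  expect_false(top_split[ann$sample <= 3][1] == top_split[ann$sample > 3][1])
  # merge heights are non-decreasing and orders are permutations
  expect_true(!is.unsorted(res$col_heights))
  expect_setequal(res$col_order, seq_len(nrow(ann)))
  expect_setequal(res$row_order, seq_len(G))
})

test_that("technical replicates are mutual nearest neighbours", {
  sim <- simulate_log2(synthetic_config(n_features = 300, seed = 46))
  x <- sim$matrix
  s1 <- x[, x$lanes$scan == 1L & x$lanes$cartridge == "A"]
  D <- as.matrix(dist(t(s1$values)))
  diag(D) <- Inf
  nn <- apply(D, 1, which.min)
  for (i in seq_len(ncol(s1$values))) {
    expect_equal(s1$lanes$sample[nn[i]], s1$lanes$sample[i])
    expect_equal(unname(nn[nn[i]]), i)
  }
})

test_that("column partition is invariant to input lane order", {
  sim <- simulate_log2(synthetic_config(n_features = 80, seed = 47))
  x <- sim$matrix[, 1:24]
  res1 <- cluster_heatmap(x)
  set.seed(48)
  perm <- sample(24)
  res2 <- cluster_heatmap(x[, perm])
  p1 <- stats::cutree(res1$col_hclust, k = 6)
  p2 <- stats::cutree(res2$col_hclust, k = 6)[order(perm)]
  # same partition up to label renaming
  expect_equal(length(unique(paste(p1, p2))), 6L)
  # degenerate identical matrix still clusters, with zero heights
  flat <- ncounter_matrix(matrix(2, 5, 4),
                          data.frame(cartridge = "A", scan = 1L,
                                     sample = 1L, replicate = 1:4),
                          scale = "log2")
  resf <- cluster_heatmap(flat)
  expect_equal(max(resf$col_heights), 0)
})
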
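# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# Small count matrix with all probe classes on a minimal 2-lane "design"
# (one cartridge, one sample in duplicate) for normalization unit tests.
toy_count_matrix <- function(values, code_class,
                             lanes = data.frame(cartridge = "A", scan = 1L,
                                                sample = 1L,
                                                replicate = seq_len(ncol(values)))) {
  ncounter_matrix(values, lanes, code_class = code_class,
                  scale = "linear_counts")
}

# A random lane_record for RCC round-trip property tests.
random_lane_record <- function(n_probes = 10) {
  classes <- sample(c("Endogenous", "Positive", "Negative", "Housekeeping"),
                    n_probes, replace = TRUE)
  structure(
    list(lane_id = paste0("L", sample.int(999, 1)),
         cartridge = sample(LETTERS[1:4], 1),
         scan = sample(1:2, 1), sample = sample(1:6, 1),
         replicate = sample(1:2, 1),
         fov_count = sample(c(320L, 600L), 1),
         probes = data.frame(
           code_class = classes,
           name = sprintf("probe_%03d", seq_len(n_probes)),
           accession = sprintf("ACC%03d", seq_len(n_probes)),
           count = sample.int(5000, n_probes) - 1L,
           stringsAsFactors = FALSE)),
    class = "lane_record")
}

# Independent sequential-SS oracle: per-feature stats::lm + anova() Type I
# sums of squares with the same factor coding as the fitted model.
oracle_anova_ss <- function(values, ann, model) {
  ann$P <- factor(ann$prep)
  ann$S <- factor(ann$scanner)
  ann$B <- factor(ann$sample)
  ann$Tm <- factor(ann$scan)
  ann$PS3 <- factor(ifelse(ann$prep == ann$scanner,
                           paste0("both_", ann$prep), "mixed"))
  ann$CartC <- (ann$cartridge == "C") - (ann$cartridge == "D")
  ann$AB <- factor(ann$cartridge)
  ann$y <- values
  form <- switch(model,
    scan1 = y ~ P + S + B,
    scan2 = y ~ PS3 + CartC + B,
    both_scans = y ~ AB + Tm + B)
  a <- stats::anova(stats::lm(form, data = ann))
  ss <- a[["Sum Sq"]]
  names(ss) <- rownames(a)
  names(ss)[names(ss) == "Residuals"] <- "residual"
  ss
}

# Observations + annotations for one model on the standard design.
model_obs <- function(model) {
  d <- build_design()
  ann <- d$obs
  keep <- switch(model,
    scan1 = ann$scan == 1L,
    scan2 = ann$scan == 2L,
    both_scans = ann$cartridge %in% c("A", "B"))
  ann[keep, , drop = FALSE]
}

# Log2 matrix over the full design from a features x 96 value matrix.
design_matrix <- function(values) {
  ncounter_matrix(values,
                  build_design()$obs[c("cartridge", "scan", "sample",
                                       "replicate")],
                  scale = "log2")
}

# Normal-equations LOESS oracle, independent of loess_smooth's lm.wfit
# route: explicit tricube weights and solve(t(X) W X) at each query point.
oracle_loess <- function(x, y, span, degree, x0) {
  n <- length(x)
  q <- ceiling(span * n)
  d <- abs(x - x0)
  idx <- order(d)[seq_len(q)]
  dmax <- d[idx[q]]
  w <- if (dmax <= 0) rep(1, q) else (1 - pmin(d[idx] / dmax, 1)^3)^3
  keep <- w > 0
  xi <- x[idx][keep] - x0
  X <- outer(xi, 0:degree, `^`)
  W <- diag(w[keep], nrow = length(xi))
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y[idx][keep])
  beta[1]
}
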
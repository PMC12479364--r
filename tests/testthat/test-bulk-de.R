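make_counts <- function(G = 50, n = 6, seed = 1, lambda = 100) {
  set.seed(seed)
  m <- matrix(rnbinom(G * n, mu = rexp(G, 1 / lambda), size = 10), G, n,
              dimnames = list(sprintf("g%03d", 1:G), paste0("s", 1:n)))
  storage.mode(m) <- "integer"
  m
}

test_that("technical replicate summing adds runs and keeps singletons", {
  m <- make_counts(20, 4)
  runs <- cbind(m, m)
  colnames(runs) <- c(paste0(colnames(m), "_run1"), paste0(colnames(m), "_run2"))
  doubled <- sum_technical_replicates(runs, rep(colnames(m), 2))
  expect_identical(unname(doubled), unname(m + m))
  expect_identical(sum_technical_replicates(m, colnames(m)), m)
  expect_error(sum_technical_replicates(m, c("a", "b")), "length")
})

test_that("library-size filter drops strictly-below samples only", {
  m <- matrix(0L, 2, 2, dimnames = list(c("g1", "g2"), c("big", "small")))
  m[, 1] <- c(6e5L, 6e5L)   # 1.2e6
  m[, 2] <- c(5e5L, 4e5L)   # 9e5
  out <- filter_samples_by_library_size(m)
  expect_identical(colnames(out), "big")
  expect_identical(attr(out, "dropped_samples"), "small")

  exact <- matrix(c(5e5L, 5e5L), 2, 1, dimnames = list(c("g1", "g2"), "edge"))
  expect_identical(ncol(filter_samples_by_library_size(exact)), 1L)  # == 1e6 kept
  expect_identical(ncol(filter_samples_by_library_size(m, min_reads = 0)), 2L)
  expect_error(filter_samples_by_library_size(m, min_reads = 1e9), "all samples")
})

test_that("low-expression filter applies the CPM-in-k-samples and total rules", {
  # 4 samples with 1e6 libraries, groups of 2: CPM == count here
  libfill <- function(counts) {
    extra <- 1e6 - colSums(counts)
    rbind(counts, filler = as.integer(extra))
  }
  m <- libfill(matrix(c(12L, 12L, 0L, 0L,
                        3L, 3L, 3L, 3L,
                        0L, 0L, 0L, 0L,
                        7L, 7L, 0L, 0L), 4, 4, byrow = TRUE,
                      dimnames = list(paste0("g", 1:4), paste0("s", 1:4))))
  out <- filter_low_expression(m, c("A", "A", "B", "B"))
  expect_true("g1" %in% rownames(out))        # CPM 12 in 2 samples, total 24
  expect_false("g2" %in% rownames(out))       # total 12 < 15
  expect_false("g3" %in% rownames(out))       # all zero
  expect_false("g4" %in% rownames(out))       # CPM 7 < 10
  expect_error(filter_low_expression(m, c("A", "A")), "length")
})

test_that("TMM factors are 1 for identical and exactly scaled columns", {
  m <- make_counts(100, 2)
  same <- cbind(a = m[, 1], b = m[, 1])
  expect_equal(as.numeric(tmm_factors(same)), c(1, 1))
  scaled <- cbind(a = m[, 1], b = 3L * m[, 1])
  expect_equal(as.numeric(tmm_factors(scaled)), c(1, 1))
  zero <- cbind(a = c(1L, 0L), b = c(0L, 5L))
  rownames(zero) <- c("g1", "g2")
  expect_error(tmm_factors(zero), "no positive genes")
})

test_that("TMM factors match the loop-based formula oracle to 1e-12", {
  for (seed in 1:25) {
    m <- make_counts(50, 6, seed = seed, lambda = 50 + 10 * seed)
    expect_equal(as.numeric(tmm_factors(m)), oracle_tmm_factors(m),
                 tolerance = 1e-12)
  }
})

test_that("TMM factors track edgeR's implementation closely", {
  for (seed in 1:5) {
    m <- make_counts(200, 6, seed = seed, lambda = 200)
    ours <- as.numeric(tmm_factors(m))
    theirs <- as.numeric(edgeR::calcNormFactors(m, method = "TMM"))
    expect_equal(ours, theirs, tolerance = 0.02)
  }
})

test_that("log-CPM follows its closed form and scale invariances", {
  y <- matrix(0L, 1, 1, dimnames = list("g", "s"))
  fake_lib <- rbind(y, lib = 1000000L)
  lc <- log_cpm(fake_lib, prior = 0.5)
  expect_equal(lc["g", "s"], log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)

  m <- make_counts(30, 3)
  lc1 <- log_cpm(m, prior = 0)
  lc2 <- log_cpm(2L * m, prior = 0)
  expect_equal(lc1, lc2, tolerance = 1e-12)

  # y = L * 1e-6 * 2^k with prior 0 gives exactly k
  k <- 3
  mm <- matrix(c(as.integer(8 * 2^k), as.integer(1e6 - 8 * 2^k)), 2, 1,
               dimnames = list(c("g", "rest"), "s"))
  expect_equal(log_cpm(mm * 0 + mm, prior = 0)["g", "s"],
               log2(8 * 2^k), tolerance = 1e-12)
})

test_that("precision weights are positive and track the mean-variance trend", {
  set.seed(5)
  n <- 12; G <- 300
  design <- cbind(1, rep(0:1, each = n / 2))
  # homoskedastic gaussian data: weights should be nearly flat
  flat <- matrix(rnorm(G * n, 8, 1), G, n,
                 dimnames = list(paste0("g", 1:G), paste0("s", 1:n)))
  w <- mean_variance_weights(flat, design)
  expect_true(all(w > 0))
  expect_lt(max(w) / min(w), 2)

  # counts: variance decreasing in mean on the log scale, so weights rise
  # with expression
  mu <- rexp(G, 1 / 200)
  counts <- matrix(rnbinom(G * n, mu = mu, size = 5), G, n,
                   dimnames = dimnames(flat))
  counts <- counts[rowSums(counts) > 0, ]
  lc <- log_cpm(counts)
  w2 <- mean_variance_weights(lc, design[seq_len(ncol(lc)), ])
  rho <- cor(rowMeans(lc), rowMeans(w2), method = "spearman")
  expect_gt(rho, 0)
})

test_that("variance moderation follows the convex-combination formula", {
  # direct formula evaluation: s^2 = 1, d = 4, d0 = 4, s0^2 = 2
  s2_post <- (4 * 2 + 4 * 1) / (4 + 4)
  expect_equal(s2_post, 1.5)

  set.seed(9)
  G <- 200; n <- 8
  design <- cbind(1, rep(0:1, each = 4))
  y <- matrix(rnorm(G * n, 5, 1), G, n,
              dimnames = list(paste0("g", 1:G), paste0("s", 1:n)))
  fits <- fit_and_moderate(y, design = design)
  expect_true(all(fits$s2_post >= pmin(fits$sigma2, fits$s02) - 1e-12))
  expect_true(all(fits$s2_post <= pmax(fits$sigma2, fits$s02) + 1e-12))
  expect_equal(fits$df_residual, n - 2)

  # identical variances: the prior matches and shrinkage changes nothing
  y_const_var <- matrix(rnorm(G * n), G, n, dimnames = dimnames(y))
  fc <- fit_and_moderate(y_const_var, design = design)
  expect_equal(fc$s02, mean(fc$sigma2), tolerance = 0.2)
})

test_that("forcing d0 = 0 reduces the moderated t to the ordinary t", {
  set.seed(10)
  G <- 100; n <- 8
  design <- cbind(intercept = 1, grp = rep(0:1, each = 4))
  y <- matrix(rnorm(G * n, 5, rexp(G) + 0.5), G, n,
              dimnames = list(paste0("g", 1:G), paste0("s", 1:n)))
  fits0 <- fit_and_moderate(y, design = design, d0 = 0)
  res <- treat_test(fits0, "grp", fc_threshold = 1)
  # ordinary per-gene t-test via lm
  for (g in c(1, 17, 58)) {
    lmres <- summary(lm(y[g, ] ~ design[, 2]))$coefficients
    expect_equal(unname(res$t[g]), unname(lmres[2, "t value"]), tolerance = 1e-8)
    expect_equal(unname(res$P.Value[g]), unname(lmres[2, "Pr(>|t|)"]), tolerance = 1e-8)
  }
})

test_that("hyperparameter estimation agrees with limma::squeezeVar", {
  set.seed(11)
  G <- 500; df <- 4
  s2 <- rchisq(G, df) / df * rf(G, 8, 8)
  sq <- limma::squeezeVar(s2, df)
  ours <- tfhsig:::.fit_fdist(s2, df)
  expect_equal(ours$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(ours$s02, sq$var.prior, tolerance = 1e-6)
  post <- (ours$d0 * ours$s02 + df * s2) / (ours$d0 + df)
  expect_equal(post, sq$var.post, tolerance = 1e-6)
})

test_that("the whole moderated TREAT pipeline matches limma on shared inputs", {
  set.seed(12)
  G <- 300; n <- 10
  design <- cbind(intercept = 1, grp = rep(0:1, each = 5))
  y <- matrix(rnorm(G * n, 6, sqrt(rf(G, 10, 10))), G, n,
              dimnames = list(paste0("g", 1:G), paste0("s", 1:n)))
  w <- matrix(rexp(G * n) + 0.5, G, n)
  ours <- treat_test(
    fit_and_moderate(y, w, design,
                     contrasts = matrix(c(0, 1), 2, dimnames = list(NULL, "grp"))),
    "grp", fc_threshold = 1.1)
  lfit <- limma::lmFit(y, design, weights = w)
  lres <- limma::treat(lfit, fc = 1.1)
  expect_equal(ours$logFC, unname(lres$coefficients[, "grp"]), tolerance = 1e-8)
  expect_equal(ours$P.Value, unname(lres$p.value[, "grp"]), tolerance = 1e-6)
})

test_that("TREAT reduces to the moderated t at threshold 1 and respects the boundary", {
  set.seed(13)
  G <- 200; n <- 8
  design <- cbind(1, rep(0:1, each = 4))
  y <- matrix(rnorm(G * n, 5, 1), G, n,
              dimnames = list(paste0("g", 1:G), paste0("s", 1:n)))
  cm <- matrix(c(0, 1), 2, dimnames = list(NULL, "grp"))
  fits <- fit_and_moderate(y, design = design, contrasts = cm)
  r1 <- treat_test(fits, "grp", fc_threshold = 1)
  tt <- fits$effects[, 1] / (fits$stdev_unscaled[, 1] * sqrt(fits$s2_post))
  p_plain <- 2 * pt(-abs(tt), df = fits$df_residual + min(fits$d0, 1e6))
  expect_lt(max(abs(r1$P.Value - p_plain)), 1e-10)

  # |logFC| exactly at the threshold: p >= 0.5
  tau <- attr(treat_test(fits, "grp", fc_threshold = 1.2), "tau")
  se <- fits$stdev_unscaled[, 1] * sqrt(fits$s2_post)
  df_tot <- fits$df_residual + min(fits$d0, 1e6)
  p_boundary <- pt(0, df_tot, lower.tail = FALSE) +
    pt(2 * tau / se, df_tot, lower.tail = FALSE)
  expect_true(all(p_boundary >= 0.5))

  # monotone: p non-decreasing in tau at fixed estimate
  r2 <- treat_test(fits, "grp", fc_threshold = 1.3)
  expect_true(all(r2$P.Value >= r1$P.Value - 1e-12))
})

test_that("BH adjustment matches the hand-executed step-up procedure", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.37), 0.37)
  set.seed(14)
  p <- runif(50)
  q <- adjust_bh(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # same order as p up to ties
  expect_true(all(q >= p - 1e-15) && all(q <= 1))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("directional calls respect the inclusive FDR boundary", {
  res <- data.frame(gene = c("a", "b", "c"),
                    logFC = c(0.8, -0.5, 1.2),
                    adj.P.Val = c(0.01, 0.2, 0.05))
  d <- decide_directions(res, fdr = 0.05)
  expect_identical(unname(d), c(1L, 0L, 1L))
})

test_that("QC embeddings behave on duplicated and separated samples", {
  set.seed(15)
  G <- 200
  base <- rnorm(G, 6, 1)
  grpA <- sapply(1:3, function(i) base + rnorm(G, 0, 0.1))
  grpB <- sapply(1:3, function(i) base + c(rep(2, 50), rep(0, G - 50)) + rnorm(G, 0, 0.1))
  m <- cbind(grpA, grpB, grpA[, 1])
  dimnames(m) <- list(paste0("g", 1:G), paste0("s", 1:7))
  emb <- qc_embeddings(m)
  # duplicated sample (s7 == s1) maps to the same PCA point
  expect_equal(emb$pca_coords["s1", ], emb$pca_coords["s7", ], tolerance = 1e-8)
  # first axis separates the groups
  pc1 <- emb$pca_coords[1:6, 1]
  expect_true(max(pc1[1:3]) < min(pc1[4:6]) || min(pc1[1:3]) > max(pc1[4:6]))
  # RLE of identical columns is all zero
  same <- cbind(a = base, b = base, c = base)
  rownames(same) <- paste0("g", 1:G)
  expect_true(all(suppressWarnings(qc_embeddings(same, n_components = 1))$rle_matrix == 0))
})
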
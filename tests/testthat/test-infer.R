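test_that("pair correlations handle exact dependence, ranks and constants", {
  set.seed(1)
  x <- rnorm(50)
  X <- rbind(g1 = x, g2 = 2 * x, g3 = rnorm(50))
  r <- pair_correlations(X)
  expect_equal(r["g1", "g2"], 1)
  # Spearman is invariant under a monotone transform of one gene
  Xs <- rbind(g1 = x, g2 = exp(x))
  expect_equal(pair_correlations(Xs, method = "spearman")["g1", "g2"], 1)
  # independent noise at large n has small correlation
  set.seed(2)
  Xn <- rbind(a = rnorm(1000), b = rnorm(1000))
  expect_lt(abs(pair_correlations(Xn)["a", "b"]), 0.1)
  # constant gene: zeroed with a warning
  Xc <- rbind(g1 = x, g2 = rep(1, 50))
  expect_warning(rc <- pair_correlations(Xc), "constant")
  expect_equal(rc["g1", "g2"], 0)
  expect_error(pair_correlations(X, mask = 1:3), "at least 4")
})

test_that("z-score statistic matches the pooled Fisher-transform formula", {
  set.seed(11)
  n1 <- 60; n2 <- 40
  X <- rbind(g1 = rnorm(n1 + n2), g2 = rnorm(n1 + n2), g3 = rnorm(n1 + n2))
  X["g2", 1:n1] <- X["g1", 1:n1] * 0.8 + rnorm(n1, sd = 0.4)
  bits <- rep(c(0, 1), c(n1, n2))
  C <- matrix(bits, 1, dimnames = list("kd", NULL))
  tab <- zscore_dc(X, C)
  # independent recomputation from the two correlation matrices
  r1 <- cor(t(X[, bits == 0])); r2 <- cor(t(X[, bits == 1]))
  z12 <- (atanh(r1["g1", "g2"]) - atanh(r2["g1", "g2"])) /
    sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  row <- tab[tab$gene_a == "g1" & tab$gene_b == "g2", ]
  expect_equal(row$score, z12, tolerance = 1e-12)
  expect_equal(row$p, 2 * pnorm(-abs(z12)), tolerance = 1e-12)
  # swapping condition labels flips the sign but not the p-value
  tab2 <- zscore_dc(X, 1 - C)
  expect_equal(tab2$score, -tab$score, tolerance = 1e-12)
  expect_equal(tab2$p, tab$p, tolerance = 1e-12)
  # table structure: unordered pairs, no self-pairs, each pair once
  expect_false(any(tab$gene_a == tab$gene_b))
  expect_equal(anyDuplicated(dcbench:::pair_key(tab$gene_a, tab$gene_b)), 0)
  expect_true(all(tab$p_adj >= tab$p - 1e-15))
})

test_that("identical conditions give zero z-scores", {
  set.seed(13)
  X <- matrix(rnorm(5 * 80), 5, dimnames = list(paste0("g", 1:5), NULL))
  half <- rep(c(0, 1), 40)
  X[, half == 1] <- X[, half == 0]  # both states literally identical
  tab <- zscore_dc(X, matrix(half, 1))
  expect_true(all(abs(tab$score) < 1e-10))
  expect_true(all(tab$p > 1 - 1e-8))
})

test_that("z-score approaches the single-condition Fisher test in the degenerate limit", {
  set.seed(17)
  n1 <- 50; n2 <- 5000
  x1 <- rnorm(n1); y1 <- 0.7 * x1 + rnorm(n1, sd = 0.5)
  X <- rbind(g1 = c(x1, rnorm(n2)), g2 = c(y1, rnorm(n2)))
  bits <- rep(c(0, 1), c(n1, n2))
  tab <- zscore_dc(X, matrix(bits, 1))
  r1 <- cor(x1, y1)
  prill <- atanh(r1) * sqrt(n1 - 3)
  expect_equal(tab$score, prill, tolerance = 0.08)
})

test_that("DiffCoEx scores follow the soft-threshold correlation difference", {
  set.seed(19)
  x <- rnorm(60)
  X <- rbind(g1 = c(x, rnorm(60)), g2 = c(x, rnorm(60)), g3 = rnorm(120))
  bits <- rep(c(0, 1), each = 60)
  tab <- diffcoex_dc(X, matrix(bits, 1), beta_power = 6, n_perm = 2)
  r1 <- cor(t(X[, bits == 0])); r2 <- cor(t(X[, bits == 1]))
  expected <- (abs(sign(r1) * r1^2 - sign(r2) * r2^2) / 2)^3
  row <- tab[tab$gene_a == "g1" & tab$gene_b == "g2", ]
  expect_equal(row$score, expected["g1", "g2"], tolerance = 1e-12)
  # perfectly reversed correlation scores 1
  Xr <- rbind(a = c(x, x), b = c(x, -x))
  tabr <- diffcoex_dc(Xr, matrix(bits, 1), beta_power = 6, n_perm = 1)
  expect_equal(tabr$score, 1, tolerance = 1e-9)
  # equal correlations score 0
  Xe <- rbind(a = c(x, x), b = c(2 * x, 2 * x))
  tabe <- diffcoex_dc(Xe, matrix(bits, 1), beta_power = 6, n_perm = 1)
  expect_equal(tabe$score, 0, tolerance = 1e-12)
})

test_that("FTGI detects interactions and is calibrated under the null", {
  set.seed(23)
  n <- 200
  bits <- rep(c(0, 1), each = n / 2)
  # constructed strong interaction: slope +1 vs -1
  x <- rnorm(n)
  y <- ifelse(bits == 0, x, -x) + rnorm(n, sd = 0.1)
  X <- rbind(g1 = x, g2 = y)
  tab <- ftgi_dc(X, matrix(bits, 1))
  expect_lt(tab$p, 1e-6)
  # label swap leaves the statistic unchanged
  tab2 <- ftgi_dc(X, matrix(1 - bits, 1))
  expect_equal(tab2$score, tab$score, tolerance = 1e-9)
  # null calibration: same linear relation in both conditions. The
  # undirected pair score is the max over the two fit directions, so the
  # pair-level rate at alpha lies between alpha and 2*alpha; assert that
  # envelope (with a 99% binomial band) rather than exact uniformity.
  set.seed(29)
  ps <- replicate(400, {
    x <- rnorm(n)
    y <- x + rnorm(n)
    ftgi_dc(rbind(a = x, b = y), matrix(bits, 1))$p
  })
  frac <- mean(ps < 0.05)
  expect_gt(frac, 0.05 - 2.58 * sqrt(0.05 * 0.95 / 400))
  expect_lt(frac, 0.10 + 2.58 * sqrt(0.10 * 0.90 / 400))
})

test_that("MINDy scores mutual-information changes in bits", {
  set.seed(31)
  n <- 400
  bits <- rep(c(0, 1), each = n)
  # two equiprobable levels, perfectly coupled in state 1 only
  x0 <- rep(c(0, 1), n / 2); y0 <- sample(x0)
  x1 <- rep(c(0, 1), n / 2); y1 <- x1
  X <- rbind(g1 = c(x0, x1), g2 = c(y0, y1)) +
    matrix(rnorm(4 * n, sd = 1e-3), 2)
  tab <- mindy_dc(X, matrix(bits, 1), bins = 2, n_perm = 1)
  expect_equal(tab$score, 1, tolerance = 0.05)
  # independent identically-distributed genes score near zero
  Xi <- rbind(g1 = rnorm(2 * n), g2 = rnorm(2 * n))
  tabi <- mindy_dc(Xi, matrix(bits, 1), bins = 2, n_perm = 1)
  expect_lt(tabi$score, 0.05)
  expect_error(mindy_dc(Xi[, 1:40], matrix(bits[1:40], 1), bins = 8),
               "bins")
})

test_that("pooled permutation p-values count correctly and stay positive", {
  X <- matrix(rnorm(3 * 40), 3, dimnames = list(c("a", "b", "c"), NULL))
  bits <- rep(c(0, 1), each = 20)
  # a score function ignoring the data: observed 1, null always 0
  p <- permutation_test(function(X, b) {
    if (all(b == bits)) rep(1, 3) else rep(0, 3)
  }, X, bits, n_perm = 5)
  # 3 pairs x 5 permutations = 15 null values, none >= 1
  expect_equal(p, rep(1 / 16, 3))
  # observed equal to every null value: p = 1
  p2 <- permutation_test(function(X, b) rep(0.5, 3), X, bits, n_perm = 5)
  expect_equal(p2, rep(1, 3))
  expect_true(all(p > 0 & p <= 1))
})

test_that("BH adjustment and FDR thresholding behave as step-up control", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  p <- runif(20)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p - 1e-15))
  # thresholding is monotone in the cut-off
  tab <- data.frame(condition = "kd", gene_a = letters[1:5],
                    gene_b = LETTERS[1:5], score = 1:5,
                    p = c(0.001, 0.02, 0.2, 0.5, 0.9))
  tab$p_adj <- bh_adjust(tab$p)
  n05 <- threshold_network(tab, 0.05)[["kd"]]
  n10 <- threshold_network(tab, 0.1)[["kd"]]
  expect_true(all(paste(n05[, 1], n05[, 2]) %in% paste(n10[, 1], n10[, 2])))
  expect_equal(nrow(threshold_network(tab, 1)[["kd"]]), 5)
  tab$p_adj <- 1
  expect_equal(nrow(threshold_network(tab, 0.1)[["kd"]]), 0)
})

test_that("co-expression difference baselines return symmetric differences", {
  set.seed(37)
  x <- rnorm(100)
  # identical data in both states: empty differential network
  X <- rbind(g1 = c(x, x), g2 = c(2 * x, 2 * x), g3 = rnorm(200))
  bits <- rep(c(0, 1), each = 100)
  for (fl in c("wgcna", "prill-z")) {
    # the g1/g2 fixture correlation is exactly 1, so the Fisher transform
    # emits its clamping warning by design
    net <- suppressWarnings(
      coexpression_difference_baseline(X, matrix(bits, 1), fl))
    expect_equal(nrow(net[[1]]), 0)
  }
  # edge present in one state only is reported
  y0 <- x + rnorm(100, sd = 0.1)
  X2 <- rbind(g1 = c(x, rnorm(100)), g2 = c(y0, rnorm(100)))
  net2 <- coexpression_difference_baseline(X2, matrix(bits, 1), "wgcna")
  expect_equal(nrow(net2[[1]]), 1)
  # |r| = 0.7 at power 6 gives weight 0.117649 > 0.05: retained
  expect_gt(0.7^6, 0.05)
  # ... while |r| = 0.6 gives 0.046656 < 0.05: dropped
  expect_lt(0.6^6, 0.05)
})

test_that("driver-associated genes are filtered by absolute correlation", {
  set.seed(41)
  d <- rnorm(80)
  X <- rbind(driver = d, hit = -d + rnorm(80, sd = 0.1),
             free = rnorm(80))
  X2 <- filter_condition_associated(X, "driver", 0.5)
  expect_false("driver" %in% rownames(X2))
  expect_false("hit" %in% rownames(X2))
  expect_true("free" %in% rownames(X2))
  # threshold 1 removes only perfect correlation (the driver itself)
  X3 <- filter_condition_associated(X, "driver", 1)
  expect_setequal(rownames(X3), c("hit", "free"))
})

test_that("z-score p-values are calibrated under a null simulation", {
  set.seed(43)
  G <- 142  # 10011 gene pairs
  X <- matrix(rnorm(G * 200), G,
              dimnames = list(sprintf("g%03d", 1:G), NULL))
  bits <- rep(c(0, 1), each = 100)[sample(200)]
  tab <- zscore_dc(X, matrix(bits, 1))
  frac <- mean(tab$p < 0.05)
  m <- choose(G, 2)
  band <- 2.58 * sqrt(0.05 * 0.95 / m)
  expect_gt(frac, 0.05 - band)
  expect_lt(frac, 0.05 + band)
})

test_that("the dispatcher routes to every implemented method", {
  set.seed(47)
  X <- matrix(rnorm(6 * 80), 6, dimnames = list(paste0("g", 1:6), NULL))
  C <- matrix(rep(c(0, 1), each = 40), 1, dimnames = list("kd", NULL))
  for (m in c("zscore.pearson", "zscore.spearman", "ftgi")) {
    tab <- dc_infer(X, C, method = m)
    expect_s3_class(tab, "dc_score_table")
    expect_equal(nrow(tab), choose(6, 2))
    expect_true(all(tab$p >= 0 & tab$p <= 1))
  }
  tab <- dc_infer(X, C, method = "diffcoex", n_perm = 2)
  expect_s3_class(tab, "dc_score_table")
  net <- dc_infer(X, C, method = "coexp.wgcna")
  expect_type(net, "list")
  expect_error(dc_infer(X, C, method = "nope"))
})
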
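test_that("edge parameters stay in the linear-like ranges and are reproducible", {
  net <- small_network(seed = 2)
  p <- parameterise_edges(net, seed = 7)
  expect_true(all(p$ec50 >= 0.4 & p$ec50 <= 0.6))
  expect_true(all(p$n >= 1.01 & p$n <= 1.70))
  expect_identical(p, parameterise_edges(net, seed = 7))
  # near-singular EC50^n = 1/2: beta stays finite (direct evaluation of
  # (E - 1)/(2E - 1) at E = 0.5^1.01 gives 72.885)
  E <- 0.5^1.01
  expect_equal((E - 1) / (2 * E - 1), 72.885, tolerance = 1e-4)
  expect_equal(activation_value(0.5, 0.5, 1.01), 0.5, tolerance = 1e-9)
})

test_that("activation function satisfies its defining identities", {
  set.seed(31)
  ec50 <- runif(1000, 0.4, 0.6)
  n <- runif(1000, 1.01, 1.70)
  for (i in seq_len(1000)) {
    expect_equal(activation_value(0, ec50[i], n[i]), 0, tolerance = 1e-12)
    expect_equal(activation_value(ec50[i], ec50[i], n[i]), 0.5,
                 tolerance = 1e-12)
    expect_equal(activation_value(1, ec50[i], n[i]), 1, tolerance = 1e-12)
  }
  # strictly increasing
  for (i in seq_len(200)) {
    a <- sort(runif(2))
    expect_lt(activation_value(a[1], ec50[i], n[i]),
              activation_value(a[2], ec50[i], n[i]))
  }
  # hand-computed value: EC50 = 0.4, n = 1 gives f(A) = 3A/(2 + A)
  expect_equal(activation_value(0.5, 0.4, 1), 0.6, tolerance = 1e-12)
  expect_error(activation_value(1.5, 0.5, 1.2), "\\[0, 1\\]")
})

test_that("regulation combines multiplicatively and commutes", {
  net <- regnet(c("A", "B", "T"),
                data.frame(from = c("A", "B"), to = c("T", "T"),
                           sign = c("activation", "activation")))
  p <- fixed_params(net, ec50 = c(0.45, 0.55), n = c(1.2, 1.5))
  # two activators at their own EC50 give 0.5 * 0.5
  expect_equal(regulation_value(c(0.45, 0.55), p), 0.25, tolerance = 1e-12)
  # permuting regulators leaves the value unchanged
  expect_equal(regulation_value(c(0.55, 0.45), p[2:1, ]),
               regulation_value(c(0.45, 0.55), p), tolerance = 1e-15)
  # a single repressor at its EC50 gives 1 - 0.5
  pr <- p[1, ]; pr$sign <- "repression"
  expect_equal(regulation_value(0.45, pr), 0.5, tolerance = 1e-12)
})

test_that("C-vine matrices are valid correlation matrices", {
  expect_equal(cvine_correlation(1), matrix(1, 1, 1))
  # with all partials forced to zero the result is the identity
  expect_equal(cvine_correlation(5, sampler = function(n) rep(0, n)), diag(5))
  # for d = 2 the partial equals the marginal correlation
  R2 <- cvine_correlation(2, sampler = function(n) rep(0.5, n))
  expect_equal(R2[1, 2], 0.5)
  # positive definiteness across dimensions and seeds
  for (d in c(2, 5, 10, 50)) {
    for (s in 1:25) {
      R <- cvine_correlation(d, seed = s * d)
      expect_true(isSymmetric(R))
      expect_equal(diag(R), rep(1, d))
      expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), 0)
    }
  }
})

test_that("input model distributions match their Beta parameterisation", {
  net <- regnet(sprintf("I%03d", 1:200),
                data.frame(from = character(0), to = character(0),
                           sign = character(0)))
  kd <- sprintf("I%03d", 1:80)
  m <- sample_input_model(net, kd_genes = kd, seed = 5)
  # Beta(10,10) has mean 1/2; Beta(10,100) has mean 10/110
  expect_equal(mean(m$mu_wt), 0.5, tolerance = 0.03)
  expect_equal(mean(m$mu_kd), 10 / 110, tolerance = 0.1)
  # spread never exceeds the three-sigma support bound
  expect_true(all(m$sigma_wt <= pmin(m$mu_wt, 1 - m$mu_wt) / 3))
  expect_true(all(m$sigma_kd <= pmin(m$mu_kd, 1 - m$mu_kd) / 3))
  # knockdown inputs are excluded from the correlation model
  expect_equal(rownames(m$R), setdiff(m$inputs, kd))
  expect_error(sample_input_model(net, "nope", seed = 1), "input genes")
})

test_that("input sampling respects bounds, means and knockdown states", {
  net <- regnet(c("I1", "I2", "I3", "K1"),
                data.frame(from = character(0), to = character(0),
                           sign = character(0)))
  model <- sample_input_model(net, "K1", seed = 3)
  design <- structure(list(kd_genes = "K1", rho = c(K1 = 0.5),
                           C = matrix(rep(c(0, 1), each = 250), 1,
                                      dimnames = list("K1", NULL)),
                           n_samples = 500), class = "kd_design")
  X <- sample_inputs(model, design, seed = 9)
  expect_true(all(X >= 0 & X <= 1))
  kd <- design$C["K1", ] == 1
  expect_lt(mean(X["K1", kd]), mean(X["K1", !kd]))
  # identity correlations and tiny spread reproduce the means
  model$R[] <- diag(nrow(model$R))
  model$sigma_wt[] <- 1e-4
  X2 <- sample_inputs(model, design, n_samples = 500, seed = 10)
  expect_equal(unname(rowMeans(X2[c("I1", "I2", "I3"), ])),
               unname(model$mu_wt[c("I1", "I2", "I3")]), tolerance = 1e-4)
})

test_that("knockdown designs stay within the configured ranges", {
  inputs <- sprintf("I%02d", 1:12)
  d <- design_knockdowns(inputs, n_samples = 300, seed = 21)
  expect_true(length(d$kd_genes) >= 2 && length(d$kd_genes) <= 8)
  expect_true(all(d$rho >= 0.2 & d$rho <= 0.8))
  expect_equal(dim(d$C), c(length(d$kd_genes), 300))
  counts <- rowSums(d$C)
  expect_true(all(counts > 0 & counts < 300))
  expect_error(design_knockdowns(character(0), 100, seed = 1),
               "not enough input genes")
})

test_that("steady-state propagation is exact and matches the fixed-point solver", {
  # co-activation motif without noise: C = f_A(A) * f_B(B) exactly
  net <- motif_coactivation()
  p <- fixed_params(net, ec50 = c(0.4, 0.5), n = c(1, 1.3))
  inp <- rbind(A = c(0.3, 0.8), B = c(0.6, 0.2))
  X <- solve_steady_state(net, p, inp, sigma_act = 0)
  expected <- activation_value(inp["A", ], 0.4, 1) *
    activation_value(inp["B", ], 0.5, 1.3)
  expect_equal(unname(X["C", ]), expected, tolerance = 1e-14)
  expect_true(all(X >= 0 & X <= 1))

  # oracle equivalence on a 150-gene network
  net2 <- sample_subnetwork(shared_source(), 150, 10, 0.25, seed = 17)
  p2 <- parameterise_edges(net2, seed = 3)
  inputs2 <- classify_genes(net2)$inputs
  m2 <- sample_input_model(net2, character(0), seed = 4)
  inp2 <- matrix(rep(m2$mu_wt, 3), ncol = 3,
                 dimnames = list(inputs2, NULL))
  inp2[, 2] <- pmin(inp2[, 2] + 0.1, 1)
  inp2[, 3] <- pmax(inp2[, 3] - 0.1, 0)
  Xa <- solve_steady_state(net2, p2, inp2, sigma_act = 0)
  Xb <- solve_steady_state(net2, p2, inp2, sigma_act = 0,
                           method = "fixed_point", max_iter = 5000)
  expect_true(all(attr(Xb, "converged")))
  expect_lt(max(abs(Xa - Xb)), 1e-8)
})

test_that("simulated datasets have the right shape and are bit-reproducible", {
  net <- small_network(seed = 19)
  cfg <- sim_config(n_samples = 60)
  ds <- simulate_dataset(net, seed = 5, config = cfg)
  expect_equal(dim(ds$X), c(length(net$genes), 60))
  expect_equal(ncol(ds$design$C), 60)
  ds2 <- simulate_dataset(net, seed = 5, config = cfg)
  expect_identical(ds$X, ds2$X)
  # noise-free runs are a deterministic function of the inputs
  cfg0 <- sim_config(n_samples = 20, sigma_act = 0, sigma_meas = 0)
  d1 <- simulate_dataset(net, seed = 8, config = cfg0)
  expect_true(all(d1$X >= 0 & d1$X <= 1))
})

test_that("knocking down a co-activator weakens the co-regulator/target association", {
  rs <- t(vapply(1:20, function(s) {
    demo <- simulate_coactivation_demo(seed = s, n_samples = 400)
    c(wt = demo$r_wt, kd = demo$r_kd)
  }, c(wt = 0, kd = 0)))
  # directional: wildtype-state correlation dominates the knockdown state
  expect_true(all(rs[, "wt"] > rs[, "kd"]))
  expect_gt(mean(rs[, "wt"]) - mean(rs[, "kd"]), 0.2)
})

test_that("dataset serialisation writes matrices that read back", {
  net <- small_network(seed = 23)
  ds <- simulate_dataset(net, seed = 2, config = sim_config(n_samples = 30))
  dir <- tempfile()
  write_dataset(ds, dir)
  X <- read_matrix_tsv(file.path(dir, "expression.tsv"))
  expect_equal(dim(X), dim(ds$X))
  expect_equal(unname(X), unname(ds$X), tolerance = 1e-12)
  C <- read_matrix_tsv(file.path(dir, "conditions.tsv"))
  expect_equal(unname(C), unname(ds$design$C))
})
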
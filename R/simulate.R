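#' Sample normalised-Hill parameters for every edge
#'
#' Each regulatory edge gets an independent pair (EC50, n) drawn uniformly
#' from `[0.4, 0.6]` and `[1.01, 1.70]` respectively, restricting the model
#' to linear-like activation functions. The derived quantities
#' `E = EC50^n`, `beta = (E - 1) / (2E - 1)` and `Kn = beta - 1` are
#' precomputed; `K` itself is never materialised because it is non-real when
#' `beta < 1` and only `K^n` enters the activation function. When
#' `|2E - 1| < 1e-9` the activation function degenerates to `f(A) = A^n`
#' (the analytic limit), flagged in the `limit` column.
#'
#' @param net an acyclic `regnet`.
#' @param seed integer seed.
#' @param ec50_range,n_range sampling ranges for the two Hill parameters.
#' @return data.frame with one row per edge: `from`, `to`, `sign`, `ec50`,
#'   `n`, `beta`, `Kn`, `limit`.
#' @export
parameterise_edges <- function(net, seed = 1, ec50_range = c(0.4, 0.6),
                               n_range = c(1.01, 1.70)) {
  m <- nrow(net$edges)
  withr_seed(seed, {
    ec50 <- stats::runif(m, ec50_range[1], ec50_range[2])
    n <- stats::runif(m, n_range[1], n_range[2])
    p <- net$edges
    p$ec50 <- ec50
    p$n <- n
    E <- ec50^n
    p$limit <- abs(2 * E - 1) < 1e-9
    p$beta <- ifelse(p$limit, NA_real_, (E - 1) / (2 * E - 1))
    p$Kn <- p$beta - 1
    p
  })
}

#' Normalised-Hill activation function
#'
#' `f(A) = beta * A^n / (Kn + A^n)` with `beta` and `Kn` derived from EC50
#' and `n` so that `f(0) = 0`, `f(EC50) = 1/2` and `f(1) = 1`. `f` is
#' strictly increasing on `[0, 1]`.
#'
#' @param a regulator abundance(s) in `[0, 1]`.
#' @param ec50 half-maximal abundance in `[0, 1]` (exclusive of 0 and 1).
#' @param n Hill coefficient (> 0).
#' @return activation value(s) in `[0, 1]`.
#' @export
activation_value <- function(a, ec50, n) {
  if (any(a < 0 | a > 1))
    stop("abundance values must lie in [0, 1]")
  E <- ec50^n
  if (abs(2 * E - 1) < 1e-9) return(a^n)
  beta <- (E - 1) / (2 * E - 1)
  .f_act(a, beta, beta - 1, n, FALSE)
}

# internal: activation from precomputed beta/Kn; `limit` marks the E = 1/2
# singularity where f(A) = A^n exactly
.f_act <- function(a, beta, Kn, n, limit) {
  an <- a^n
  if (limit) an else beta * an / (Kn + an)
}

#' Combined regulation of one gene by several regulators
#'
#' Activators contribute their activation function and repressors contribute
#' one minus it; contributions combine multiplicatively (a logical AND
#' gate), so the result is commutative and associative in the regulators.
#'
#' @param abundances numeric vector of regulator abundances in `[0, 1]`.
#' @param params data.frame of edge parameters (rows aligned with
#'   `abundances`) as produced by [parameterise_edges()].
#' @return a single abundance in `[0, 1]`.
#' @export
regulation_value <- function(abundances, params) {
  if (any(abundances < 0 | abundances > 1))
    stop("abundance values must lie in [0, 1]")
  v <- 1
  for (i in seq_along(abundances)) {
    f <- .f_act(abundances[i], params$beta[i], params$Kn[i], params$n[i],
                params$limit[i])
    v <- v * if (params$sign[i] == "repression") 1 - f else f
  }
  v
}

#' Random correlation matrix via the C-vine construction
#'
#' Builds a valid (symmetric, unit-diagonal, positive-definite) correlation
#' matrix from sampled partial correlations using the canonical-vine
#' recursion. By default partials are drawn as `2 * Beta(5, 5) - 1`, i.e. a
#' symmetric distribution on `[-1, 1]` concentrated around zero.
#'
#' @param d dimension (>= 1).
#' @param sampler function of `n` returning `n` partial correlations in
#'   `(-1, 1)`.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return a `d x d` correlation matrix.
#' @export
cvine_correlation <- function(d, sampler = function(n) 2 * stats::rbeta(n, 5, 5) - 1,
                              seed = NULL) {
  withr_seed(seed, {
    R <- diag(d)
    if (d < 2) return(R)
    P <- matrix(0, d, d)
    P[upper.tri(P)] <- sampler(d * (d - 1) / 2)
    for (i in seq_len(d - 1)) {
      for (j in seq.int(i + 1, d)) {
        rho <- P[i, j]
        if (i > 1) {
          for (l in seq.int(i - 1, 1)) {
            rho <- rho * sqrt((1 - P[l, i]^2) * (1 - P[l, j]^2)) +
              P[l, i] * P[l, j]
          }
        }
        R[i, j] <- R[j, i] <- rho
      }
    }
    R
  })
}

#' Sample the input-gene distribution model
#'
#' Wildtype means are drawn from `Beta(10, 10)` (centred at 0.5) and
#' knockdown means from `Beta(10, 100)` (centred near 0.09, an abrogated
#' abundance). A per-gene spread factor `b ~ Beta(15, 15)` scales the
#' standard deviation as `sigma = b * min(mu, 1 - mu) / 3`, which keeps the
#' three-sigma support of each truncated normal inside `[0, 1]`. Non-
#' knockdown inputs share a C-vine random correlation matrix; knockdown
#' inputs are independent of everything so the differential signal is not
#' confounded. The model is held constant across all realisations of a
#' simulation.
#'
#' @param net a `regnet`.
#' @param kd_genes character vector of knockdown input genes.
#' @param seed integer seed.
#' @return list with `inputs`, `kd_genes`, `mu_wt`, `mu_kd`, `sigma_wt`,
#'   `sigma_kd`, `b` and correlation matrix `R` over non-knockdown inputs.
#' @export
sample_input_model <- function(net, kd_genes = character(0), seed = 1) {
  inputs <- classify_genes(net)$inputs
  if (!all(kd_genes %in% inputs))
    stop("knockdown genes must be input genes")
  withr_seed(seed, {
    ni <- length(inputs)
    mu_wt <- stats::setNames(stats::rbeta(ni, 10, 10), inputs)
    b <- stats::setNames(stats::rbeta(ni, 15, 15), inputs)
    sigma_wt <- b * pmin(mu_wt, 1 - mu_wt) / 3
    mu_kd <- stats::setNames(stats::rbeta(length(kd_genes), 10, 100), kd_genes)
    sigma_kd <- b[kd_genes] * pmin(mu_kd, 1 - mu_kd) / 3
    free <- setdiff(inputs, kd_genes)
    R <- cvine_correlation(length(free))
    dimnames(R) <- list(free, free)
    list(inputs = inputs, kd_genes = kd_genes, mu_wt = mu_wt, mu_kd = mu_kd,
         sigma_wt = sigma_wt, sigma_kd = sigma_kd, b = b, R = R)
  })
}

#' Design knockdown conditions
#'
#' Selects the number of knockdown genes uniformly from `n_kd_range`
#' (default 2 to 8), picks them without replacement from the input genes,
#' draws a per-gene knockdown proportion `rho ~ Uniform(0.2, 0.8)` and
#' assigns each sample to the knockdown state independently with probability
#' `rho` (so the knockdown sample count is `Binomial(n_samples, rho)`).
#' Designs leaving any knockdown with zero samples in either state are
#' rejected and redrawn.
#'
#' @param inputs character vector of input genes (or a `regnet`).
#' @param n_samples number of expression profiles.
#' @param n_kd_range integer range for the number of knockdowns.
#' @param rho_range range of the knockdown proportion.
#' @param seed integer seed.
#' @param max_attempts bounded retries for degenerate designs.
#' @return list of class `kd_design` with `kd_genes`, `rho` and binary
#'   condition matrix `C` (knockdowns x samples, 1 = knockdown state).
#' @export
design_knockdowns <- function(inputs, n_samples = 500, n_kd_range = c(2, 8),
                              rho_range = c(0.2, 0.8), seed = 1,
                              max_attempts = 100) {
  if (inherits(inputs, "regnet")) inputs <- classify_genes(inputs)$inputs
  lo <- min(n_kd_range)
  hi <- min(max(n_kd_range), length(inputs))
  if (hi < lo)
    stop("not enough input genes for the requested number of knockdowns")
  withr_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      n_kd <- if (hi > lo) sample(seq.int(lo, hi), 1) else lo
      kd_genes <- sample(inputs, n_kd)
      rho <- stats::setNames(stats::runif(n_kd, rho_range[1], rho_range[2]),
                             kd_genes)
      C <- matrix(stats::rbinom(n_kd * n_samples, 1, rep(rho, n_samples)),
                  nrow = n_kd, ncol = n_samples,
                  dimnames = list(kd_genes, NULL))
      counts <- rowSums(C)
      if (all(counts > 0 & counts < n_samples)) {
        return(structure(list(kd_genes = kd_genes, rho = rho, C = C,
                              n_samples = n_samples),
                         class = "kd_design"))
      }
    }
    stop("failed to draw a knockdown design with both states observed for ",
         "every knockdown after ", max_attempts, " attempts")
  })
}

# univariate truncated-normal draws on [0, 1] by inverse-CDF
.rtruncnorm01 <- function(n, mu, sd) {
  lo <- stats::pnorm((0 - mu) / sd)
  hi <- stats::pnorm((1 - mu) / sd)
  mu + sd * stats::qnorm(lo + stats::runif(n) * (hi - lo))
}

# truncated multivariate normal on [0,1]^d: whole-vector rejection with a
# capped number of batches, then univariate truncated resampling of
# out-of-range coordinates as a guaranteed-termination fallback
.rtruncmvnorm01 <- function(n, mu, sigma, R, max_batches = 50) {
  d <- length(mu)
  Sigma <- diag(sigma, d) %*% R %*% diag(sigma, d)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * abs(max(ev)))
    stop("input correlation matrix is not positive definite")
  out <- matrix(NA_real_, n, d)
  need <- n
  for (batch in seq_len(max_batches)) {
    draw <- MASS::mvrnorm(max(need, 2), mu = mu, Sigma = Sigma)
    ok <- rowSums(draw >= 0 & draw <= 1) == d
    take <- min(sum(ok), need)
    if (take > 0) {
      out[seq.int(n - need + 1, n - need + take), ] <-
        draw[which(ok)[seq_len(take)], , drop = FALSE]
      need <- need - take
    }
    if (need == 0) return(out)
  }
  draw <- MASS::mvrnorm(max(need, 2), mu = mu, Sigma = Sigma)[seq_len(need), , drop = FALSE]
  for (j in seq_len(d)) {
    bad <- draw[, j] < 0 | draw[, j] > 1
    if (any(bad))
      draw[bad, j] <- .rtruncnorm01(sum(bad), mu[j], sigma[j])
  }
  out[seq.int(n - need + 1, n), ] <- draw
  out
}

#' Sample input-gene abundances for a set of profiles
#'
#' Non-knockdown inputs are drawn jointly, per sample, from a truncated
#' multivariate normal on `[0, 1]` with the model's means, standard
#' deviations and C-vine correlation matrix. Each knockdown input is drawn
#' independently from a univariate truncated normal whose mean (and sd)
#' switch between the wildtype and knockdown model according to the sample's
#' condition bit.
#'
#' @param model input model from [sample_input_model()].
#' @param design `kd_design` from [design_knockdowns()].
#' @param n_samples number of profiles (defaults to the design's).
#' @param seed integer seed.
#' @return matrix inputs x samples with all values in `[0, 1]`.
#' @export
sample_inputs <- function(model, design, n_samples = design$n_samples,
                          seed = 1) {
  withr_seed(seed, {
    X <- matrix(NA_real_, length(model$inputs), n_samples,
                dimnames = list(model$inputs, NULL))
    free <- setdiff(model$inputs, model$kd_genes)
    if (length(free)) {
      draw <- .rtruncmvnorm01(n_samples, model$mu_wt[free],
                              model$sigma_wt[free],
                              model$R[free, free, drop = FALSE])
      X[free, ] <- t(draw)
    }
    for (g in model$kd_genes) {
      kd <- design$C[g, seq_len(n_samples)] == 1
      x <- numeric(n_samples)
      if (any(!kd))
        x[!kd] <- .rtruncnorm01(sum(!kd), model$mu_wt[g], model$sigma_wt[g])
      if (any(kd))
        x[kd] <- .rtruncnorm01(sum(kd), model$mu_kd[g], model$sigma_kd[g])
      X[g, ] <- x
    }
    X
  })
}

#' Solve steady-state abundances for all non-input genes
#'
#' Under the normalised-Hill model each non-input gene's rate equation is
#' `dB/dt = g(parents) - B`, so at steady state `B` equals its combined
#' regulation value. On an acyclic network this is computed exactly by
#' propagation in topological order (`method = "propagate"`). A damped
#' fixed-point solver (`method = "fixed_point"`) is provided as an
#' independent oracle and for non-DAG extensions; profiles that fail to
#' converge are flagged in the `converged` attribute. Activation noise
#' multiplies every activation function value by an independent lognormal
#' variable (`meanlog` 0, `sdlog` `sigma_act`) per edge and sample; noise
#' draws are fixed up-front so both solvers see the same perturbed system.
#'
#' @param net a `regnet`.
#' @param params edge parameters from [parameterise_edges()].
#' @param inputs matrix of input abundances (inputs x samples).
#' @param sigma_act lognormal sdlog of the activation noise (0 disables).
#' @param seed integer seed for the noise draws.
#' @param method `"propagate"` (exact on DAGs) or `"fixed_point"`.
#' @param tol,max_iter fixed-point convergence controls.
#' @return matrix genes x samples of steady-state abundances, with a logical
#'   `converged` attribute (one flag per sample).
#' @export
solve_steady_state <- function(net, params, inputs, sigma_act = 0.05,
                               seed = 1, method = c("propagate", "fixed_point"),
                               tol = 1e-10, max_iter = 1000) {
  method <- match.arg(method)
  if (method == "propagate" && !is_acyclic(net))
    stop("network contains cycles; use method = \"fixed_point\"")
  n_samples <- ncol(inputs)
  genes <- net$genes
  input_genes <- rownames(inputs)
  X <- matrix(NA_real_, length(genes), n_samples,
              dimnames = list(genes, colnames(inputs)))
  X[input_genes, ] <- inputs
  # fixed per-(edge, sample) lognormal noise factors
  eta <- withr_seed(seed, {
    if (sigma_act > 0)
      matrix(stats::rlnorm(nrow(params) * n_samples, 0, sigma_act),
             nrow(params), n_samples)
    else
      matrix(1, nrow(params), n_samples)
  })
  parent_edges <- split(seq_len(nrow(params)), params$to)
  solved <- setdiff(genes, input_genes)

  eval_gene <- function(g, Xcur) {
    eidx <- parent_edges[[g]]
    v <- rep(1, n_samples)
    for (e in eidx) {
      a <- pmin(pmax(Xcur[params$from[e], ], 0), 1)
      f <- .f_act(a, params$beta[e], params$Kn[e], params$n[e],
                  params$limit[e]) * eta[e, ]
      if (params$sign[e] == "repression") f <- 1 - f
      v <- v * f
    }
    v
  }

  if (method == "propagate") {
    ord <- net$genes[as.integer(igraph::topo_sort(as_igraph(net)))]
    for (g in intersect(ord, solved)) X[g, ] <- eval_gene(g, X)
    converged <- rep(TRUE, n_samples)
  } else {
    for (g in solved) X[g, ] <- 0.5
    converged <- rep(FALSE, n_samples)
    damp <- 0.9
    for (it in seq_len(max_iter)) {
      delta <- 0
      for (g in solved) {
        new <- (1 - damp) * X[g, ] + damp * eval_gene(g, X)
        delta <- pmax(delta, abs(new - X[g, ]))
        X[g, ] <- new
      }
      converged <- delta < tol
      if (all(converged)) break
    }
  }
  attr(X, "converged") <- converged
  X
}

#' Default simulation configuration
#'
#' @param n_samples profiles per simulation.
#' @param n_kd_range integer range for the number of knockdowns.
#' @param rho_range knockdown proportion range.
#' @param sigma_act lognormal activation-noise sdlog.
#' @param sigma_meas additive Gaussian measurement-noise sd.
#' @param solver steady-state solver passed to [solve_steady_state()].
#' @return a named list.
#' @export
sim_config <- function(n_samples = 500, n_kd_range = c(2, 8),
                       rho_range = c(0.2, 0.8), sigma_act = 0.05,
                       sigma_meas = 0.05, solver = "propagate") {
  list(n_samples = n_samples, n_kd_range = n_kd_range,
       rho_range = rho_range, sigma_act = sigma_act,
       sigma_meas = sigma_meas, solver = solver)
}

#' Simulate an expression dataset from a regulatory network
#'
#' Orchestrates the full generative pipeline: edge parameterisation,
#' knockdown design, input-gene model, input sampling, steady-state solving
#' with activation noise, and additive Gaussian measurement noise on every
#' entry of the final matrix. Child seeds for each stage are derived
#' deterministically from `seed`, so the result is bit-reproducible given
#' `(net, seed, config)`. Profiles whose steady state did not converge are
#' dropped (reported via `n_dropped`), which is why a 500-profile request
#' can return slightly fewer columns under the fixed-point solver.
#'
#' @param net an acyclic `regnet`.
#' @param seed integer seed.
#' @param config list from [sim_config()].
#' @param design optional pre-built `kd_design` (skips the design stage).
#' @param model optional pre-built input model.
#' @return object of class `expression_dataset`: list with matrix `X`
#'   (genes x samples, noise included), `design`, `model`, `params`, `net`,
#'   `seed`, `config`, `n_dropped`.
#' @export
simulate_dataset <- function(net, seed = 1, config = sim_config(),
                             design = NULL, model = NULL) {
  params <- parameterise_edges(net, seed = child_seed(seed, 1))
  inputs_genes <- classify_genes(net)$inputs
  if (is.null(design))
    design <- design_knockdowns(inputs_genes, config$n_samples,
                                config$n_kd_range, config$rho_range,
                                seed = child_seed(seed, 2))
  if (is.null(model))
    model <- sample_input_model(net, design$kd_genes,
                                seed = child_seed(seed, 3))
  inputs <- sample_inputs(model, design, config$n_samples,
                          seed = child_seed(seed, 4))
  X <- solve_steady_state(net, params, inputs, sigma_act = config$sigma_act,
                          seed = child_seed(seed, 5), method = config$solver)
  keep <- attr(X, "converged")
  n_dropped <- sum(!keep)
  X <- X[, keep, drop = FALSE]
  C <- design$C[, keep, drop = FALSE]
  if (config$sigma_meas > 0) {
    X <- X + withr_seed(child_seed(seed, 6),
                        matrix(stats::rnorm(length(X), 0, config$sigma_meas),
                               nrow(X), ncol(X)))
  }
  colnames(X) <- sprintf("S%04d", seq_len(ncol(X)))
  colnames(C) <- colnames(X)
  design$C <- C
  design$n_samples <- ncol(X)
  structure(list(X = X, design = design, model = model, params = params,
                 net = net, seed = seed, config = config,
                 n_dropped = n_dropped),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples, %d knockdown(s)\n",
              nrow(x$X), ncol(x$X), length(x$design$kd_genes)))
  cat("  knockdowns:", paste(x$design$kd_genes, collapse = ", "), "\n")
  if (x$n_dropped)
    cat("  dropped", x$n_dropped, "non-converged profile(s)\n")
  invisible(x)
}

#' Write an expression dataset to plain-text files
#'
#' The expression matrix is written as a genes x samples TSV (first column
#' `gene`), the condition matrix as a knockdowns x samples TSV, and the
#' parameters/provenance as JSON.
#'
#' @param dataset an `expression_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xp <- file.path(dir, "expression.tsv")
  utils::write.table(data.frame(gene = rownames(dataset$X), dataset$X,
                                check.names = FALSE),
                     xp, sep = "\t", quote = FALSE, row.names = FALSE)
  cp <- file.path(dir, "conditions.tsv")
  utils::write.table(data.frame(knockdown = rownames(dataset$design$C),
                                dataset$design$C, check.names = FALSE),
                     cp, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = dataset$seed, config = dataset$config,
         kd_genes = dataset$design$kd_genes,
         rho = as.list(dataset$design$rho),
         n_dropped = dataset$n_dropped,
         params = dataset$params),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
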
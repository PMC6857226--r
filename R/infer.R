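#' Pairwise gene correlations over a sample subset
#'
#' @param X genes x samples expression matrix.
#' @param mask logical or integer sample subset (at least 4 samples).
#' @param method `"pearson"` or `"spearman"` (Pearson on average ranks).
#' @return symmetric genes x genes correlation matrix; genes with constant
#'   expression get zero correlations with a warning.
#' @export
pair_correlations <- function(X, mask = seq_len(ncol(X)),
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  Xs <- X[, mask, drop = FALSE]
  if (ncol(Xs) < 4)
    stop("at least 4 samples are required to estimate correlations")
  suppressWarnings(r <- stats::cor(t(Xs), method = method))
  if (anyNA(r)) {
    warning("constant gene(s) detected; their correlations were set to 0")
    r[is.na(r)] <- 0
  }
  diag(r) <- 1
  r
}

# clamp correlations away from +/-1 so atanh stays finite
.clamp_r <- function(r) {
  if (any(abs(r[upper.tri(r)]) >= 1))
    warning("correlation(s) of magnitude 1 clamped before Fisher transform")
  pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
}

# accept a kd_design or a plain K x N binary matrix
.condition_matrix <- function(design) {
  C <- if (inherits(design, "kd_design")) design$C else as.matrix(design)
  if (is.null(rownames(C)))
    rownames(C) <- paste0("condition", seq_len(nrow(C)))
  if (!all(C %in% c(0, 1)))
    stop("condition matrix must be binary")
  C
}

# long-format score table for one condition from symmetric matrices
.pair_table <- function(condition, genes, score, p) {
  ut <- upper.tri(score)
  idx <- which(ut, arr.ind = TRUE)
  data.frame(condition = condition,
             gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
             score = score[ut], p = p[ut],
             stringsAsFactors = FALSE)
}

.finish_table <- function(tabs, method) {
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out$p_adj <- NA_real_
  for (cond in unique(out$condition)) {
    sel <- out$condition == cond
    out$p_adj[sel] <- bh_adjust(out$p[sel])
  }
  out$method <- method
  class(out) <- c("dc_score_table", "data.frame")
  out
}

#' Fisher z-score differential co-expression
#'
#' For every unordered gene pair and every condition, correlations are
#' estimated separately in the two states, Fisher z-transformed, and their
#' difference scaled by the pooled standard error
#' `sqrt(1/(n1-3) + 1/(n2-3))`. The statistic is referred to a standard
#' normal distribution (two-sided). Adjusted p-values are Benjamini-
#' Hochberg, computed per condition.
#'
#' @param X genes x samples matrix.
#' @param design `kd_design` or binary condition matrix (rows = conditions,
#'   1 = knockdown state).
#' @param cor_method `"pearson"` or `"spearman"`; the Spearman variant uses
#'   the same `1/(n-3)` variance after rank transformation.
#' @return a `dc_score_table`: long data.frame with columns `condition`,
#'   `gene_a`, `gene_b`, `score` (z), `p`, `p_adj`, `method`.
#' @export
zscore_dc <- function(X, design, cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  C <- .condition_matrix(design)
  genes <- rownames(X)
  tabs <- lapply(rownames(C), function(cond) {
    bits <- C[cond, ]
    n1 <- sum(bits == 0); n2 <- sum(bits == 1)
    if (min(n1, n2) < 4)
      stop("condition '", cond, "' has fewer than 4 samples in one state")
    r1 <- .clamp_r(pair_correlations(X, bits == 0, cor_method))
    r2 <- .clamp_r(pair_correlations(X, bits == 1, cor_method))
    z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
    p <- 2 * stats::pnorm(-abs(z))
    .pair_table(cond, genes, z, p)
  })
  .finish_table(tabs, paste0("zscore.", cor_method))
}

# signed-square soft-threshold correlation difference, the DiffCoEx
# adjacency between two states
.diffcoex_scores <- function(X, bits, beta_power) {
  r1 <- pair_correlations(X, bits == 0, "pearson")
  r2 <- pair_correlations(X, bits == 1, "pearson")
  (abs(sign(r1) * r1^2 - sign(r2) * r2^2) / 2)^(beta_power / 2)
}

#' DiffCoEx-style differential co-expression
#'
#' Scores each pair with the soft-thresholded signed-square correlation
#' difference `(|sign(r1) r1^2 - sign(r2) r2^2| / 2)^(beta/2)` and attaches
#' permutation p-values with the pooled-null scheme of
#' [permutation_test()].
#'
#' @inheritParams zscore_dc
#' @param beta_power even soft-threshold exponent (default 6).
#' @param n_perm number of label permutations (default 5).
#' @param seed integer seed for the permutations.
#' @return a `dc_score_table`.
#' @export
diffcoex_dc <- function(X, design, beta_power = 6, n_perm = 5, seed = 1) {
  C <- .condition_matrix(design)
  genes <- rownames(X)
  tabs <- lapply(rownames(C), function(cond) {
    bits <- C[cond, ]
    s <- .diffcoex_scores(X, bits, beta_power)
    ut <- upper.tri(s)
    p <- permutation_test(function(X, b) .diffcoex_scores(X, b, beta_power)[ut],
                          X, bits, n_perm = n_perm,
                          seed = child_seed(seed, match(cond, rownames(C))))
    pm <- s; pm[ut] <- p # only the upper triangle is read below
    .pair_table(cond, genes, s, pm)
  })
  .finish_table(tabs, "diffcoex")
}

#' Interaction linear-model (FTGI-style) differential co-expression
#'
#' For each ordered pair `(i, j)` fits `x_j ~ x_i + c + x_i:c` where `c` is
#' the binary condition, and takes the squared Wald statistic of the
#' interaction coefficient, referred to a chi-squared distribution with one
#' degree of freedom. The undirected pair score is the maximum statistic
#' over the two directions. Fits are batched per regressor gene through a
#' single QR decomposition, so the full pair scan is fast.
#'
#' @inheritParams zscore_dc
#' @return a `dc_score_table` (score = Wald chi-squared statistic).
#' @export
ftgi_dc <- function(X, design) {
  C <- .condition_matrix(design)
  genes <- rownames(X)
  G <- length(genes)
  tabs <- lapply(rownames(C), function(cond) {
    bits <- C[cond, ]
    n <- length(bits)
    if (min(sum(bits == 0), sum(bits == 1)) < 5)
      stop("condition '", cond, "' has fewer than 5 samples in one state")
    Y <- t(X)
    stat <- matrix(NA_real_, G, G)
    skipped <- FALSE
    for (i in seq_len(G)) {
      xi <- X[i, ]
      M <- cbind(1, xi, bits, xi * bits)
      qrM <- qr(M)
      if (qrM$rank < 4) { skipped <- TRUE; next }
      coefs <- qr.coef(qrM, Y)
      res <- Y - M %*% coefs
      rss <- colSums(res^2)
      sigma2 <- rss / (n - 4)
      XtXinv44 <- chol2inv(qr.R(qrM))[4, 4]
      tval2 <- coefs[4, ]^2 / (XtXinv44 * sigma2)
      stat[i, ] <- tval2
    }
    if (skipped)
      warning("rank-deficient fit(s) skipped for condition '", cond, "'")
    diag(stat) <- NA
    und <- pmax(stat, t(stat), na.rm = TRUE)
    und[is.infinite(und)] <- NA
    p <- stats::pchisq(und, df = 1, lower.tail = FALSE)
    .pair_table(cond, genes, und, p)
  })
  .finish_table(tabs, "ftgi")
}

# equal-frequency discretisation of each gene within a sample subset
.discretise <- function(X, bins) {
  t(apply(X, 1, function(x) {
    ceiling(rank(x, ties.method = "first") * bins / length(x))
  }))
}

# mutual information (bits) between all gene pairs from binned data
.mi_matrix <- function(B, bins) {
  G <- nrow(B)
  n <- ncol(B)
  marg <- lapply(seq_len(G), function(i) tabulate(B[i, ], bins) / n)
  mi <- matrix(0, G, G)
  for (i in seq_len(G - 1)) {
    bi <- (B[i, ] - 1L) * bins
    for (j in seq.int(i + 1, G)) {
      joint <- tabulate(bi + B[j, ], bins * bins) / n
      pij <- joint[joint > 0]
      exp_ij <- as.vector(outer(marg[[j]], marg[[i]]))[joint > 0]
      mi[i, j] <- mi[j, i] <- sum(pij * log2(pij / exp_ij))
    }
  }
  mi
}

.mindy_scores <- function(X, bits, bins) {
  abs(.mi_matrix(.discretise(X[, bits == 1, drop = FALSE], bins), bins) -
        .mi_matrix(.discretise(X[, bits == 0, drop = FALSE], bins), bins))
}

#' Conditional mutual information (MINDy-style) differential co-expression
#'
#' Scores each pair with the absolute difference in mutual information
#' between the two condition states, estimated by equal-frequency binning
#' within each state (MI in bits). This is the conditional-mutual-
#' information modulator statistic restricted to a binary modulator; it is
#' symmetric by construction. Permutation p-values use the pooled-null
#' scheme.
#'
#' @inheritParams diffcoex_dc
#' @param bins number of equal-frequency bins per gene (default 8); each
#'   state needs at least `bins^2` samples.
#' @return a `dc_score_table`.
#' @export
mindy_dc <- function(X, design, bins = 8, n_perm = 5, seed = 1) {
  C <- .condition_matrix(design)
  genes <- rownames(X)
  tabs <- lapply(rownames(C), function(cond) {
    bits <- C[cond, ]
    if (min(sum(bits == 0), sum(bits == 1)) < bins^2)
      stop("condition '", cond, "' needs at least bins^2 = ", bins^2,
           " samples per state; reduce `bins`")
    s <- .mindy_scores(X, bits, bins)
    ut <- upper.tri(s)
    p <- permutation_test(function(X, b) .mindy_scores(X, b, bins)[ut],
                          X, bits, n_perm = n_perm,
                          seed = child_seed(seed, match(cond, rownames(C))))
    pm <- s; pm[ut] <- p
    .pair_table(cond, genes, s, pm)
  })
  .finish_table(tabs, "mindy")
}

#' Pooled-null permutation test
#'
#' Condition labels are permuted `n_perm` times; the scores of all pairs
#' under all permutations are pooled into one null distribution, and each
#' observed score is assigned `p = (1 + #null >= observed) / (1 + #null)`.
#' The add-one smoothing keeps p-values strictly positive.
#'
#' @param score_fun function `(X, bits) -> numeric vector` of per-pair
#'   scores.
#' @param X genes x samples matrix.
#' @param bits binary condition vector.
#' @param n_perm number of permutations (>= 1, default 5).
#' @param seed integer seed.
#' @return numeric vector of p-values aligned with `score_fun(X, bits)`.
#' @export
permutation_test <- function(score_fun, X, bits, n_perm = 5, seed = 1) {
  stopifnot(n_perm >= 1)
  obs <- score_fun(X, bits)
  null <- withr_seed(seed, {
    unlist(lapply(seq_len(n_perm), function(b) score_fun(X, sample(bits))))
  })
  null <- null[!is.na(null)]
  sn <- sort(null)
  n_ge <- length(sn) - findInterval(obs, sn, left.open = TRUE)
  (1 + n_ge) / (1 + length(sn))
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over [stats::p.adjust()] (step-up FDR with monotonicity
#' enforcement); kept as a named step because adjustment is applied
#' separately per condition throughout the pipeline.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Threshold a score table into differential networks
#'
#' @param table a `dc_score_table`.
#' @param fdr FDR cut-off on the adjusted p-values (default 0.1).
#' @return named list (one element per condition) of two-column pair
#'   matrices.
#' @export
threshold_network <- function(table, fdr = 0.1) {
  conds <- unique(table$condition)
  out <- lapply(conds, function(cond) {
    sel <- table$condition == cond & !is.na(table$p_adj) & table$p_adj < fdr
    pair_matrix(table$gene_a[sel], table$gene_b[sel])
  })
  names(out) <- conds
  out
}

#' Co-expression difference baselines
#'
#' Builds a co-expression network separately in each condition state and
#' returns the symmetric difference (non-overlapping edges) as the
#' differential network. The `"wgcna"` flavour uses the soft-threshold
#' adjacency `|r|^power` with edges above `weight_cut`; the `"prill-z"`
#' flavour applies the single-condition Fisher z-test
#' `z = atanh(r) * sqrt(n - 3)` (two-sided), Benjamini-Hochberg adjustment
#' and the FDR cut-off within each state.
#'
#' @inheritParams zscore_dc
#' @param flavour `"wgcna"` or `"prill-z"`.
#' @param power soft-threshold exponent of the wgcna flavour.
#' @param weight_cut adjacency threshold of the wgcna flavour.
#' @param fdr FDR cut-off of the prill-z flavour.
#' @return named list (per condition) of pair matrices.
#' @export
coexpression_difference_baseline <- function(X, design,
                                             flavour = c("wgcna", "prill-z"),
                                             power = 6, weight_cut = 0.05,
                                             fdr = 0.1) {
  flavour <- match.arg(flavour)
  C <- .condition_matrix(design)
  state_edges <- function(mask) {
    n <- sum(mask)
    r <- pair_correlations(X, mask, "pearson")
    ut <- upper.tri(r)
    keep <- if (flavour == "wgcna") {
      (abs(r)^power)[ut] > weight_cut
    } else {
      z <- atanh(.clamp_r(r)[ut]) * sqrt(n - 3)
      bh_adjust(2 * stats::pnorm(-abs(z))) < fdr
    }
    idx <- which(ut, arr.ind = TRUE)
    pair_matrix(rownames(X)[idx[keep, 1]], rownames(X)[idx[keep, 2]])
  }
  out <- lapply(rownames(C), function(cond) {
    bits <- C[cond, ]
    e0 <- state_edges(bits == 0)
    e1 <- state_edges(bits == 1)
    k0 <- paste(e0[, 1], e0[, 2])
    k1 <- paste(e1[, 1], e1[, 2])
    both <- rbind(e0[!(k0 %in% k1), , drop = FALSE],
                  e1[!(k1 %in% k0), , drop = FALSE])
    pair_matrix(both[, 1], both[, 2])
  })
  names(out) <- rownames(C)
  out
}

#' Drop genes strongly associated with a driver
#'
#' Removes genes whose absolute correlation with the driver (a gene name or
#' a numeric sample-length vector, e.g. the knockdown condition) exceeds the
#' threshold, so that downstream differential analysis focuses on genes for
#' which the driver is a co-regulator rather than the sole regulator. The
#' driver gene itself always has `|r| = 1` and is therefore always removed.
#'
#' @param X genes x samples matrix.
#' @param driver gene name (row of `X`) or numeric vector over samples.
#' @param threshold absolute-correlation cut-off in `(0, 1]` (default 0.5).
#' @return the reduced matrix.
#' @export
filter_condition_associated <- function(X, driver, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  d <- if (is.character(driver)) X[driver, ] else as.numeric(driver)
  r <- suppressWarnings(apply(X, 1, function(x) stats::cor(x, d)))
  r[is.na(r)] <- 0
  # perfectly correlated genes (the driver itself) are always dropped
  keep <- abs(r) <= threshold & abs(r) < 1 - 1e-12
  X[keep, , drop = FALSE]
}

#' Unified differential co-expression dispatcher
#'
#' @param X genes x samples matrix.
#' @param design `kd_design` or binary condition matrix.
#' @param method one of `"zscore.pearson"`, `"zscore.spearman"`,
#'   `"diffcoex"`, `"ftgi"`, `"mindy"`, `"coexp.wgcna"`, `"coexp.prill-z"`.
#' @param fdr FDR cut-off used when a method thresholds internally.
#' @param ... passed to the method.
#' @return a `dc_score_table` for scoring methods; for the co-expression
#'   baselines, a per-condition list of pair matrices (they have no
#'   pair-level p-values).
#' @export
dc_infer <- function(X, design,
                     method = c("zscore.pearson", "zscore.spearman",
                                "diffcoex", "ftgi", "mindy",
                                "coexp.wgcna", "coexp.prill-z"),
                     fdr = 0.1, ...) {
  method <- match.arg(method)
  switch(method,
    "zscore.pearson" = zscore_dc(X, design, "pearson"),
    "zscore.spearman" = zscore_dc(X, design, "spearman"),
    "diffcoex" = diffcoex_dc(X, design, ...),
    "ftgi" = ftgi_dc(X, design),
    "mindy" = mindy_dc(X, design, ...),
    "coexp.wgcna" = coexpression_difference_baseline(X, design, "wgcna",
                                                     fdr = fdr, ...),
    "coexp.prill-z" = coexpression_difference_baseline(X, design, "prill-z",
                                                       fdr = fdr, ...)
  )
}

#' Write a score table as long-format TSV
#' @param table a `dc_score_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
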
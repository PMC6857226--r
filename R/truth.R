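#' Deterministic steady state at the input means
#'
#' Evaluates the network as a noise-free deterministic system with every
#' input gene fixed at its wildtype mean (knockdown inputs use the wildtype
#' mean too: the perturbation analysis characterises the intact system).
#'
#' @param net an acyclic `regnet`.
#' @param params edge parameters from [parameterise_edges()].
#' @param means named numeric vector of input-gene means.
#' @return named abundance vector over all genes.
#' @export
deterministic_state <- function(net, params, means) {
  inputs <- classify_genes(net)$inputs
  if (!all(inputs %in% names(means)))
    stop("means must cover every input gene")
  m <- matrix(means[inputs], ncol = 1, dimnames = list(inputs, NULL))
  X <- solve_steady_state(net, params, m, sigma_act = 0, seed = 0,
                          method = "propagate")
  stats::setNames(X[, 1], rownames(X))
}

#' Perturbation sensitivity of all genes to one input
#'
#' The chosen input's mean is reduced by `perturbation` (default 25%) and
#' the deterministic steady state recomputed. Sensitivity of gene `g` is the
#' relative change in its abundance divided by the perturbation fraction:
#' `((x_g - x'_g) / x_g) / perturbation`. Base abundances below
#' `abundance_floor` in magnitude are zeroed first (numerical guard), giving
#' those genes zero sensitivity. For linear-like activation functions the
#' result is essentially invariant to the perturbation size.
#'
#' @param net an acyclic `regnet`.
#' @param params edge parameters.
#' @param means named input means (wildtype).
#' @param input the input gene to perturb.
#' @param perturbation fractional reduction of the input mean.
#' @param abundance_floor abundances below this are treated as zero.
#' @return named sensitivity vector over all genes.
#' @export
perturbation_sensitivity <- function(net, params, means, input,
                                     perturbation = 0.25,
                                     abundance_floor = 0.001) {
  inputs <- classify_genes(net)$inputs
  if (!(input %in% inputs))
    stop("'", input, "' is not an input gene")
  base <- deterministic_state(net, params, means)
  pmeans <- means
  pmeans[input] <- means[input] * (1 - perturbation)
  pert <- deterministic_state(net, params, pmeans)
  base[abs(base) < abundance_floor] <- 0
  s <- ifelse(base == 0, 0, ((base - pert) / base) / perturbation)
  stats::setNames(s, names(base))
}

#' Build the perturbation-sensitivity matrix
#'
#' One column per input gene, computed with [perturbation_sensitivity()].
#' Binarising the absolute sensitivities at `threshold` yields the
#' gene-by-input dependency matrix; the association structure it encodes is
#' the influence network of the system.
#'
#' @param net an acyclic `regnet`.
#' @param params edge parameters.
#' @param means named input means (wildtype), e.g. `model$mu_wt`.
#' @param perturbation fractional perturbation (default 0.25).
#' @param threshold binarisation threshold on `|sensitivity|`.
#' @param abundance_floor numerical floor on base abundances.
#' @return list of class `sensitivity_matrix` with numeric matrix `S`
#'   (genes x inputs), binary matrix `binary`, and the thresholds used.
#' @export
build_sensitivity_matrix <- function(net, params, means, perturbation = 0.25,
                                     threshold = 0.01,
                                     abundance_floor = 0.001) {
  inputs <- classify_genes(net)$inputs
  S <- vapply(inputs, function(i)
    perturbation_sensitivity(net, params, means, i, perturbation,
                             abundance_floor),
    numeric(length(net$genes)))
  dimnames(S) <- list(net$genes, inputs)
  structure(list(S = S, binary = (abs(S) >= threshold) + 0L,
                 threshold = threshold, perturbation = perturbation),
            class = "sensitivity_matrix")
}

#' Genes sensitive only to one input
#'
#' Returns the non-input genes whose binarised sensitivity row is 1 for
#' input `k` and 0 for every other input. Ahead of inference these sole
#' targets of the knocked-down gene are filtered out (they are near-copies
#' of the knockdown gene and would break conditional independence); in the
#' truth derivation the same rule identifies the tightly correlated
#' "proxies" of each input.
#'
#' @param sens a `sensitivity_matrix`.
#' @param k an input gene (column of the matrix).
#' @return character vector of gene names (possibly empty).
#' @export
sole_target_filter <- function(sens, k) {
  B <- sens$binary
  if (!(k %in% colnames(B)))
    stop("'", k, "' is not an input gene of the sensitivity matrix")
  rs <- rowSums(B)
  hits <- rownames(B)[B[, k] == 1L & rs == 1L]
  setdiff(hits, colnames(B))
}

#' Derive the nested truth differential networks
#'
#' For each knockdown gene `k`: every other input `i` that shares a
#' sensitive target `t` with `k` manifests true differential co-expression
#' with that target, contributing the unordered pair `(i, t)` to the
#' *association* network; the pairs `(p, t)` are added for every proxy `p`
#' solely sensitive to `i`, since proxies are tightly correlated with their
#' input in the deterministic system. Restricting to pairs whose putative
#' regulator has a directed path to the target gives the *influence*
#' network, and further restricting to direct regulatory edges gives the
#' *direct* network, so `direct` is a subset of `influence` is a subset of
#' `association`. Pairs incident to the knockdown gene itself or to its sole
#' targets (which are filtered before inference) are excluded from all
#' three.
#'
#' @param net the `regnet` the sensitivities were computed on.
#' @param sens a `sensitivity_matrix`.
#' @param kd_genes knockdown input genes.
#' @return object of class `truth_networks`: `per_kd` is a list (one entry
#'   per knockdown) of `direct`/`influence`/`association` pair matrices and
#'   the `filtered` gene set; `sensitivity` stores the input matrix.
#' @export
derive_truth_networks <- function(net, sens, kd_genes) {
  B <- sens$binary
  inputs <- colnames(B)
  if (!all(kd_genes %in% inputs))
    stop("knockdown genes must be input genes")
  g <- as_igraph(net)
  # reachability by directed path, cached per putative regulator (inputs and
  # their proxies both act as regulators in the association edges)
  reach_cache <- new.env(hash = TRUE)
  reach_of <- function(r) {
    hit <- reach_cache[[r]]
    if (is.null(hit)) {
      hit <- net$genes[as.integer(igraph::subcomponent(g, r, mode = "out"))]
      assign(r, hit, envir = reach_cache)
    }
    hit
  }
  proxies <- lapply(inputs, function(i) sole_target_filter(sens, i))
  names(proxies) <- inputs
  edge_key <- paste(net$edges$from, net$edges$to)

  per_kd <- lapply(kd_genes, function(k) {
    filtered <- proxies[[k]]
    sens_k <- rownames(B)[B[, k] == 1L]
    reg <- character(0); tgt <- character(0)
    for (i in setdiff(inputs, k)) {
      shared <- intersect(rownames(B)[B[, i] == 1L], sens_k)
      shared <- setdiff(shared, c(inputs, filtered, k))
      if (!length(shared)) next
      regs_i <- c(i, setdiff(proxies[[i]], c(filtered, shared)))
      for (r in regs_i) {
        t_ok <- setdiff(shared, r)
        reg <- c(reg, rep(r, length(t_ok)))
        tgt <- c(tgt, t_ok)
      }
    }
    association <- pair_matrix(reg, tgt)
    if (length(reg)) {
      # regulator/target orientation is known here, before pair sorting
      has_path <- mapply(function(r, t) t %in% reach_of(r), reg, tgt)
      is_direct <- paste(reg, tgt) %in% edge_key
      influence <- pair_matrix(reg[has_path], tgt[has_path])
      direct <- pair_matrix(reg[is_direct], tgt[is_direct])
    } else {
      influence <- direct <- pair_matrix(character(0), character(0))
    }
    list(direct = direct, influence = influence, association = association,
         filtered = filtered)
  })
  names(per_kd) <- kd_genes
  structure(list(per_kd = per_kd, kd_genes = kd_genes, sensitivity = sens),
            class = "truth_networks")
}

#' @export
print.truth_networks <- function(x, ...) {
  cat("truth_networks for", length(x$kd_genes), "knockdown(s):\n")
  for (k in x$kd_genes) {
    t <- x$per_kd[[k]]
    cat(sprintf("  %s: direct %d / influence %d / association %d edges, %d filtered gene(s)\n",
                k, nrow(t$direct), nrow(t$influence), nrow(t$association),
                length(t$filtered)))
  }
  invisible(x)
}

#' Write truth networks as a long edge-list TSV
#'
#' One row per (knockdown, level, edge) with columns `knockdown`, `level`
#' (`direct`, `influence` or `association`), `gene_a`, `gene_b`.
#'
#' @param truth a `truth_networks` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_networks <- function(truth, path) {
  rows <- list()
  for (k in truth$kd_genes) {
    for (lvl in c("direct", "influence", "association")) {
      m <- truth$per_kd[[k]][[lvl]]
      if (nrow(m))
        rows[[length(rows) + 1]] <- data.frame(
          knockdown = k, level = lvl, gene_a = m[, 1], gene_b = m[, 2],
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(knockdown = character(0), level = character(0),
               gene_a = character(0), gene_b = character(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
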
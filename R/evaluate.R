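#' Pooled precision, recall and F1 for predicted differential networks
#'
#' Confusion counts are pooled over knockdown conditions within a
#' simulation (conditions with an empty truth set are excluded from
#' pooling), then precision, recall and `F1 = 2PR / (P + R)` are computed;
#' F1 is defined as 0 when `P + R = 0`. If every condition has an empty
#' truth set the result row is flagged `undefined`.
#'
#' @param predicted named list (per knockdown) of two-column pair matrices.
#' @param truth named list (per knockdown) of pair matrices, or a
#'   `truth_networks` object together with `level`.
#' @param level truth level to score against when `truth` is a
#'   `truth_networks` object (`"direct"`, `"influence"` or
#'   `"association"`).
#' @return one-row data.frame with `TP`, `FP`, `FN`, `precision`, `recall`,
#'   `F1`, `undefined`.
#' @export
precision_recall_f1 <- function(predicted, truth, level = "association") {
  if (inherits(truth, "truth_networks"))
    truth <- lapply(truth$per_kd, function(t) t[[level]])
  tp <- fp <- fn <- 0
  any_truth <- FALSE
  for (k in names(truth)) {
    tr <- truth[[k]]
    if (is.null(tr) || nrow(tr) == 0) next
    any_truth <- TRUE
    tk <- pair_key(tr[, 1], tr[, 2])
    pr <- predicted[[k]]
    pk <- if (is.null(pr) || nrow(pr) == 0) character(0) else
      pair_key(pr[, 1], pr[, 2])
    tp <- tp + sum(pk %in% tk)
    fp <- fp + sum(!(pk %in% tk))
    fn <- fn + sum(!(tk %in% pk))
  }
  P <- if (tp + fp > 0) tp / (tp + fp) else 0
  R <- if (tp + fn > 0) tp / (tp + fn) else 0
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  data.frame(TP = tp, FP = fp, FN = fn, precision = P, recall = R, F1 = F1,
             undefined = !any_truth)
}

#' Run inference methods on a simulated dataset and score them
#'
#' For each knockdown condition the sole sensitive targets of the
#' knocked-down gene are removed from the expression matrix (they are
#' near-copies of the condition variable), the method is run on the
#' remaining genes, thresholded at the FDR cut-off, and the predictions are
#' pooled against the three truth levels. The knockdown gene itself stays
#' in the matrix; since truth edges never touch it, any of its significant
#' pairs count as false positives. A method failure is recorded per method
#' and the run continues.
#'
#' @param dataset an `expression_dataset`.
#' @param truth a `truth_networks` object for the same simulation.
#' @param methods character vector of [dc_infer()] method names.
#' @param fdr FDR cut-off (default 0.1).
#' @param n_perm permutations for permutation-based methods.
#' @param seed integer seed for permutation-based methods.
#' @return list with `results` (data.frame: method, level, confusion counts
#'   and scores), `predictions` (per method, per knockdown pair matrices)
#'   and `errors` (per-method failure messages).
#' @export
evaluate_run <- function(dataset, truth, methods = "zscore.pearson",
                         fdr = 0.1, n_perm = 5, seed = 1) {
  X <- dataset$X
  design <- dataset$design
  rows <- list()
  preds_all <- list()
  errors <- list()
  for (m in methods) {
    pred <- tryCatch({
      per_kd <- lapply(design$kd_genes, function(k) {
        drop <- truth$per_kd[[k]]$filtered
        Xk <- X[!(rownames(X) %in% drop), , drop = FALSE]
        Ck <- design$C[k, , drop = FALSE]
        out <- dc_infer(Xk, Ck, method = m, fdr = fdr, n_perm = n_perm,
                        seed = child_seed(seed, match(k, design$kd_genes)))
        if (inherits(out, "dc_score_table"))
          threshold_network(out, fdr)[[1]]
        else
          out[[1]]
      })
      names(per_kd) <- design$kd_genes
      per_kd
    }, error = function(e) e)
    if (inherits(pred, "error")) {
      errors[[m]] <- conditionMessage(pred)
      next
    }
    preds_all[[m]] <- pred
    for (lvl in c("direct", "influence", "association")) {
      row <- precision_recall_f1(pred, truth, lvl)
      row <- cbind(data.frame(method = m, level = lvl), row)
      rows[[length(rows) + 1]] <- row
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else NULL
  list(results = results, predictions = preds_all, errors = errors)
}

#' Node degree by regulatory role in a differential network
#'
#' Computes the degree of every connected node in a differential (or truth)
#' network and annotates it as a target (zero out-degree in the regulatory
#' network) or a regulator. Nodes absent from the differential network are
#' excluded. Log-degree means per role summarise the hub structure: in
#' these differential networks high-degree nodes are typically
#' differentially regulated targets, not transcription factors.
#'
#' @param edges a two-column pair matrix, or a list of them (pooled).
#' @param net the generating `regnet`.
#' @return list with per-gene `table` (gene, degree, role) and
#'   `mean_log_degree` (named: target, regulator), using natural logs.
#' @export
degree_by_role <- function(edges, net) {
  if (is.list(edges) && !is.data.frame(edges))
    edges <- do.call(rbind, edges)
  if (is.null(edges) || nrow(edges) == 0)
    return(list(table = data.frame(gene = character(0), degree = integer(0),
                                   role = character(0)),
                mean_log_degree = c(target = NA_real_,
                                    regulator = NA_real_)))
  deg <- table(c(edges[, 1], edges[, 2]))
  roles <- classify_genes(net)
  tab <- data.frame(gene = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  tab$role <- ifelse(tab$gene %in% roles$targets, "target", "regulator")
  mld <- tapply(log(tab$degree), tab$role, mean)
  list(table = tab,
       mean_log_degree = c(target = unname(mld["target"]),
                           regulator = unname(mld["regulator"])))
}

#' Benchmark configuration
#'
#' Bundles the simulation, truth-derivation and inference constants used by
#' [run_benchmark()]. Defaults follow the standard study conditions:
#' 150-gene networks with at least 10 inputs sampled at stochasticity 0.25,
#' 500 profiles, 2-8 knockdowns at proportions in `[0.2, 0.8]`, both noise
#' sigmas 0.05, a 25% perturbation with abundance floor 0.001 and
#' sensitivity threshold 0.01, FDR 0.1 and 5 permutations.
#'
#' @param n_simulations number of simulations to run.
#' @param n_genes genes per sampled network.
#' @param n_samples profiles per simulation.
#' @param min_inputs minimum input genes in sampled networks.
#' @param k sampling stochasticity.
#' @param n_kd_range knockdown count range.
#' @param rho_range knockdown proportion range.
#' @param sigma_act,sigma_meas noise levels.
#' @param fdr FDR cut-off.
#' @param n_perm permutations for permutation-based methods.
#' @param perturbation perturbation fraction for the truth derivation.
#' @param abundance_floor numerical abundance floor.
#' @param sens_threshold binarisation threshold on sensitivities.
#' @param methods inference methods to benchmark.
#' @return named list of class `benchmark_config`.
#' @export
benchmark_config <- function(n_simulations = 10, n_genes = 150,
                             n_samples = 500, min_inputs = 10, k = 0.25,
                             n_kd_range = c(2, 8), rho_range = c(0.2, 0.8),
                             sigma_act = 0.05, sigma_meas = 0.05, fdr = 0.1,
                             n_perm = 5, perturbation = 0.25,
                             abundance_floor = 0.001, sens_threshold = 0.01,
                             methods = "zscore.pearson") {
  cfg <- list(n_simulations = n_simulations, n_genes = n_genes,
              n_samples = n_samples, min_inputs = min_inputs, k = k,
              n_kd_range = n_kd_range, rho_range = rho_range,
              sigma_act = sigma_act, sigma_meas = sigma_meas, fdr = fdr,
              n_perm = n_perm, perturbation = perturbation,
              abundance_floor = abundance_floor,
              sens_threshold = sens_threshold, methods = methods)
  stopifnot(cfg$fdr > 0, cfg$perturbation > 0, cfg$abundance_floor > 0,
            cfg$sens_threshold > 0, cfg$n_perm >= 1)
  class(cfg) <- c("benchmark_config", "list")
  cfg
}

#' Simulate, derive truth and evaluate one network
#'
#' One full benchmark iteration on an already-sampled network: simulate a
#' dataset, run the perturbation-sensitivity analysis, derive the truth
#' networks, and evaluate the configured inference methods. Simulations in
#' which no knockdown shares a sensitive target with another input (no
#' co-regulation, hence empty truth everywhere) are reported as failed.
#'
#' @param net an acyclic `regnet`.
#' @param seed integer seed.
#' @param config a `benchmark_config`.
#' @return list with `dataset`, `truth`, `evaluation`, `summary` and
#'   `failed` (NULL or a reason string).
#' @export
benchmark_one <- function(net, seed, config = benchmark_config()) {
  sc <- sim_config(n_samples = config$n_samples,
                   n_kd_range = config$n_kd_range,
                   rho_range = config$rho_range,
                   sigma_act = config$sigma_act,
                   sigma_meas = config$sigma_meas)
  ds <- simulate_dataset(net, seed = seed, config = sc)
  sens <- build_sensitivity_matrix(net, ds$params, ds$model$mu_wt,
                                   perturbation = config$perturbation,
                                   threshold = config$sens_threshold,
                                   abundance_floor = config$abundance_floor)
  truth <- derive_truth_networks(net, sens, ds$design$kd_genes)
  n_assoc <- sum(vapply(truth$per_kd, function(t) nrow(t$association), 0L))
  if (n_assoc == 0)
    return(list(dataset = ds, truth = truth, evaluation = NULL,
                summary = NULL,
                failed = "no co-regulation: all truth sets empty"))
  ev <- evaluate_run(ds, truth, methods = config$methods, fdr = config$fdr,
                     n_perm = config$n_perm, seed = child_seed(seed, 99))
  summ <- network_summary(net, truth, ds$model, ds$design)
  list(dataset = ds, truth = truth, evaluation = ev, summary = summ,
       failed = NULL)
}

#' Run a multi-simulation benchmark
#'
#' Loops simulate -> truth -> infer -> evaluate over freshly sampled
#' subnetworks of a source network. Per-simulation failures (no
#' co-regulation, degenerate designs, method errors) are logged and never
#' abort the sweep.
#'
#' @param config a `benchmark_config`.
#' @param source source `regnet` to sample from; by default a synthetic
#'   yeast-scale source network (690 genes, 1094 edges) is generated.
#' @param seed global integer seed; per-simulation seeds are derived from
#'   it.
#' @param keep_details keep per-simulation datasets/truths (memory-heavy).
#' @return list of class `benchmark_run` with tidy `results` (one row per
#'   simulation x method x truth level), `summaries`, `failures`, `config`
#'   and `seed`.
#' @export
run_benchmark <- function(config = benchmark_config(), source = NULL,
                          seed = 1, keep_details = FALSE) {
  if (is.null(source))
    source <- generate_synthetic_source(690, 1094,
                                        seed = child_seed(seed, 1000))
  rows <- list()
  summaries <- list()
  failures <- list()
  details <- list()
  for (s in seq_len(config$n_simulations)) {
    sim_seed <- child_seed(seed, s)
    res <- tryCatch({
      net <- sample_subnetwork(source, config$n_genes, config$min_inputs,
                               config$k, seed = child_seed(sim_seed, 1))
      benchmark_one(net, sim_seed, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        data.frame(simulation = s, reason = conditionMessage(res))
      next
    }
    if (!is.null(res$failed)) {
      failures[[length(failures) + 1]] <-
        data.frame(simulation = s, reason = res$failed)
      next
    }
    for (m in names(res$evaluation$errors))
      failures[[length(failures) + 1]] <-
        data.frame(simulation = s,
                   reason = paste0(m, ": ", res$evaluation$errors[[m]]))
    if (!is.null(res$evaluation$results)) {
      r <- cbind(data.frame(simulation = s, seed = sim_seed),
                 res$evaluation$results)
      rows[[length(rows) + 1]] <- r
    }
    summaries[[s]] <- res$summary
    if (keep_details) details[[s]] <- res
  }
  out <- list(
    results = if (length(rows)) do.call(rbind, rows) else NULL,
    summaries = summaries,
    failures = if (length(failures)) do.call(rbind, failures) else NULL,
    config = config, seed = seed
  )
  if (keep_details) out$details <- details
  class(out) <- c("benchmark_run", "list")
  out
}

#' @export
print.benchmark_run <- function(x, ...) {
  n_ok <- if (is.null(x$results)) 0 else length(unique(x$results$simulation))
  cat(sprintf("benchmark_run: %d/%d simulations completed\n",
              n_ok, x$config$n_simulations))
  if (!is.null(x$results)) {
    agg <- stats::aggregate(F1 ~ method + level, data = x$results, FUN = stats::median)
    names(agg)[3] <- "median_F1"
    print(agg, row.names = FALSE)
  }
  invisible(x)
}

#' Minimum sample size to detect a correlation
#'
#' Smallest per-condition sample size at which a one-sided Fisher z-test of
#' a given correlation reaches significance:
#' the smallest `n` with `atanh(r) * sqrt(n - 3) > qnorm(1 - alpha)`.
#'
#' @param r target correlation magnitude (default 0.3).
#' @param alpha significance level (default 0.05).
#' @return integer sample size.
#' @export
min_samples_for_correlation <- function(r = 0.3, alpha = 0.05) {
  zcrit <- stats::qnorm(1 - alpha)
  n <- 4L
  while (atanh(r) * sqrt(n - 3) <= zcrit) n <- n + 1L
  n
}
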
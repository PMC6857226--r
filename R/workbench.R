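#' Load a benchmark configuration from YAML
#'
#' Keys mirror the arguments of [benchmark_config()]; any key not known to
#' the configuration is rejected. An empty or absent file yields the full
#' defaults.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return a `benchmark_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(benchmark_config())
  if (!file.exists(path))
    stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(benchmark_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(benchmark_config, raw)
}

#' Save / load a benchmark run
#'
#' `save_run` writes the tidy results and failure tables as TSV, plus a JSON
#' manifest recording the configuration, seed, package version and an MD5
#' checksum of every output file. `load_run` verifies the checksums and
#' reconstructs the run; numeric round-trip is exact to write precision
#' (~1e-15 relative).
#'
#' @param run a `benchmark_run`.
#' @param dir output directory.
#' @return `save_run` returns `dir` invisibly; `load_run` returns a
#'   `benchmark_run`.
#' @export
save_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (!is.null(run$results)) {
    utils::write.table(format(run$results, digits = 17, trim = TRUE,
                              scientific = NA),
                       file.path(dir, "results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, "results.tsv")
  }
  if (!is.null(run$failures)) {
    utils::write.table(run$failures, file.path(dir, "failures.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, "failures.tsv")
  }
  sums <- as.list(tools::md5sum(file.path(dir, files)))
  names(sums) <- files
  manifest <- list(
    tool = "dcbench",
    version = as.character(utils::packageVersion("dcbench")),
    seed = run$seed,
    config = unclass(run$config),
    files = sums,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_run
#' @export
load_run <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath))
    stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  for (f in names(manifest$files)) {
    actual <- unname(tools::md5sum(file.path(dir, f)))
    if (is.na(actual) || actual != manifest$files[[f]])
      stop("checksum mismatch for ", f, "; run artifacts corrupted")
  }
  results <- if ("results.tsv" %in% names(manifest$files))
    utils::read.table(file.path(dir, "results.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE) else NULL
  failures <- if ("failures.tsv" %in% names(manifest$files))
    utils::read.table(file.path(dir, "failures.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE) else NULL
  cfg <- manifest$config
  cfg <- do.call(benchmark_config, cfg[names(cfg) %in%
                                         names(formals(benchmark_config))])
  structure(list(results = results, summaries = NULL, failures = failures,
                 config = cfg, seed = manifest$seed,
                 version = manifest$version),
            class = c("benchmark_run", "list"))
}

#' Read an expression or condition matrix from TSV
#'
#' Expects the layout written by [write_dataset()]: header row of sample
#' ids, first column of gene (or knockdown) identifiers.
#'
#' @param path TSV path.
#' @return numeric matrix with rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

.cli_usage <- "usage: dcbench <subcommand> [options]

subcommands:
  simulate   sample a network and simulate one expression dataset
  truth      derive the truth differential networks for a simulation
  infer      score a dataset with a DC method (--expression, --conditions)
  evaluate   one full simulate/truth/infer/evaluate iteration
  benchmark  multi-simulation sweep (--n-sims)
  fig1       three-gene co-activation demonstration; prints r_all/r_wt/r_kd

common options:
  --seed INT      global seed (default 1)
  --config PATH   YAML configuration file
  --outdir PATH   output directory (default '.')
  --method NAME   inference method (default zscore.pearson)
  --n-sims INT    number of simulations for 'benchmark'
  --expression PATH / --conditions PATH   inputs for 'infer'
"

.cli_args <- function(argv) {
  opts <- list(seed = 1L, config = NULL, outdir = ".",
               method = "zscore.pearson", `n-sims` = NULL,
               expression = NULL, conditions = NULL)
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (!(key %in% names(opts)))
      stop("unknown option: --", key)
    if (i == length(argv))
      stop("option --", key, " needs a value")
    val <- argv[i + 1]
    opts[[key]] <- if (key %in% c("seed", "n-sims")) as.integer(val) else val
    i <- i + 2
  }
  opts
}

#' Command-line entry point
#'
#' Thin dispatcher over the package's module entry points; see the wrapper
#' script in `inst/cli/dcbench.R`. Returns an exit status rather than
#' quitting so it is testable in-process: 0 on success, 2 on usage errors,
#' 1 on runtime failure.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return integer exit status, invisibly.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) {
    message(.cli_usage)
    return(invisible(2L))
  }
  sub <- argv[1]
  if (!(sub %in% c("simulate", "truth", "infer", "evaluate", "benchmark",
                   "fig1"))) {
    message("unknown subcommand: ", sub, "\n\n", .cli_usage)
    return(invisible(2L))
  }
  opts <- tryCatch(.cli_args(argv[-1]), error = function(e) e)
  if (inherits(opts, "error")) {
    message(conditionMessage(opts), "\n\n", .cli_usage)
    return(invisible(2L))
  }
  cfg <- tryCatch(load_config(opts$config), error = function(e) e)
  if (inherits(cfg, "error")) {
    message(conditionMessage(cfg))
    return(invisible(2L))
  }
  status <- tryCatch({
    .cli_dispatch(sub, opts, cfg)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.cli_dispatch <- function(sub, opts, cfg) {
  seed <- opts$seed
  outdir <- opts$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sample_net <- function() {
    source <- generate_synthetic_source(690, 1094,
                                        seed = child_seed(seed, 1000))
    sample_subnetwork(source, cfg$n_genes, cfg$min_inputs, cfg$k,
                      seed = child_seed(seed, 1))
  }
  if (sub == "fig1") {
    demo <- simulate_coactivation_demo(seed)
    cat(sprintf("r_all\t%.6f\nr_wt\t%.6f\nr_kd\t%.6f\n",
                demo$r_all, demo$r_wt, demo$r_kd))
    return(invisible(NULL))
  }
  if (sub == "simulate") {
    net <- sample_net()
    ds <- simulate_dataset(net, seed = seed,
                           config = sim_config(n_samples = cfg$n_samples,
                                               n_kd_range = cfg$n_kd_range,
                                               rho_range = cfg$rho_range,
                                               sigma_act = cfg$sigma_act,
                                               sigma_meas = cfg$sigma_meas))
    write_dataset(ds, outdir)
    write_network(net, file.path(outdir, "network.sif"), "sif")
    message("wrote dataset to ", outdir)
    return(invisible(NULL))
  }
  if (sub == "truth") {
    net <- sample_net()
    res <- benchmark_one(net, seed, cfg)
    write_truth_networks(res$truth, file.path(outdir, "truth.tsv"))
    message("wrote truth networks to ", file.path(outdir, "truth.tsv"))
    return(invisible(NULL))
  }
  if (sub == "infer") {
    if (is.null(opts$expression) || is.null(opts$conditions))
      stop("'infer' needs --expression and --conditions")
    X <- read_matrix_tsv(opts$expression)
    C <- read_matrix_tsv(opts$conditions)
    tab <- dc_infer(X, C, method = opts$method, fdr = cfg$fdr,
                    n_perm = cfg$n_perm)
    write_score_table(tab, file.path(outdir, "scores.tsv"))
    message("wrote scores to ", file.path(outdir, "scores.tsv"))
    return(invisible(NULL))
  }
  n_sims <- if (sub == "evaluate") 1L else
    if (!is.null(opts$`n-sims`)) opts$`n-sims` else cfg$n_simulations
  cfg$n_simulations <- n_sims
  cfg$methods <- unique(c(opts$method, cfg$methods))
  run <- run_benchmark(cfg, seed = seed)
  save_run(run, outdir)
  message("wrote benchmark results to ", outdir)
  invisible(NULL)
}
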
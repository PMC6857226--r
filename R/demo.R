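#' Two-co-activator knockdown demonstration
#'
#' Simulates the canonical three-gene differential co-expression motif:
#' input genes A and B co-activate target C (multiplicative normalised-Hill
#' activation), A is always wildtype, and B is knocked down in about half of
#' the samples. Because the co-activators must cooperate to activate C, the
#' knockdown abolishes the A-C association in the knockdown samples while
#' leaving it strong in the wildtype samples: the textbook differential
#' co-expression signal that an ordinary co-expression analysis would
#' dilute.
#'
#' @param seed integer seed.
#' @param n_samples number of profiles (default 500).
#' @return list with the `expression_dataset` and the three Pearson
#'   correlations of A with C: `r_all` (all samples), `r_wt` (B wildtype)
#'   and `r_kd` (B knocked down).
#' @export
simulate_coactivation_demo <- function(seed = 1, n_samples = 500) {
  net <- regnet(c("A", "B", "C"),
                data.frame(from = c("A", "B"), to = c("C", "C"),
                           sign = "activation"))
  design <- withr_seed(child_seed(seed, 2), {
    repeat {
      bits <- stats::rbinom(n_samples, 1, 0.5)
      if (any(bits == 1) && any(bits == 0)) break
    }
    structure(list(kd_genes = "B",
                   rho = c(B = 0.5),
                   C = matrix(bits, 1, n_samples,
                              dimnames = list("B", NULL)),
                   n_samples = n_samples),
              class = "kd_design")
  })
  ds <- simulate_dataset(net, seed = seed,
                         config = sim_config(n_samples = n_samples),
                         design = design)
  kd <- ds$design$C["B", ] == 1
  list(dataset = ds,
       r_all = stats::cor(ds$X["A", ], ds$X["C", ]),
       r_wt = stats::cor(ds$X["A", !kd], ds$X["C", !kd]),
       r_kd = stats::cor(ds$X["A", kd], ds$X["C", kd]))
}
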
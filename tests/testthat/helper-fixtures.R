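# Small fixture builders shared across the test files.

# A and B co-activate C (the canonical differential co-expression motif)
motif_coactivation <- function() {
  regnet(c("A", "B", "C"),
         data.frame(from = c("A", "B"), to = c("C", "C"),
                    sign = "activation"))
}

# A -> C, B -> C, A -> D: D is solely regulated by A
motif_proxy <- function() {
  regnet(c("A", "B", "C", "D"),
         data.frame(from = c("A", "B", "A"), to = c("C", "C", "D"),
                    sign = "activation"))
}

# edge parameters with hand-picked EC50/n (no sampling)
fixed_params <- function(net, ec50, n) {
  p <- net$edges
  p$ec50 <- rep_len(ec50, nrow(p))
  p$n <- rep_len(n, nrow(p))
  E <- p$ec50^p$n
  p$limit <- abs(2 * E - 1) < 1e-9
  p$beta <- ifelse(p$limit, NA_real_, (E - 1) / (2 * E - 1))
  p$Kn <- p$beta - 1
  p
}

# source network reused by sampling-heavy tests (built once per test run)
shared_source <- local({
  src <- NULL
  function() {
    if (is.null(src)) src <<- generate_synthetic_source(690, 1094, seed = 42)
    src
  }
})

# a small simulation-ready network for cheap end-to-end tests
small_network <- function(seed = 1, n_genes = 40) {
  src <- shared_source()
  sample_subnetwork(src, n_genes, min_inputs = 5, k = 0.25, seed = seed)
}
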
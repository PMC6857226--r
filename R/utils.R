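# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so simulation stages are independently reproducible.
withr_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a child seed from a global seed
#'
#' Counter-based mixing so every pipeline stage gets its own reproducible
#' stream from one user-facing seed. The result is always a positive integer
#' below 2^31.
#'
#' @param seed global integer seed.
#' @param index stage counter (any non-negative integer).
#' @return an integer seed.
#' @export
child_seed <- function(seed, index) {
  # Knuth-style multiplicative mixing in double precision (exact < 2^53)
  x <- (as.numeric(seed) %% 2147483647) + 1
  y <- (x * 48271 + as.numeric(index) * 2654435761) %% 2147483647
  as.integer(y %% 2147483562 + 1)
}

# unordered pair key "a|b" with lexicographically sorted endpoints
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# two-column character matrix of sorted unordered pairs, deduplicated
pair_matrix <- function(a, b) {
  if (!length(a))
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("gene_a", "gene_b"))))
  m <- cbind(gene_a = pmin(a, b), gene_b = pmax(a, b))
  m[!duplicated(paste(m[, 1], m[, 2])), , drop = FALSE]
}
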
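#' Signed directed regulatory networks
#'
#' A `regnet` object is a light container for a signed, directed gene
#' regulatory network: a character vector of gene identifiers and an edge
#' table with columns `from`, `to` and `sign` (`"activation"` or
#' `"repression"`). Genes with no incoming edge are *input genes* (their
#' abundance is sampled rather than solved), genes with no outgoing edge are
#' *target genes*, and everything with at least one outgoing edge is a
#' regulator.
#'
#' @param genes character vector of gene identifiers.
#' @param edges data.frame with columns `from`, `to`, `sign`.
#' @return An object of class `regnet`.
#' @export
regnet <- function(genes, edges) {
  genes <- as.character(genes)
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers")
  edges <- data.frame(
    from = as.character(edges$from),
    to = as.character(edges$to),
    sign = as.character(edges$sign),
    stringsAsFactors = FALSE
  )
  if (nrow(edges)) {
    bad <- !(edges$sign %in% c("activation", "repression"))
    if (any(bad))
      stop("unknown edge sign(s): ", paste(unique(edges$sign[bad]), collapse = ", "))
    if (any(edges$from == edges$to))
      stop("self-loops are not allowed")
    if (anyDuplicated(edges[, c("from", "to")]))
      stop("at most one edge per ordered gene pair")
    missing <- setdiff(unique(c(edges$from, edges$to)), genes)
    if (length(missing))
      stop("edge endpoints not in gene list: ", paste(missing, collapse = ", "))
  }
  structure(list(genes = genes, edges = edges), class = "regnet")
}

#' @export
print.regnet <- function(x, ...) {
  roles <- classify_genes(x)
  cat(sprintf(
    "regnet: %d genes, %d edges (%d activation / %d repression)\n",
    length(x$genes), nrow(x$edges),
    sum(x$edges$sign == "activation"), sum(x$edges$sign == "repression")
  ))
  cat(sprintf(
    "  %d input genes, %d regulators, %d targets\n",
    length(roles$inputs), length(roles$regulators), length(roles$targets)
  ))
  invisible(x)
}

#' Convert a regulatory network to an igraph graph
#'
#' @param net a `regnet`.
#' @param directed build a directed graph (default) or its undirected
#'   skeleton.
#' @return An `igraph` graph whose vertices are the network's genes.
#' @export
as_igraph <- function(net, directed = TRUE) {
  g <- igraph::make_empty_graph(n = 0, directed = directed)
  g <- igraph::add_vertices(g, length(net$genes), name = net$genes)
  if (nrow(net$edges))
    g <- igraph::add_edges(g, rbind(net$edges$from, net$edges$to),
                           sign = net$edges$sign)
  g
}

#' Classify genes by regulatory role
#'
#' Inputs are genes without regulators (in-degree zero), targets are genes
#' with zero out-degree, and regulators are all genes with at least one
#' outgoing edge (inputs with out-edges are counted as regulators too).
#'
#' @param net a `regnet`.
#' @return list with character vectors `inputs`, `regulators`, `targets`.
#' @export
classify_genes <- function(net) {
  indeg <- table(factor(net$edges$to, levels = net$genes))
  outdeg <- table(factor(net$edges$from, levels = net$genes))
  list(
    inputs = net$genes[indeg == 0],
    regulators = net$genes[outdeg > 0],
    targets = net$genes[outdeg == 0]
  )
}

#' Test whether a network is acyclic
#' @param net a `regnet`.
#' @return logical.
#' @export
is_acyclic <- function(net) {
  igraph::is_dag(as_igraph(net))
}

.sif_sign <- c(
  ac = "activation", activation = "activation",
  re = "repression", repression = "repression",
  du = "repression", dual = "repression"
)

#' Read a network from simple interaction format (SIF)
#'
#' Each non-empty line is `regulator <sep> type <sep> target` where the type
#' token is one of `ac`, `re`, `du` (or the long forms `activation`,
#' `repression`, `dual`). Dual-type edges are resolved to repression on
#' loading. Fields may be separated by tabs or runs of whitespace.
#'
#' @param path path to a SIF file.
#' @return a `regnet`.
#' @export
read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    stop("SIF parse error: '", path, "' contains no interactions")
  parts <- strsplit(lines, "[ \t]+")
  nf <- lengths(parts)
  if (any(nf != 3))
    stop("SIF parse error: line ", which(nf != 3)[1], " does not have 3 fields")
  m <- do.call(rbind, parts)
  type <- tolower(m[, 2])
  unknown <- !(type %in% names(.sif_sign))
  if (any(unknown))
    stop("SIF parse error: unknown interaction type '", m[unknown, 2][1],
         "' on line ", which(unknown)[1])
  if (any(m[, 1] == m[, 3]))
    stop("SIF parse error: self-loop on line ", which(m[, 1] == m[, 3])[1])
  edges <- data.frame(from = m[, 1], to = m[, 3],
                      sign = unname(.sif_sign[type]),
                      stringsAsFactors = FALSE)
  edges <- unique(edges)
  if (anyDuplicated(edges[, c("from", "to")]))
    stop("SIF parse error: conflicting duplicate edges for the same gene pair")
  regnet(unique(c(edges$from, edges$to)), edges)
}

#' Write a network or edge set to disk
#'
#' `format = "sif"` writes three tab-separated columns
#' (regulator, `ac`/`re`, target) and round-trips with [read_sif()];
#' `format = "tsv"` writes a plain two-column edge list (plus a `sign` column
#' when signs are available).
#'
#' @param x a `regnet`, or a two-column matrix/data.frame of edges.
#' @param path output path.
#' @param format `"sif"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(x, path, format = c("sif", "tsv")) {
  format <- match.arg(format)
  if (inherits(x, "regnet")) {
    edges <- x$edges
  } else {
    edges <- as.data.frame(x, stringsAsFactors = FALSE)
    names(edges)[1:2] <- c("from", "to")
  }
  if (format == "sif") {
    if (is.null(edges$sign))
      stop("SIF output requires edge signs")
    type <- c(activation = "ac", repression = "re")[edges$sign]
    out <- paste(edges$from, type, edges$to, sep = "\t")
    writeLines(out, path)
  } else {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Generate a synthetic source regulatory network
#'
#' Builds an acyclic, weakly connected, signed network of a given size for
#' use as a sampling source when no curated SIF network is supplied. Genes
#' are laid out in a fixed topological order; a designated prefix of the
#' order acts as input genes (never regulated). Every non-input gene
#' receives one parent first (which guarantees a path down to the input
#' layer) and the remaining edges are assigned by preferential attachment on
#' current out-degree, which yields the heavy-tailed regulator degree
#' distribution typical of transcriptional networks. A fixed proportion of
#' edges is flagged as repression.
#'
#' @param n_genes number of genes.
#' @param n_edges number of edges; must satisfy the spanning-skeleton
#'   feasibility bound reported in the error message.
#' @param min_inputs size of the input layer (genes with in-degree zero).
#'   The default, 5% of the genes, keeps input genes scarce the way
#'   top-level regulators are in curated transcriptional networks, so that
#'   ~150-gene subnetwork samples typically contain on the order of ten
#'   input genes.
#' @param prop_repression proportion of edges drawn as repressors.
#' @param seed integer seed; the same seed reproduces the same network.
#' @return a `regnet`.
#' @export
generate_synthetic_source <- function(n_genes, n_edges,
                                      min_inputs = max(2, round(0.05 * n_genes)),
                                      prop_repression = 0.25, seed = 1) {
  if (min_inputs >= n_genes)
    stop("min_inputs must be smaller than n_genes")
  n_inputs <- min_inputs
  n_free <- n_genes - n_inputs
  min_edges <- n_free + n_inputs - 1L # spanning skeleton (see below)
  max_edges <- choose(n_genes, 2) - choose(n_inputs, 2)
  if (n_edges < min_edges || n_edges > max_edges)
    stop("n_edges infeasible: need between ", min_edges, " and ", max_edges,
         " edges for ", n_genes, " genes with ", n_inputs, " inputs")
  withr_seed(seed, {
    width <- max(4, nchar(n_genes))
    genes <- sprintf(paste0("G%0", width, "d"), seq_len(n_genes))
    # gene index == topological order; edges always go low -> high, so the
    # result is acyclic by construction. A skeleton guarantees a single
    # weak component: the j-th non-input gene is regulated by the j-th
    # input (round-robin if inputs outnumber non-inputs) plus a spine edge
    # from the previous non-input, and leftover inputs attach round-robin.
    from <- integer(0)
    to <- integer(0)
    nonin <- function(j) n_inputs + j
    for (j in seq_len(n_free)) {
      if (j <= n_inputs) {
        from <- c(from, j); to <- c(to, nonin(j))
        if (j >= 2) { from <- c(from, nonin(j - 1L)); to <- c(to, nonin(j)) }
      } else {
        from <- c(from, sample.int(nonin(j) - 1L, 1L)); to <- c(to, nonin(j))
      }
    }
    if (n_inputs > n_free) {
      for (k in seq.int(n_free + 1L, n_inputs)) {
        from <- c(from, k); to <- c(to, nonin((k - 1L) %% n_free + 1L))
      }
    }
    k <- length(from)
    # remaining edges: preferential attachment on current out-degree gives
    # the heavy-tailed regulator degrees of transcriptional networks
    outdeg <- tabulate(from, n_genes)
    have <- new.env(hash = TRUE)
    for (i in seq_len(k)) assign(paste(from[i], to[i]), TRUE, envir = have)
    from <- c(from, integer(n_edges - k))
    to <- c(to, integer(n_edges - k))
    while (k < n_edges) {
      j <- sample.int(n_free, 1L) + n_inputs
      w <- outdeg[seq_len(j - 1L)] + 1
      i <- sample.int(j - 1L, 1L, prob = w)
      key <- paste(i, j)
      if (!is.null(have[[key]])) next
      assign(key, TRUE, envir = have)
      k <- k + 1L
      from[k] <- i
      to[k] <- j
      outdeg[i] <- outdeg[i] + 1L
    }
    edges <- data.frame(from = genes[from], to = genes[to],
                        sign = ifelse(stats::runif(n_edges) < prop_repression,
                                      "repression", "activation"),
                        stringsAsFactors = FALSE)
    regnet(genes, edges)
  })
}

#' Sample a subnetwork by greedy neighbour expansion
#'
#' Grows a connected induced subnetwork from a random start node. At each
#' step, with probability `k` the next gene is drawn uniformly from the
#' undirected neighbours of the current set ("stochastic" move), otherwise
#' the neighbour with the most connections into the current set is taken
#' (ties broken at random). The induced subnetwork inherits all source edges
#' between sampled genes. Sampling is rejected and restarted until the
#' result has at least `min_inputs` genes with in-degree zero (the grown set
#' is weakly connected by construction).
#'
#' @param source a `regnet` to sample from.
#' @param n_nodes number of genes to sample.
#' @param min_inputs minimum number of input genes in the result.
#' @param k stochasticity of the expansion, in `[0, 1]`.
#' @param seed integer seed.
#' @param max_attempts resampling attempts before giving up.
#' @param start optional fixed start gene (mainly for reproducibility tests).
#' @return a `regnet` with exactly `n_nodes` genes.
#' @export
sample_subnetwork <- function(source, n_nodes, min_inputs = 10, k = 0.25,
                              seed = 1, max_attempts = 100, start = NULL) {
  if (n_nodes > length(source$genes))
    stop("n_nodes exceeds the number of genes in the source network")
  if (n_nodes == length(source$genes)) return(source)
  g <- as_igraph(source, directed = FALSE)
  adj <- igraph::as_adj_list(g, mode = "all")
  names(adj) <- source$genes
  withr_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      start_v <- if (is.null(start)) sample(source$genes, 1) else start
      sel <- match(start_v, source$genes)
      in_set <- logical(length(source$genes))
      in_set[sel] <- TRUE
      # counts of connections into the current set for frontier nodes
      conn <- integer(length(source$genes))
      nb <- as.integer(adj[[sel]])
      conn[nb] <- conn[nb] + 1L
      while (sum(in_set) < n_nodes) {
        frontier <- which(!in_set & conn > 0L)
        if (!length(frontier))
          stop("source network exhausted before reaching n_nodes ",
               "(disconnected source?)")
        if (stats::runif(1) < k) {
          pick <- frontier[sample.int(length(frontier), 1L)]
        } else {
          best <- frontier[conn[frontier] == max(conn[frontier])]
          pick <- if (length(best) == 1L) best else
            best[sample.int(length(best), 1L)]
        }
        in_set[pick] <- TRUE
        nb <- as.integer(adj[[pick]])
        conn[nb] <- conn[nb] + 1L
      }
      genes <- source$genes[in_set]
      edges <- source$edges[source$edges$from %in% genes &
                              source$edges$to %in% genes, , drop = FALSE]
      net <- regnet(genes, edges)
      if (length(classify_genes(net)$inputs) >= min_inputs)
        return(net)
    }
  })
  stop("could not satisfy the minimum-input-gene constraint (>= ", min_inputs,
       " inputs) after ", max_attempts, " sampling attempts")
}

#' Summary statistics of a simulation's network and model
#'
#' Computes the 16 characteristics used to describe each simulation: average
#' number of input regulators per differentially regulated target, global and
#' mean-local clustering coefficients, densities of the source and of the
#' differential association network, diameter and radius, eigenvector
#' centrality of each knockdown gene, input-gene means and variances,
#' knockdown sample proportions, number of co-targeted (differentially
#' regulated) genes, number of inputs, knockdowns and regulators, and the
#' variance of the input-gene correlations. Graph statistics are computed on
#' the undirected skeleton; density is edges over `choose(N, 2)`. On a
#' disconnected skeleton the diameter and radius are computed on the largest
#' component and the summary is flagged.
#'
#' @param net a `regnet`.
#' @param truth optional `truth_networks` object (enables the differential
#'   network statistics).
#' @param model optional input model from [sample_input_model()].
#' @param design optional knockdown design from [design_knockdowns()].
#' @return a named list of class `network_summary`.
#' @export
network_summary <- function(net, truth = NULL, model = NULL, design = NULL) {
  g <- as_igraph(net, directed = FALSE)
  gs <- igraph::simplify(g)
  comp <- igraph::components(gs)
  connected <- comp$no == 1
  gd <- if (connected) gs else
    igraph::induced_subgraph(gs, which(comp$membership == which.max(comp$csize)))
  n <- length(net$genes)
  roles <- classify_genes(net)
  out <- list(
    clust_coef_global = zero_if_nan(igraph::transitivity(gs, type = "global")),
    clust_coef_local = zero_if_nan(
      igraph::transitivity(gs, type = "localaverageundirected", isolates = "zero")),
    density_source = nrow(net$edges) / choose(n, 2),
    diameter = igraph::diameter(gd, unconnected = FALSE),
    radius = igraph::radius(gd),
    num_inputs = length(roles$inputs),
    num_tfs = length(roles$regulators),
    connected = connected
  )
  if (!is.null(design)) {
    kd <- design$kd_genes
    ec <- igraph::eigen_centrality(gs)$vector
    out$eigen_centrality <- ec[kd]
    out$num_kd_genes <- length(kd)
    out$kd_sample_props <- pmin(design$rho, 1 - design$rho)
  }
  if (!is.null(model)) {
    out$input_means <- stats::setNames(model$mu_wt, model$inputs)
    out$input_vars <- stats::setNames(model$sigma_wt^2, model$inputs)
    R <- model$R
    out$var_of_input_cors <- if (!is.null(R) && nrow(R) > 1)
      stats::var(R[upper.tri(R)]) else NA_real_
  }
  if (!is.null(truth)) {
    assoc <- unique(do.call(rbind, lapply(truth$per_kd, function(t) t$association)))
    out$density_diffnet <- if (is.null(assoc)) 0 else nrow(assoc) / choose(n, 2)
    targets <- unique(assoc[, 2])
    out$num_co_targeted <- length(targets)
    if (length(targets)) {
      B <- truth$sensitivity$binary
      out$avg_num_input_tfs <- mean(rowSums(B[targets, , drop = FALSE]))
    } else {
      out$avg_num_input_tfs <- NA_real_
    }
  }
  class(out) <- "network_summary"
  out
}

#' @export
print.network_summary <- function(x, ...) {
  cat("network/model summary:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (length(v) > 1)
      cat(sprintf("  %-20s %s\n", nm,
                  paste(signif(unname(v), 3), collapse = " ")))
    else
      cat(sprintf("  %-20s %s\n", nm, format(signif(unname(v), 4))))
  }
  invisible(x)
}

#' Serialise / deserialise a network as JSON
#'
#' @param net a `regnet`.
#' @param path output (input) path.
#' @return `read_network_json` returns a `regnet`.
#' @export
write_network_json <- function(net, path) {
  jsonlite::write_json(
    list(genes = net$genes, edges = net$edges),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  regnet(x$genes, x$edges)
}

zero_if_nan <- function(x) ifelse(is.nan(x), 0, x)
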
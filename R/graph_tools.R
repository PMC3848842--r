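# Shared graph machinery for all network stages: a light undirected-graph
# container, degree-preserving edge randomization (null model for linkage
# significance), degree-proportional random graphs (null model for the
# disease network), Markov clustering, and connected components.
#
# igraph supplies the standard graph algorithms (double-edge-swap rewiring,
# components); the container stays a plain edge table so pair keys match the
# rest of the pipeline.

#' Construct an undirected graph from an edge list
#'
#' @param a,b endpoint id vectors (one edge per element).
#' @param nodes optional node universe; defaults to the endpoints. Extra
#'   nodes are kept as isolated vertices.
#' @param weights optional numeric edge weights.
#' @param allow_self permit self-loops? Default drops them.
#' @return list with `nodes`, `edges` (data.frame `a`, `b`, canonical order,
#'   no duplicates) and `weights`; class `"ppi_graph"`.
#' @export
ppi_graph <- function(a, b, nodes = NULL, weights = NULL, allow_self = FALSE) {
  ed <- canonical_pairs(as.character(a), as.character(b))
  if (!is.null(weights)) ed$w <- as.numeric(weights)
  if (!allow_self) ed <- ed[ed$a != ed$b, , drop = FALSE]
  ed <- ed[!duplicated(pair_key(ed$a, ed$b)), , drop = FALSE]
  rownames(ed) <- NULL
  nodes <- sort(unique(c(nodes, ed$a, ed$b)))
  structure(list(nodes = nodes,
                 edges = ed[c("a", "b")],
                 weights = if (!is.null(weights)) ed$w else NULL),
            class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat("undirected graph:", length(x$nodes), "nodes,", nrow(x$edges), "edges",
      if (!is.null(x$weights)) "(weighted)" else "", "\n")
  invisible(x)
}

.as_igraph <- function(g) {
  ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                      vertices = data.frame(name = g$nodes))
  if (!is.null(g$weights)) igraph::E(ig)$weight <- g$weights
  ig
}

.from_igraph <- function(ig) {
  ed <- igraph::as_data_frame(ig, what = "edges")
  ppi_graph(ed$from, ed$to, nodes = igraph::V(ig)$name)
}

#' Node degrees and degree centrality
#'
#' Degree centrality of a node is its degree divided by (number of nodes - 1).
#'
#' @param g a `"ppi_graph"`.
#' @param node optional single node id; default returns all nodes.
#' @return named numeric vector of centralities.
#' @export
degree_centrality <- function(g, node = NULL) {
  if (length(g$nodes) < 2L) stop("degree centrality needs at least 2 nodes")
  d <- graph_degree(g)
  dc <- d / (length(g$nodes) - 1L)
  if (is.null(node)) return(dc)
  if (!node %in% g$nodes) stop("node not in graph: ", node)
  dc[[node]]
}

#' @rdname degree_centrality
#' @return for `graph_degree()`, the named integer degree vector.
#' @export
graph_degree <- function(g) {
  d <- stats::setNames(integer(length(g$nodes)), g$nodes)
  tab <- table(c(g$edges$a, g$edges$b))
  d[names(tab)] <- as.integer(tab)
  d
}

#' Neighbors of a node
#' @param g a `"ppi_graph"`.
#' @param node a node id.
#' @return character vector of adjacent node ids.
#' @export
graph_neighbors <- function(g, node) {
  c(g$edges$b[g$edges$a == node], g$edges$a[g$edges$b == node])
}

#' Degree-preserving edge randomization
#'
#' Rewires the graph by repeated double edge swaps: two edges (a,b), (c,d)
#' are replaced by (a,d), (c,b) when neither new edge is a self-loop or a
#' duplicate. Every node keeps its exact degree; this is the null model used
#' by all linkage-significance tests.
#'
#' @param g a simple `"ppi_graph"` (no self-loops).
#' @param n_swaps_factor attempted swaps = `n_swaps_factor * |E|`.
#' @param seed integer RNG seed.
#' @return rewired `"ppi_graph"` with the same degree sequence.
#' @export
randomize_preserving_degree <- function(g, n_swaps_factor = 10L, seed = NULL) {
  m <- nrow(g$edges)
  if (m < 2L) {
    warning("graph too constrained to swap; returning input")
    return(g)
  }
  run <- function() {
    ig <- .as_igraph(g)
    rw <- igraph::rewire(ig, igraph::keeping_degseq(loops = FALSE,
                                                    niter = n_swaps_factor * m))
    .from_igraph(rw)
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' Random graph with degree-proportional endpoint sampling
#'
#' Builds a graph with `n_edges` edges by repeatedly drawing two distinct
#' endpoints with probability proportional to their degree in a template
#' network, rejecting already-accepted edges. Nodes with template degree 0
#' are never sampled. This reproduces the degree distribution of the template
#' only approximately (unlike edge-swap randomization, which is exact).
#'
#' @param degree_template named integer vector: node -> degree weight.
#' @param n_edges number of distinct edges to accept.
#' @param seed integer RNG seed.
#' @param budget_factor give up after `budget_factor * n_edges` draws.
#' @return a `"ppi_graph"`.
#' @export
random_graph_degree_proportional <- function(degree_template, n_edges,
                                             seed = NULL, budget_factor = 100L) {
  nodes <- names(degree_template)[degree_template > 0]
  w <- as.numeric(degree_template[degree_template > 0])
  if (length(nodes) < 2L) stop("need at least 2 nodes with positive degree")
  max_edges <- length(nodes) * (length(nodes) - 1L) / 2
  if (n_edges > max_edges) stop("n_edges exceeds the complete graph size")
  draw <- function() {
    seen <- character(0); ea <- character(n_edges); eb <- character(n_edges)
    accepted <- 0L; tries <- 0L; budget <- budget_factor * n_edges
    while (accepted < n_edges) {
      tries <- tries + 1L
      if (tries > budget) stop("retry budget exhausted while sampling edges; ",
                               "graph too dense for rejection sampling")
      pick <- sample(nodes, 2L, prob = w)
      k <- pair_key(pick[1], pick[2])
      if (k %in% seen) next
      seen <- c(seen, k)
      accepted <- accepted + 1L
      ea[accepted] <- pick[1]; eb[accepted] <- pick[2]
    }
    ppi_graph(ea, eb, nodes = names(degree_template))
  }
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

#' Markov clustering (MCL) of a weighted graph
#'
#' Runs the standard MCL iteration on the column-stochastic transition matrix
#' of the graph: expansion (matrix squaring) alternating with inflation
#' (elementwise power followed by column renormalization) and pruning of
#' entries below `prune`, until the matrix change falls under `tol`. Clusters
#' are read from the connected components of the support of the limit matrix;
#' every node lands in exactly one cluster. Self-loops with weight equal to
#' the node's maximum incident weight are added before iterating, the usual
#' device to guarantee convergence.
#'
#' @param g a weighted (or unweighted) `"ppi_graph"` with non-negative
#'   weights.
#' @param inflation inflation exponent (default 2, the conventional default).
#' @param max_iter iteration cap; non-convergence returns the current
#'   clustering with a warning.
#' @param tol convergence threshold on the max absolute matrix change.
#' @param prune entries below this are zeroed each iteration.
#' @return list of character vectors (the clusters), ordered by decreasing
#'   size then lexicographically by first member.
#' @export
mcl_cluster <- function(g, inflation = 2, max_iter = 100L, tol = 1e-6,
                        prune = 1e-5) {
  nodes <- g$nodes
  n <- length(nodes)
  if (n == 0L) return(list())
  w <- if (is.null(g$weights)) rep(1, nrow(g$edges)) else g$weights
  if (any(w < 0)) stop("MCL requires non-negative weights")
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  ia <- match(g$edges$a, nodes); ib <- match(g$edges$b, nodes)
  M[cbind(ia, ib)] <- w; M[cbind(ib, ia)] <- w
  loop <- apply(M, 2, max)
  loop[loop == 0] <- 1   # isolated nodes become their own attractor
  diag(M) <- loop
  normalize <- function(m) sweep(m, 2, colSums(m), "/")
  M <- normalize(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                      # expansion
    M2 <- M2^inflation                 # inflation
    M2[M2 < prune] <- 0
    M2 <- normalize(M2)
    if (max(abs(M2 - M)) < tol) { M <- M2; converged <- TRUE; break }
    M <- M2
  }
  if (!converged) warning("MCL did not converge in ", max_iter, " iterations")
  support <- (M > prune) | (t(M) > prune)
  cg <- igraph::graph_from_adjacency_matrix(support, mode = "undirected",
                                            diag = FALSE)
  comp <- igraph::components(cg)$membership
  cl <- split(nodes, comp)
  cl <- lapply(cl, sort)
  ord <- order(-lengths(cl), vapply(cl, `[`, character(1), 1L))
  unname(cl[ord])
}

#' Connected components of a graph
#' @param g a `"ppi_graph"`.
#' @return list of character vectors (node sets), by decreasing size.
#' @export
connected_components <- function(g) {
  if (!length(g$nodes)) return(list())
  comp <- igraph::components(.as_igraph(g))$membership
  cl <- lapply(split(names(comp), comp), sort)
  unname(cl[order(-lengths(cl), vapply(cl, `[`, character(1), 1L))])
}
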
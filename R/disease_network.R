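# Disease-disease association network: diseases are linked when predicted
# interactions join their causative genes (same degree-preserving exceedance
# rule as pathway linkages), edges are scored by a literature-similarity
# measure built from disease-term association p-values and term-wise PubMed
# id sets, and the score distribution is compared against degree-proportional
# random networks with a one-sided Kolmogorov-Smirnov test.

#' Build the disease association network
#'
#' A candidate edge joins two diseases when at least one predicted
#' interaction joins their causative gene sets; predicted self-interactions
#' never count (a shared causative gene alone creates no association). Edges
#' are retained when the supporting-interaction count strictly exceeds the
#' count in at least `quantile` of degree-preserving randomizations of the
#' predicted PPI network.
#'
#' @param predictions a thresholded `"prediction_set"`.
#' @param diseases a `"disease_table"` (diseases without a mapped literature
#'   term have already been dropped by the reader).
#' @param n_random randomized networks (published protocol: 10,000).
#' @param quantile retention quantile (published protocol: 0.999).
#' @param seed integer RNG seed.
#' @return `"linkage_network"` over disease ids whose `links` carry
#'   `n_interactions`, `n_null_ge` and the literature `similarity` of each
#'   retained pair.
#' @export
build_disease_network <- function(predictions, diseases, n_random = 10000L,
                                  quantile = 0.999, seed = 1L) {
  edges <- as.data.frame(predictions)[c("a", "b")]
  membership <- lapply(diseases, `[[`, "genes")
  sig <- .significant_set_linkages(edges, membership, n_random, quantile, seed)
  keys <- names(sig$observed)[sig$keep]
  parts <- strsplit(keys, "\t", fixed = TRUE)
  a <- vapply(parts, `[`, character(1), 1L)
  b <- vapply(parts, `[`, character(1), 2L)
  simv <- vapply(seq_along(a), function(i)
    literature_similarity(diseases[[a[i]]], diseases[[b[i]]]), numeric(1))
  links <- data.frame(a = a, b = b,
                      n_interactions = unname(sig$observed[keys]),
                      n_null_ge = unname(sig$fail[keys]),
                      similarity = simv, stringsAsFactors = FALSE)
  links <- links[order(pair_key(links$a, links$b)), , drop = FALSE]
  rownames(links) <- NULL
  # graph restricted to associated diseases, so component counts and the
  # degree template for random networks reflect the network actually found
  graph <- ppi_graph(links$a, links$b)
  structure(list(links = links, graph = graph, n_random = n_random,
                 quantile = quantile),
            class = "linkage_network")
}

#' Literature similarity of two diseases
#'
#' Combines how specifically each disease maps to its best literature term
#' with how often the two terms co-occur in the literature:
#' sim = -(|Px intersect Py| / min(|Px|, |Py|)) * ln(max(p1, p2)),
#' where Px, Py are the PubMed id sets of the two terms and p1, p2 the
#' disease-term association p-values. Disjoint literature or an uninformative
#' association (p = 1) gives 0.
#'
#' @param d1,d2 per-disease entries of a `"disease_table"` (fields `pmids`,
#'   `p_om`).
#' @return non-negative similarity score; symmetric in its arguments.
#' @export
literature_similarity <- function(d1, d2) {
  if (!length(d1$pmids) || !length(d2$pmids))
    stop("empty PubMed id set for a disease term")
  overlap <- length(intersect(d1$pmids, d2$pmids)) /
    min(length(d1$pmids), length(d2$pmids))
  -overlap * log(max(d1$p_om, d2$p_om))
}

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' Tests the alternative that `observed` is stochastically larger than
#' `reference`: D = sup_x (F_ref(x) - F_obs(x)) over the pooled value grid,
#' with the standard one-sided asymptotic bound
#' p = exp(-2 n m D^2 / (n + m)).
#'
#' @param observed,reference numeric samples.
#' @return list with `D` and `p`.
#' @export
ks_one_sided <- function(observed, reference) {
  if (!length(observed) || !length(reference)) stop("empty sample")
  grid <- sort(unique(c(observed, reference)))
  F_obs <- stats::ecdf(observed)(grid)
  F_ref <- stats::ecdf(reference)(grid)
  D <- max(F_ref - F_obs, 0)
  n <- length(observed); m <- length(reference)
  list(D = D, p = exp(-2 * n * m * D^2 / (n + m)))
}

#' Literature scores of degree-proportional random disease networks
#'
#' Each replicate draws a network with the observed edge count whose
#' endpoints are sampled in proportion to their degree in the observed
#' disease network (diseases of degree 0 never appear), then computes the
#' literature similarity of every random edge.
#'
#' @param observed a `"linkage_network"` over diseases.
#' @param diseases the `"disease_table"`.
#' @param n number of random networks (published protocol: 250).
#' @param seed integer RNG seed.
#' @return list of numeric vectors, one per replicate (each of length equal
#'   to the observed edge count).
#' @export
random_disease_networks <- function(observed, diseases, n = 250L, seed = 1L) {
  if (!nrow(observed$links)) stop("empty observed disease network")
  template <- graph_degree(observed$graph)
  n_edges <- nrow(observed$links)
  lapply(seq_len(n), function(r) {
    rg <- random_graph_degree_proportional(template, n_edges, seed = seed + r)
    vapply(seq_len(nrow(rg$edges)), function(i)
      literature_similarity(diseases[[rg$edges$a[i]]],
                            diseases[[rg$edges$b[i]]]), numeric(1))
  })
}

#' Compare observed disease-association scores against random networks
#'
#' Pools the literature scores of the random replicates and applies the
#' one-sided KS test with the alternative that observed scores are
#' stochastically larger.
#'
#' @inheritParams random_disease_networks
#' @return list: `D`, `p`, `observed_scores`, `n_random_scores`,
#'   `n_components` (connected components of the observed network).
#' @export
disease_network_significance <- function(observed, diseases, n = 250L,
                                         seed = 1L) {
  rnd <- unlist(random_disease_networks(observed, diseases, n = n, seed = seed),
                use.names = FALSE)
  ks <- ks_one_sided(observed$links$similarity, rnd)
  list(D = ks$D, p = ks$p,
       observed_scores = observed$links$similarity,
       n_random_scores = length(rnd),
       n_components = length(connected_components(observed$graph)))
}
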
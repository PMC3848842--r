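# Pathway-pathway linkage network built from a thresholded prediction set:
# pathways are linked when predicted interactions join their member proteins,
# linkages are kept when the supporting-interaction count beats a
# degree-preserving randomization null, compound sharing among linked
# pathways is tested against a second null on the linkage graph itself, the
# linkage network is clustered with MCL, and clusters are tested for
# pathway-ontology enrichment with a bias-corrected hypergeometric test.

# Count predicted interactions joining members of every entity pair
# (entities = pathways or diseases). Self-interactions (P, P) never count,
# and an entity is never linked to itself. Each edge contributes once to
# every distinct entity pair it joins.
.count_set_linkages <- function(edges, membership) {
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  prot2ent <- .invert_membership(membership)
  keys <- unlist(lapply(seq_len(nrow(edges)), function(i) {
    ea <- prot2ent[[edges$a[i]]]; eb <- prot2ent[[edges$b[i]]]
    if (is.null(ea) || is.null(eb)) return(character(0))
    gr <- expand.grid(ea, eb, stringsAsFactors = FALSE)
    gr <- gr[gr[[1]] != gr[[2]], , drop = FALSE]
    unique(pair_key(gr[[1]], gr[[2]]))
  }), use.names = FALSE)
  if (!length(keys)) return(structure(integer(0), names = character(0)))
  tab <- table(keys)
  structure(as.integer(tab), names = names(tab))
}

.invert_membership <- function(membership) {
  ent <- rep(names(membership), lengths(membership))
  prot <- unlist(membership, use.names = FALSE)
  lapply(split(ent, prot), unique)
}

#' Count inter-pathway predicted interactions
#'
#' @param predictions a thresholded `"prediction_set"` (or edge data.frame
#'   with columns `a`, `b`).
#' @param pathways a `"pathway_set"`.
#' @return named integer vector keyed by canonical pathway-pair key; pairs
#'   with no supporting interaction are absent. Proteins that belong to both
#'   pathways of a pair still contribute interactions counted once; predicted
#'   self-interactions contribute nothing.
#' @export
count_interpathway <- function(predictions, pathways) {
  membership <- lapply(pathways, `[[`, "members")
  .count_set_linkages(as.data.frame(predictions)[c("a", "b")], membership)
}

# Shared significance machinery: keep entity links whose observed support
# strictly exceeds the support in at least `quantile` of degree-preserving
# randomizations of the underlying protein network. Ties count against
# retention.
.significant_set_linkages <- function(edges, membership, n_random, quantile,
                                      seed, n_swaps_factor = 10L) {
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  observed <- .count_set_linkages(edges, membership)
  if (!length(observed)) stop("no candidate linkages: no cross-set interaction")
  g <- ppi_graph(edges$a, edges$b)
  fail <- structure(integer(length(observed)), names = names(observed))
  for (r in seq_len(n_random)) {
    rg <- randomize_preserving_degree(g, n_swaps_factor = n_swaps_factor,
                                      seed = seed + r)
    null_counts <- .count_set_linkages(rg$edges, membership)
    hit <- names(observed)[match(names(null_counts), names(observed))]
    hit <- hit[!is.na(hit)]
    nc <- null_counts[hit]
    fail[hit] <- fail[hit] + as.integer(nc >= observed[hit])
  }
  keep <- (n_random - fail) >= quantile * n_random
  list(observed = observed, fail = fail, keep = keep,
       n_random = n_random, quantile = quantile)
}

#' Significant pathway linkages against a degree-preserving null
#'
#' For each of `n_random` degree-preserving randomizations of the predicted
#' PPI network, inter-pathway interaction counts are recomputed; a pathway
#' linkage is retained when its observed count strictly exceeds the
#' randomized count in at least `quantile` of the replicates (ties count
#' against retention). Edge weight is the observed count divided by the
#' number of possible non-self protein pairs between the two pathways.
#'
#' @inheritParams count_interpathway
#' @param n_random number of randomized networks (published protocol:
#'   10,000).
#' @param quantile retention quantile (published protocol: 0.999).
#' @param seed integer RNG seed.
#' @param max_pathways_per_compound compounds present in more than this many
#'   pathways are considered ubiquitous and ignored by the
#'   `shares_compound` flag.
#' @return object of class `"linkage_network"`: data.frame `links` with
#'   columns `a`, `b`, `n_interactions`, `n_null_ge` (replicates whose null
#'   count reached the observed), `weight`, `shares_compound`, plus the
#'   retained `graph` (a weighted `"ppi_graph"`) and the run parameters.
#' @export
significant_linkages <- function(predictions, pathways, n_random = 10000L,
                                 quantile = 0.999, seed = 1L,
                                 max_pathways_per_compound = 15L) {
  edges <- as.data.frame(predictions)[c("a", "b")]
  membership <- lapply(pathways, `[[`, "members")
  sig <- .significant_set_linkages(edges, membership, n_random, quantile, seed)
  keys <- names(sig$observed)[sig$keep]
  parts <- strsplit(keys, "\t", fixed = TRUE)
  a <- vapply(parts, `[`, character(1), 1L)
  b <- vapply(parts, `[`, character(1), 2L)
  poss <- vapply(seq_along(a), function(i) {
    .possible_nonself_pairs(membership[[a[i]]], membership[[b[i]]])
  }, numeric(1))
  rare <- .non_ubiquitous_compounds(pathways, max_pathways_per_compound)
  shares <- vapply(seq_along(a), function(i) {
    length(intersect(intersect(pathways[[a[i]]]$compounds, rare),
                     pathways[[b[i]]]$compounds)) > 0L
  }, logical(1))
  links <- data.frame(a = a, b = b,
                      n_interactions = unname(sig$observed[keys]),
                      n_null_ge = unname(sig$fail[keys]),
                      weight = unname(sig$observed[keys]) / poss,
                      shares_compound = shares,
                      stringsAsFactors = FALSE)
  links <- links[order(pair_key(links$a, links$b)), , drop = FALSE]
  rownames(links) <- NULL
  graph <- if (nrow(links))
    ppi_graph(links$a, links$b, nodes = names(pathways), weights = links$weight)
  else ppi_graph(character(0), character(0), nodes = names(pathways))
  structure(list(links = links, graph = graph, n_random = n_random,
                 quantile = quantile),
            class = "linkage_network")
}

# Unordered protein pairs {P, Q}, P in A, Q in B, P != Q.
.possible_nonself_pairs <- function(A, B) {
  x <- length(intersect(A, B))
  length(A) * length(B) - x - x * (x - 1) / 2
}

.non_ubiquitous_compounds <- function(pathways, max_pathways_per_compound) {
  cmp <- unlist(lapply(pathways, function(p) unique(p$compounds)),
                use.names = FALSE)
  tab <- table(cmp)
  names(tab)[tab <= max_pathways_per_compound]
}

#' @export
print.linkage_network <- function(x, ...) {
  cat("linkage network:", nrow(x$links), "significant links (quantile",
      x$quantile, "over", x$n_random, "randomizations)\n")
  invisible(x)
}

#' Compound sharing among linked pathways
#'
#' Counts retained linkages whose two pathways share at least one
#' non-ubiquitous metabolic compound (a compound present in more than
#' `max_pathways_per_compound` pathways — e.g. ATP — never counts). The null
#' distribution rewires the linkage graph itself, preserving every pathway's
#' degree; the empirical p-value is the fraction of replicates reaching the
#' observed count, floored at 1/(n_random + 1).
#'
#' @param linkage a `"linkage_network"`.
#' @param pathways the `"pathway_set"` with compound annotations.
#' @param max_pathways_per_compound ubiquity cut-off (default 15).
#' @param n_random randomized linkage networks (published protocol: 10,000).
#' @param seed integer RNG seed.
#' @return list: `n_sharing`, `null_mean`, `null_sd`, `p`, `n_random`.
#' @export
compound_sharing_test <- function(linkage, pathways,
                                  max_pathways_per_compound = 15L,
                                  n_random = 10000L, seed = 1L) {
  if (!nrow(linkage$links)) stop("empty linkage network")
  rare <- .non_ubiquitous_compounds(pathways, max_pathways_per_compound)
  n_share <- function(ed) {
    sum(vapply(seq_len(nrow(ed)), function(i) {
      length(intersect(intersect(pathways[[ed$a[i]]]$compounds, rare),
                       pathways[[ed$b[i]]]$compounds)) > 0L
    }, logical(1)))
  }
  g <- linkage$graph
  observed <- n_share(g$edges)
  nulls <- vapply(seq_len(n_random), function(r) {
    n_share(randomize_preserving_degree(g, seed = seed + r)$edges)
  }, numeric(1))
  list(n_sharing = observed,
       null_mean = mean(nulls), null_sd = stats::sd(nulls),
       p = max(mean(nulls >= observed), 1 / (n_random + 1)),
       n_random = n_random)
}

#' Bias-corrected annotation enrichment p-value
#'
#' Upper-tail hypergeometric probability of observing at least `M_gt`
#' annotations on the ontology branch of interest among a cluster's `M_g`
#' annotations, when `M_t` of the `M_tot` total pathway annotations lie on
#' the branch:
#' p = sum_{i = M_gt}^{min(M_g, M_t)} C(M_t, i) C(M_tot - M_t, M_g - i) /
#' C(M_tot, M_g).
#'
#' @param M_gt annotations to the cluster on the branch of interest.
#' @param M_g annotations to the cluster.
#' @param M_t pathways (annotations) on the branch of interest.
#' @param M_tot total pathway annotations made to the ontology.
#' @return p-value in (0, 1].
#' @export
enrichment_p <- function(M_gt, M_g, M_t, M_tot) {
  if (M_gt > min(M_g, M_t) || M_g > M_tot || M_t > M_tot || M_gt < 0)
    stop("impossible enrichment counts")
  sum(stats::dhyper(seq.int(M_gt, min(M_g, M_t)), M_t, M_tot - M_t, M_g))
}

#' Ontology enrichment of pathway clusters
#'
#' Each pathway annotates every ontology node it descends from (one
#' annotation per node, via its class terms). For every (cluster, node) pair
#' with at least one cluster annotation on the node, the upper-tail
#' hypergeometric p-value of [enrichment_p()] is computed; a term is called
#' significant at a 0.05 family-wide error rate under Bonferroni correction
#' over (number of clusters) x (number of ontology nodes).
#'
#' @param clusters list of character vectors of pathway ids (e.g. from
#'   [mcl_cluster()]).
#' @param dag the pathway-class `"ontology_dag"`.
#' @param pathways a `"pathway_set"` whose `classes` fields hold each
#'   pathway's ontology class terms.
#' @param alpha family-wide type I error rate (default 0.05).
#' @return data.frame with columns `cluster`, `term`, `M_gt`, `M_g`, `M_t`,
#'   `M_tot`, `p`, `significant`, ordered by p.
#' @export
cluster_enrichment <- function(clusters, dag, pathways, alpha = 0.05) {
  ann_nodes <- lapply(pathways, function(p) {
    cls <- intersect(p$classes, dag$terms)
    if (!length(cls)) return(character(0))
    unique(unlist(lapply(cls, dag_ancestors, dag = dag), use.names = FALSE))
  })
  M_tot <- sum(lengths(ann_nodes))
  if (M_tot == 0L) stop("no pathway maps into the ontology")
  node_count <- table(unlist(ann_nodes, use.names = FALSE))
  n_C <- length(clusters); n_O <- length(dag$terms)
  cutoff <- alpha / (n_C * n_O)
  rows <- list()
  for (ci in seq_along(clusters)) {
    members <- intersect(clusters[[ci]], names(ann_nodes))
    M_g <- sum(lengths(ann_nodes[members]))
    if (M_g == 0L) next
    on_branch <- table(unlist(ann_nodes[members], use.names = FALSE))
    for (t in names(on_branch)) {
      M_gt <- as.integer(on_branch[[t]])
      M_t <- as.integer(node_count[[t]])
      p <- enrichment_p(M_gt, M_g, M_t, M_tot)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = ci, term = t, M_gt = M_gt, M_g = M_g, M_t = M_t,
        M_tot = M_tot, p = p, significant = p <= cutoff,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$cluster, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
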
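# Testing-set performance (confusion counts, ROC/AUC) and the three
# functional-plausibility measures for a predicted network — pathway-sharing
# (Jaccard), information-content ontology semantic similarity, and
# co-expression enrichment — each compared against degree-preserving
# randomized networks.

#' Confusion counts of a thresholded prediction set
#'
#' @param predicted a `"prediction_set"` already thresholded (or any
#'   data.frame with columns `a`, `b`).
#' @param truth_pos,truth_neg disjoint `"interaction_set"`s of known
#'   interacting and non-interacting pairs.
#' @return list with integer `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(predicted, truth_pos, truth_neg) {
  kp <- pair_key(truth_pos$a, truth_pos$b)
  kn <- pair_key(truth_neg$a, truth_neg$b)
  if (length(intersect(kp, kn))) stop("truth sets are not disjoint")
  pred <- pair_key(predicted$a, predicted$b)
  list(TP = sum(kp %in% pred), FN = sum(!kp %in% pred),
       FP = sum(kn %in% pred), TN = sum(!kn %in% pred))
}

#' @rdname confusion
#' @param counts a confusion-count list.
#' @return sensitivity TP/(TP+FN); `NA` with a warning when undefined.
#' @export
sensitivity <- function(counts) {
  d <- counts$TP + counts$FN
  if (d == 0) { warning("sensitivity undefined: no positives"); return(NA_real_) }
  counts$TP / d
}

#' @rdname confusion
#' @return specificity TN/(TN+FP); `NA` with a warning when undefined.
#' @export
specificity <- function(counts) {
  d <- counts$TN + counts$FP
  if (d == 0) { warning("specificity undefined: no negatives"); return(NA_real_) }
  counts$TN / d
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a random positive outscores
#' a random negative, ties counting one half (midrank formulation), which is
#' invariant under any strictly monotone transform of the scores.
#'
#' @param scores numeric vector of classifier confidences.
#' @param labels 0/1 vector of true classes.
#' @return the AUC in [0,1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pathway-sharing similarity of two annotation sets
#'
#' The Jaccard index: pathways in the intersection over pathways in the
#' union. Proteins without any annotation must be excluded before this point
#' (the network is first narrowed to annotated proteins).
#'
#' @param a_annotations,b_annotations non-empty character sets of pathway ids.
#' @return numeric in [0,1].
#' @export
kegg_similarity <- function(a_annotations, b_annotations) {
  if (!length(a_annotations) || !length(b_annotations))
    stop("annotation sets must be non-empty")
  a <- unique(a_annotations); b <- unique(b_annotations)
  length(intersect(a, b)) / length(union(a, b))
}

#' Annotation probability of every ontology term
#'
#' p(c) = n(c_d) / n_c, where n(c_d) counts annotation occurrences to c or
#' any of its descendants and n_c counts all annotation occurrences in the
#' genome. A gene annotated to two terms inside one subtree counts twice:
#' occurrences, not genes, are counted.
#'
#' @param dag an `"ontology_dag"`.
#' @param annotations named list: gene id -> character vector of term ids.
#' @return named numeric vector of probabilities over `dag$terms`.
#' @export
go_term_probability <- function(dag, annotations) {
  occ <- unlist(annotations, use.names = FALSE)
  occ <- occ[occ %in% dag$terms]
  n_c <- length(occ)
  if (n_c == 0L) stop("no annotation occurrence maps into the ontology")
  direct <- table(factor(occ, levels = dag$terms))
  p <- vapply(dag$terms, function(t) {
    sum(direct[dag_descendants(dag, t)])
  }, numeric(1)) / n_c
  stats::setNames(p, dag$terms)
}

#' Information-content semantic similarity of two ontology terms
#'
#' The shared ancestor with minimal annotation probability p_m is found over
#' the intersection of the two terms' ancestor sets (each term counts as its
#' own ancestor, so sim(c, c) = -ln p(c)); the similarity is -ln(p_m).
#' Shared ancestors with p = 0 carry no information and are dropped with a
#' warning.
#'
#' @param cx,cy term ids.
#' @param dag an `"ontology_dag"`.
#' @param probs output of [go_term_probability()].
#' @return non-negative similarity score.
#' @export
go_similarity <- function(cx, cy, dag, probs) {
  shared <- intersect(dag_ancestors(dag, cx), dag_ancestors(dag, cy))
  if (!length(shared)) stop("terms share no ancestor; ontology lacks a common root")
  p <- probs[shared]
  if (any(p == 0)) {
    warning("shared ancestor(s) with zero annotation probability dropped")
    p <- p[p > 0]
    if (!length(p)) stop("no informative shared ancestor")
  }
  -log(min(p))
}

#' @rdname go_similarity
#' @param a_terms,b_terms term sets of the two proteins.
#' @return maximum similarity over all term cross pairs.
#' @export
protein_go_similarity <- function(a_terms, b_terms, dag, probs) {
  if (!length(a_terms) || !length(b_terms)) stop("term sets must be non-empty")
  max(vapply(a_terms, function(tx)
    max(vapply(b_terms, function(ty) go_similarity(tx, ty, dag, probs),
               numeric(1))), numeric(1)))
}

#' Functional similarity of a network against degree-preserving nulls
#'
#' Narrows the network to proteins carrying at least one annotation, computes
#' the observed similarity statistic, and compares it against the same
#' statistic on degree-preserving randomizations of the narrowed network.
#' Self-interactions are excluded throughout to avoid upward bias.
#'
#' Measures: `"kegg_share"` (fraction of edges whose endpoints share at least
#' one pathway, the default pathway statistic), `"kegg_jaccard"` (mean
#' Jaccard over edges), `"go"` (mean maximal information-content similarity
#' over edges; supply `dag`).
#'
#' @param network a `"ppi_graph"` or data.frame with columns `a`, `b`.
#' @param annotations named list: protein -> term/pathway id set.
#' @param measure similarity statistic, see above.
#' @param dag `"ontology_dag"`, required for `measure = "go"`.
#' @param n_random number of randomized replicates.
#' @param seed integer RNG seed.
#' @return list of class `"similarity_result"`: `observed`, `null_samples`,
#'   `null_range`, `n_random`.
#' @export
functional_similarity_null <- function(network, annotations,
                                       measure = c("kegg_share", "kegg_jaccard", "go"),
                                       dag = NULL, n_random = 100L, seed = 1L) {
  measure <- match.arg(measure)
  edges <- if (inherits(network, "ppi_graph")) network$edges else network
  annotated <- names(annotations)[lengths(annotations) > 0L]
  edges <- edges[edges$a %in% annotated & edges$b %in% annotated &
                   edges$a != edges$b, , drop = FALSE]
  if (!nrow(edges)) stop("annotation restriction empties the network")
  g <- ppi_graph(edges$a, edges$b)
  if (n_random < 10L && n_random > 0L)
    warning("fewer than 10 randomizations: null range is low-power")

  probs <- if (measure == "go") go_term_probability(dag, annotations) else NULL
  stat <- function(ed) {
    vals <- vapply(seq_len(nrow(ed)), function(i) {
      ta <- annotations[[ed$a[i]]]; tb <- annotations[[ed$b[i]]]
      switch(measure,
             kegg_share = as.numeric(length(intersect(ta, tb)) > 0L),
             kegg_jaccard = kegg_similarity(ta, tb),
             go = protein_go_similarity(ta, tb, dag, probs))
    }, numeric(1))
    mean(vals)
  }
  observed <- stat(g$edges)
  null_samples <- if (n_random > 0) vapply(seq_len(n_random), function(r) {
    stat(randomize_preserving_degree(g, seed = seed + r)$edges)
  }, numeric(1)) else numeric(0)
  structure(list(observed = observed, null_samples = null_samples,
                 null_range = if (length(null_samples)) range(null_samples)
                 else c(NA_real_, NA_real_),
                 n_random = n_random, measure = measure),
            class = "similarity_result")
}

#' Co-expression enrichment of a network
#'
#' The observed statistic is the fraction of network edges whose endpoint
#' genes have Pearson correlation above `rho_cut` across the expression
#' samples (edges with an unmeasured gene or identical endpoints are
#' excluded). A bootstrap confidence interval resamples edges with
#' replacement; the null interval comes from recomputing the fraction on
#' degree-preserving randomized networks.
#'
#' @param network a `"ppi_graph"` or edge data.frame (`a`, `b`).
#' @param expr numeric gene x sample matrix with at least 3 samples.
#' @param rho_cut correlation threshold (default 0.5).
#' @param n_boot bootstrap replicates for the CI of the observed fraction
#'   (0 disables the CI).
#' @param n_random degree-preserving null replicates.
#' @param seed integer RNG seed.
#' @return `"similarity_result"` with extra elements `boot_ci` (95% interval
#'   or NULL) and `null_ci`.
#' @export
coexpression_enrichment <- function(network, expr, rho_cut = 0.5,
                                    n_boot = 250L, n_random = 250L, seed = 1L) {
  if (ncol(expr) < 3L) stop("at least 3 expression samples required")
  edges <- if (inherits(network, "ppi_graph")) network$edges else network
  edges <- edges[edges$a %in% rownames(expr) & edges$b %in% rownames(expr) &
                   edges$a != edges$b, , drop = FALSE]
  if (!nrow(edges)) stop("no measurable edges")
  g <- ppi_graph(edges$a, edges$b)

  z <- t(scale(t(expr)))            # row-standardized; NA for constant genes
  edge_cor <- function(ed) {
    rowSums(z[ed$a, , drop = FALSE] * z[ed$b, , drop = FALSE]) / (ncol(expr) - 1)
  }
  frac <- function(ed) {
    r <- edge_cor(ed)
    mean(r > rho_cut, na.rm = TRUE)
  }
  observed <- frac(g$edges)
  res <- .with_seed(seed, {
    boot <- if (n_boot > 0) vapply(seq_len(n_boot), function(i) {
      frac(g$edges[sample.int(nrow(g$edges), replace = TRUE), , drop = FALSE])
    }, numeric(1)) else numeric(0)
    nulls <- if (n_random > 0) vapply(seq_len(n_random), function(r) {
      frac(randomize_preserving_degree(g)$edges)
    }, numeric(1)) else numeric(0)
    list(boot = boot, nulls = nulls)
  })
  structure(list(observed = observed,
                 null_samples = res$nulls,
                 null_range = if (length(res$nulls)) range(res$nulls)
                 else c(NA_real_, NA_real_),
                 n_random = n_random,
                 boot_ci = if (n_boot > 0)
                   stats::quantile(res$boot, c(0.025, 0.975), names = FALSE)
                 else NULL,
                 null_ci = if (n_random > 0)
                   stats::quantile(res$nulls, c(0.025, 0.975), names = FALSE)
                 else NULL,
                 measure = "coexpression"),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat("similarity (", x$measure, "): observed ", format(x$observed, digits = 4),
      "; null range [", format(x$null_range[1], digits = 4), ", ",
      format(x$null_range[2], digits = 4), "] over ", x$n_random,
      " randomizations\n", sep = "")
  invisible(x)
}
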
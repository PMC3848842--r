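test_that("confusion counts and derived rates follow the definitions", {
  pred <- data.frame(a = c("A", "C"), b = c("B", "D"))
  pos <- interaction_set(c("A", "E", "F", "G"), c("B", "X", "Y", "Z"))
  neg <- interaction_set(c("C", "M"), c("D", "N"))
  cm <- confusion(pred, pos, neg)
  expect_equal(cm, list(TP = 1L, FN = 3L, FP = 1L, TN = 1L))
  expect_equal(sensitivity(list(TP = 3, FN = 1)), 0.75)
  expect_equal(specificity(list(TN = 0, FP = 5)), 0)
  expect_warning(v <- sensitivity(list(TP = 0, FN = 0)), "undefined")
  expect_true(is.na(v))
  expect_error(confusion(pred, pos, interaction_set("A", "B")), "disjoint")
})

test_that("AUC equals the Mann-Whitney probability with tie handling", {
  expect_equal(roc_auc(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(0:1, 5)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  set.seed(6)
  for (i in 1:10) {
    sc <- round(stats::runif(40), 1)  # coarse grid forces ties
    lb <- stats::rbinom(40, 1, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb), oracle_auc(sc, lb))
    # invariance under strictly monotone transforms
    expect_equal(roc_auc(exp(3 * sc), lb), roc_auc(sc, lb))
  }
  skip_if_not_installed("pROC")
  set.seed(7)
  sc <- stats::runif(100); lb <- stats::rbinom(100, 1, 0.4)
  expect_equal(roc_auc(sc, lb),
               as.numeric(pROC::auc(pROC::roc(
                 lb, sc, quiet = TRUE, direction = "<",
                 levels = c("0", "1")))))
})

test_that("pathway-sharing similarity is the Jaccard index", {
  expect_equal(kegg_similarity(c("K1", "K2"), c("K2", "K3")), 1 / 3)
  expect_equal(kegg_similarity(c("K1"), c("K1")), 1)
  expect_equal(kegg_similarity("K1", "K9"), 0)
  expect_error(kegg_similarity(character(0), "K1"), "non-empty")
})

test_that("term probabilities count descendant occurrences", {
  dag <- ontology_dag(c("root", "c"), list(root = character(0), c = "root"))
  probs <- go_term_probability(dag, list(g1 = "c", g2 = "root"))
  expect_equal(probs[["root"]], 1)
  expect_equal(probs[["c"]], 0.5)
  # leaf-only annotation still gives every ancestor positive probability
  dag2 <- ontology_dag(c("r", "m", "l"),
                       list(r = character(0), m = "r", l = "m"))
  p2 <- go_term_probability(dag2, list(g1 = "l", g2 = "l"))
  expect_true(all(p2 > 0))
  expect_equal(p2[["m"]], 1)
})

test_that("semantic similarity uses the least-probable shared ancestor", {
  dag <- ontology_dag(c("root", "c"), list(root = character(0), c = "root"))
  probs <- go_term_probability(dag, list(g1 = "c", g2 = "root"))
  # a term is its own ancestor: sim(c,c) = -ln p(c)
  expect_equal(go_similarity("c", "c", dag, probs), -log(0.5))
  # only shared ancestor is the root with p = 1
  dag3 <- ontology_dag(c("r", "x", "y"),
                       list(r = character(0), x = "r", y = "r"))
  p3 <- go_term_probability(dag3, list(g1 = "x", g2 = "y"))
  expect_equal(go_similarity("x", "y", dag3, p3), 0)
  # protein-level score is the max over term cross pairs
  expect_equal(protein_go_similarity(c("x", "r"), c("y", "x"), dag3, p3),
               go_similarity("x", "x", dag3, p3))
})

test_that("similarity is symmetric, non-negative and matches the oracle", {
  for (s in 1:12) {
    toy <- random_toy_dag(s)
    dag <- ontology_dag(toy$ids, toy$parents)
    probs <- go_term_probability(dag, toy$annotations)
    picks <- matrix(sample(toy$ids, 6, replace = TRUE), ncol = 2)
    for (r in seq_len(nrow(picks))) {
      cx <- picks[r, 1]; cy <- picks[r, 2]
      got <- suppressWarnings(go_similarity(cx, cy, dag, probs))
      expect_gte(got, 0)
      expect_equal(got, suppressWarnings(go_similarity(cy, cx, dag, probs)))
      expect_equal(got, oracle_go_sim(toy$parents, toy$annotations, cx, cy))
    }
  }
})

test_that("functional-similarity nulls preserve degrees and flag low power", {
  set.seed(21)
  edges <- data.frame(a = paste0("P", 1:12), b = paste0("P", c(2:12, 1)))
  ann <- lapply(1:12, function(i) paste0("K", (i %% 3) + 1))
  names(ann) <- paste0("P", 1:12)
  res <- functional_similarity_null(edges, ann, "kegg_share",
                                    n_random = 20L, seed = 2L)
  expect_length(res$null_samples, 20L)
  expect_true(res$observed >= 0 && res$observed <= 1)
  expect_warning(functional_similarity_null(edges, ann, "kegg_share",
                                            n_random = 2L, seed = 2L),
                 "low-power")
  # annotation restriction can empty the network
  expect_error(functional_similarity_null(edges, list(Q1 = "K1"), "kegg_share"),
               "empties")
  # jaccard variant bounded by the share frequency
  res_j <- suppressWarnings(
    functional_similarity_null(edges, ann, "kegg_jaccard",
                               n_random = 5L, seed = 2L))
  expect_lte(res_j$observed, res$observed)
})

test_that("co-expression enrichment scores edges against both nulls", {
  set.seed(31)
  genes <- paste0("G", 1:20)
  # two duplicated blocks: perfectly correlated profiles within a block
  base <- matrix(stats::rnorm(2 * 12), 2, 12)
  expr <- base[rep(1:2, each = 10), ] + 0
  rownames(expr) <- genes; colnames(expr) <- paste0("S", 1:12)
  edges <- data.frame(a = genes[c(1, 3, 11, 13)], b = genes[c(2, 4, 12, 14)])
  res <- coexpression_enrichment(edges, expr, n_boot = 20L, n_random = 20L,
                                 seed = 5L)
  expect_equal(res$observed, 1)

  # i.i.d. noise: observed within the null range
  expr_n <- matrix(stats::rnorm(20 * 30), 20, 30,
                   dimnames = list(genes, paste0("S", 1:30)))
  edges_n <- data.frame(a = genes[1:8], b = genes[9:16])
  res_n <- coexpression_enrichment(edges_n, expr_n, n_boot = 0L,
                                   n_random = 40L, seed = 6L)
  expect_null(res_n$boot_ci)
  expect_gte(res_n$observed, res_n$null_range[1] - 1e-9)
  expect_lte(res_n$observed, res_n$null_range[2] + 1e-9)

  expect_error(coexpression_enrichment(edges, expr[, 1:2]), "3 expression")
  expect_error(coexpression_enrichment(data.frame(a = "Z1", b = "Z2"), expr),
               "measurable")
})
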
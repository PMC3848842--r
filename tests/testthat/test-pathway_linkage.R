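toy_pathways <- function() {
  structure(list(
    PW1 = list(members = c("P1", "P2"), compounds = c("ATP", "CPD1"),
               classes = "CL:A"),
    PW2 = list(members = "P3", compounds = c("CPD1"), classes = "CL:A"),
    PW3 = list(members = c("P4", "P5"), compounds = "CPD9", classes = "CL:B")),
    class = "pathway_set")
}

test_that("inter-pathway counting excludes self-interactions and self-links", {
  ps <- toy_pathways()
  pred <- data.frame(a = c("P1", "P2"), b = c("P3", "P3"))
  cnt <- count_interpathway(pred, ps)
  expect_equal(cnt[[pair_key("PW1", "PW2")]], 2L)

  # a predicted self-edge contributes nothing, even with shared membership
  ps2 <- structure(list(PW1 = list(members = "P1", compounds = character(0),
                                   classes = character(0)),
                        PW2 = list(members = "P1", compounds = character(0),
                                   classes = character(0))),
                   class = "pathway_set")
  cnt2 <- count_interpathway(data.frame(a = "P1", b = "P1"), ps2)
  expect_length(cnt2, 0L)

  # no cross edges: pair absent from the map
  cnt3 <- count_interpathway(data.frame(a = "P1", b = "P2"), ps)
  expect_length(cnt3, 0L)
})

test_that("possible non-self pair counts match explicit enumeration", {
  enum <- function(A, B) {
    ks <- character(0)
    for (p in A) for (q in B) if (p != q) ks <- c(ks, pair_key(p, q))
    length(unique(ks))
  }
  set.seed(17)
  pool <- paste0("x", 1:8)
  for (i in 1:20) {
    A <- sample(pool, sample(1:5, 1)); B <- sample(pool, sample(1:5, 1))
    expect_equal(ppiforest:::.possible_nonself_pairs(A, B), enum(A, B))
  }
})

test_that("planted linkages are retained and the weight is the edge fraction", {
  ps <- structure(list(
    PW1 = list(members = c("P1", "P2"), compounds = c("ATP", "CPD1"),
               classes = "CL:A"),
    PW3 = list(members = c("P4", "P5"), compounds = "CPD9",
               classes = "CL:B")),
    class = "pathway_set")
  # dense support between PW1 and PW3 plus decoy edges among unannotated
  # proteins, so the rewiring null can scatter the cross-pathway edges
  decoy <- data.frame(a = paste0("Q", 1:6), b = paste0("Q", 7:12))
  pred <- rbind(data.frame(a = c("P1", "P1", "P2", "P2"),
                           b = c("P4", "P5", "P4", "P5")), decoy)
  pred$score <- 1
  lk <- significant_linkages(pred, ps, n_random = 60L, quantile = 0.9,
                             seed = 3L)
  expect_equal(nrow(lk$links), 1L)
  expect_equal(pair_key(lk$links$a, lk$links$b), pair_key("PW1", "PW3"))
  expect_equal(lk$links$n_interactions, 4L)
  expect_equal(lk$links$weight, 1)      # 4 of 4 possible
  expect_false(lk$links$shares_compound)
  expect_true(all(lk$links$weight >= 0 & lk$links$weight <= 1))
})

test_that("the retained set shrinks as the quantile rises", {
  set.seed(41)
  prot <- paste0("P", 1:40)
  ps <- structure(lapply(split(prot, rep(1:8, each = 5)), function(m)
    list(members = m, compounds = character(0), classes = character(0))),
    class = "pathway_set")
  names(ps) <- paste0("PW", 1:8)
  pred <- data.frame(a = sample(prot, 60, replace = TRUE),
                     b = sample(prot, 60, replace = TRUE))
  pred <- pred[pred$a != pred$b, ]
  lo <- significant_linkages(pred, ps, n_random = 80L, quantile = 0.5,
                             seed = 9L)
  hi <- significant_linkages(pred, ps, n_random = 80L, quantile = 0.99,
                             seed = 9L)
  expect_true(all(pair_key(hi$links$a, hi$links$b) %in%
                    pair_key(lo$links$a, lo$links$b)))
})

test_that("compound sharing discounts ubiquitous compounds", {
  # ATP in >2 pathways is discounted with max_pathways_per_compound = 2
  ps <- structure(list(
    PW1 = list(members = c("P1", "P2"), compounds = c("ATP", "CPDX"),
               classes = character(0)),
    PW2 = list(members = c("P3", "P4"), compounds = c("ATP", "CPDX"),
               classes = character(0)),
    PW3 = list(members = c("P5", "P6"), compounds = "ATP",
               classes = character(0)),
    PW4 = list(members = c("P7", "P8"), compounds = "CPDZ",
               classes = character(0))),
    class = "pathway_set")
  links <- data.frame(a = c("PW1", "PW1"), b = c("PW2", "PW3"),
                      n_interactions = c(3L, 3L), n_null_ge = 0L,
                      weight = 0.5, shares_compound = NA)
  lk <- structure(list(links = links,
                       graph = ppi_graph(links$a, links$b,
                                         nodes = names(ps)),
                       n_random = 0L, quantile = 0.999),
                  class = "linkage_network")
  res <- compound_sharing_test(lk, ps, max_pathways_per_compound = 2L,
                               n_random = 50L, seed = 2L)
  expect_equal(res$n_sharing, 1L)   # only PW1-PW2 via CPDX; ATP discounted
  expect_gte(res$p, 1 / 51)
  expect_lte(res$p, 1)
})

test_that("enrichment p-values match the closed cases and reject impossibles", {
  expect_equal(enrichment_p(2, 2, 5, 10), 10 / 45)
  expect_equal(enrichment_p(0, 3, 4, 10), 1)
  expect_error(enrichment_p(5, 2, 5, 10), "impossible")
  expect_error(enrichment_p(1, 2, 5, 4), "impossible")
  for (s in 1:15) {
    set.seed(s)
    M_tot <- sample(4:10, 1); M_t <- sample(1:M_tot, 1)
    M_g <- sample(1:M_tot, 1); M_gt <- sample(0:min(M_g, M_t), 1)
    expect_equal(enrichment_p(M_gt, M_g, M_t, M_tot),
                 oracle_enrichment_p(M_gt, M_g, M_t, M_tot),
                 tolerance = 1e-12)
  }
})

test_that("cluster enrichment propagates annotations up the ontology", {
  dag <- ontology_dag(c("R", "A", "B", "a1", "b1"),
                      list(R = character(0), A = "R", B = "R",
                           a1 = "A", b1 = "B"))
  ps <- structure(list(
    PW1 = list(members = "P1", compounds = character(0), classes = "a1"),
    PW2 = list(members = "P2", compounds = character(0), classes = "a1"),
    PW3 = list(members = "P3", compounds = character(0), classes = "b1"),
    PW4 = list(members = "P4", compounds = character(0), classes = "b1")),
    class = "pathway_set")
  enr <- cluster_enrichment(list(c("PW1", "PW2"), c("PW3", "PW4")), dag, ps)
  expect_true(all(enr$M_gt <= pmin(enr$M_g, enr$M_t)))
  expect_true(all(enr$p > 0 & enr$p <= 1))
  # each pathway annotates 3 nodes (class, its parent, root): M_tot = 12
  expect_equal(unique(enr$M_tot), 12L)
  # branch A annotations concentrate in cluster 1
  row <- enr[enr$cluster == 1 & enr$term == "a1", ]
  expect_equal(row$M_gt, 2L)
  expect_equal(row$M_t, 2L)
  # significance uses the Bonferroni cut-off alpha/(n_C * n_O)
  expect_equal(enr$significant, enr$p <= 0.05 / (2 * 5))
})
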
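test_that("degree centrality covers star, path and isolated nodes", {
  star <- ppi_graph(rep("hub", 4), paste0("s", 1:4))
  expect_equal(degree_centrality(star, "hub"), 1)
  path3 <- ppi_graph(c("a", "b"), c("b", "c"))
  expect_equal(degree_centrality(path3, "a"), 0.5)
  iso <- ppi_graph("a", "b", nodes = c("a", "b", "z"))
  expect_equal(degree_centrality(iso, "z"), 0)
  expect_error(degree_centrality(path3, "nope"), "not in graph")
})

test_that("edge randomization conserves the degree sequence exactly", {
  set.seed(3)
  g <- random_graph_degree_proportional(
    stats::setNames(rep(3, 30), paste0("n", 1:30)), 40, seed = 3)
  d0 <- sort(graph_degree(g))
  for (r in 1:20) {
    rg <- randomize_preserving_degree(g, seed = r)
    expect_identical(sort(graph_degree(rg)), d0)
    k <- pair_key(rg$edges$a, rg$edges$b)
    expect_false(any(duplicated(k)))
    expect_false(any(rg$edges$a == rg$edges$b))
  }
})

test_that("a triangle cannot be rewired", {
  tri <- ppi_graph(c("a", "a", "b"), c("b", "c", "c"))
  rg <- randomize_preserving_degree(tri, seed = 1)
  expect_setequal(pair_key(rg$edges$a, rg$edges$b),
                  pair_key(tri$edges$a, tri$edges$b))
})

test_that("edge overlap with the original declines with more swaps", {
  g <- random_graph_degree_proportional(
    stats::setNames(rep(4, 40), paste0("n", 1:40)), 80, seed = 11)
  k0 <- pair_key(g$edges$a, g$edges$b)
  overlap <- function(f) mean(vapply(1:10, function(r) {
    rg <- randomize_preserving_degree(g, n_swaps_factor = f, seed = 50 + r)
    mean(pair_key(rg$edges$a, rg$edges$b) %in% k0)
  }, numeric(1)))
  expect_lt(overlap(10L), overlap(1L))
})

test_that("degree-proportional sampling respects the template", {
  tmpl <- stats::setNames(c(4, 4, 4, 4, 0), paste0("n", 1:5))
  g <- random_graph_degree_proportional(tmpl, 3, seed = 2)
  expect_false("n5" %in% c(g$edges$a, g$edges$b))
  expect_equal(nrow(g$edges), 3L)
  # forced complete graph
  gc <- random_graph_degree_proportional(tmpl[1:3], 3, seed = 2)
  expect_equal(nrow(gc$edges), 3L)
  # uniform template: endpoint frequencies uniform within sampling error
  tmpl2 <- stats::setNames(rep(1, 6), paste0("u", 1:6))
  counts <- table(unlist(lapply(1:2000, function(r) {
    g <- random_graph_degree_proportional(tmpl2, 1, seed = 1e6 + r)
    c(g$edges$a, g$edges$b)
  })))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
  expect_error(random_graph_degree_proportional(tmpl2, 100, seed = 1),
               "complete graph")
})

test_that("MCL separates disconnected and bridged dense modules", {
  two_tri <- ppi_graph(c("a", "a", "b", "x", "x", "y"),
                       c("b", "c", "c", "y", "z", "z"))
  cl <- mcl_cluster(two_tri)
  expect_length(cl, 2L)
  expect_setequal(cl[[1]], c("a", "b", "c"))
  expect_setequal(cl[[2]], c("x", "y", "z"))

  expect_equal(mcl_cluster(ppi_graph("a", "b")), list(c("a", "b")))

  # two 6-cliques joined by one bridge edge split at the bridge
  cl6 <- function(p) t(utils::combn(paste0(p, 1:6), 2))
  e <- rbind(cl6("L"), cl6("R"), c("L1", "R1"))
  g <- ppi_graph(e[, 1], e[, 2])
  cl <- mcl_cluster(g, inflation = 2)
  expect_length(cl, 2L)
  expect_setequal(cl[[which(vapply(cl, function(x) "L2" %in% x, logical(1)))]],
                  paste0("L", 1:6))
})

test_that("MCL is deterministic and assigns every node once", {
  set.seed(9)
  g <- random_graph_degree_proportional(
    stats::setNames(rep(3, 20), paste0("n", 1:20)), 30, seed = 9)
  c1 <- mcl_cluster(g); c2 <- mcl_cluster(g)
  expect_identical(c1, c2)
  all_nodes <- unlist(c1)
  expect_setequal(all_nodes, g$nodes)
  expect_false(any(duplicated(all_nodes)))
})

test_that("connected components partition by reachability", {
  expect_equal(connected_components(ppi_graph(character(0), character(0))),
               list())
  g <- ppi_graph(c("a", "b", "x"), c("b", "c", "y"))
  cc <- connected_components(g)
  expect_equal(lengths(cc), c(3L, 2L))
  g2 <- ppi_graph(c("a", "b", "x", "c"), c("b", "c", "y", "x"))
  expect_length(connected_components(g2), 1L)
})
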
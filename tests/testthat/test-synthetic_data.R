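test_that("the generator is fully deterministic under a seed", {
  cfg <- sim_config(n_proteins = 50L, n_true_interactions = 80L, seed = 31L)
  a <- simulate_proteome(cfg); b <- simulate_proteome(cfg)
  expect_identical(a, b)
  na <- simulate_interactions(a, cfg); nb <- simulate_interactions(b, cfg)
  expect_identical(na, nb)
  expect_identical(simulate_annotations(a, na, cfg),
                   simulate_annotations(b, nb, cfg))
})

test_that("localization archetypes collapse at zero noise", {
  cfg <- sim_config(n_proteins = 40L, loc_noise = 0, seed = 8L)
  prot <- simulate_proteome(cfg)
  comp <- prot$compartment
  k <- comp[comp == comp[[1]]]
  rows <- prot$loc[names(k), , drop = FALSE]
  expect_true(all(apply(rows, 2, function(col) max(col) - min(col) == 0)))
})

test_that("a scalar domain count fixes every protein's domain number", {
  cfg <- sim_config(n_proteins = 30L, domains_per_protein = 2L, seed = 9L)
  prot <- simulate_proteome(cfg)
  expect_true(all(lengths(prot$proteome) == 2L))
})

test_that("zero planted strengths give a flat edge-probability null", {
  cfg <- sim_config(n_proteins = 40L, affinity_strength = 0, loc_strength = 0,
                    n_true_interactions = 60L, seed = 12L)
  prot <- simulate_proteome(cfg)
  net <- simulate_interactions(prot, cfg)
  expect_equal(max(net$prob) - min(net$prob), 0)
  expect_equal(sum(net$prob), 60, tolerance = 1e-5)
})

test_that("pairs carrying a planted affinity are enriched among true edges", {
  cfg <- sim_config(seed = 23L)
  prot <- simulate_proteome(cfg)
  net <- simulate_interactions(prot, cfg)
  ids <- names(prot$proteome)
  pairs <- enumerate_candidate_pairs(ids, include_self = FALSE)
  aff <- net$affinity
  carries <- vapply(seq_len(nrow(pairs)), function(i) {
    da <- prot$proteome[[pairs$a[i]]]; db <- prot$proteome[[pairs$b[i]]]
    any(aff[da, db, drop = FALSE] > 0)
  }, logical(1))
  edge <- pair_key(pairs$a, pairs$b) %in%
    pair_key(net$interactions$a, net$interactions$b)
  rate_carrier <- mean(edge[carries]); rate_other <- mean(edge[!carries])
  expect_gt(rate_carrier / rate_other, 2)
})

test_that("the misspecified motif mode carries no domain signal", {
  cfg <- sim_config(n_proteins = 60L, n_true_interactions = 120L,
                    interaction_mode = "motif", seed = 44L)
  prot <- simulate_proteome(cfg)
  net <- simulate_interactions(prot, cfg)
  expect_gt(nrow(net$interactions), 0L)
  # probabilities no longer track the affinity matrix
  ids <- names(prot$proteome)
  pairs <- enumerate_candidate_pairs(ids, include_self = FALSE)
  aff_sum <- vapply(seq_len(nrow(pairs)), function(i) {
    da <- prot$proteome[[pairs$a[i]]]; db <- prot$proteome[[pairs$b[i]]]
    sum(net$affinity[da, db])
  }, numeric(1))
  expect_lt(abs(suppressWarnings(
    cor(aff_sum, net$prob[pair_key(pairs$a, pairs$b)], method = "spearman"))),
    0.1)
})

test_that("written bundles round-trip through the package readers", {
  dir <- file.path(tempdir(), "simbundle")
  cfg <- sim_config(n_proteins = 40L, n_true_interactions = 60L,
                    n_diseases = 6L, seed = 61L)
  sim <- simulate_bundle(cfg, dir)
  prot2 <- read_protein_domains(file.path(dir, "domains.tsv"))
  expect_identical(prot2, sim$prot$proteome)
  loc2 <- read_localization(file.path(dir, "localization.tsv"))
  expect_equal(loc2, sim$prot$loc, tolerance = 1e-12)
  ints2 <- read_interactions(file.path(dir, "interactions.tsv"),
                             source_label = "simulated")
  expect_equal(ints2, sim$net$interactions)
  ps2 <- read_pathways(file.path(dir, "pathway_members.tsv"),
                       file.path(dir, "pathway_compounds.tsv"),
                       file.path(dir, "pathway_classes.tsv"))
  expect_equal(lapply(ps2, `[[`, "members"),
               lapply(sim$ann$pathways, `[[`, "members"))
  dag2 <- read_ontology(file.path(dir, "go.obo"))
  expect_setequal(dag2$terms, sim$ann$go_dag$terms)
  dis2 <- read_diseases(file.path(dir, "disease_genes.tsv"),
                        file.path(dir, "disease_terms.tsv"),
                        file.path(dir, "disease_pmids.tsv"))
  expect_setequal(names(dis2), names(sim$ann$diseases))
  expect_equal(dis2$OMIM0001$p_om, sim$ann$diseases$OMIM0001$p_om)
  dup2 <- read_duplication(file.path(dir, "duplication.tsv"))
  expect_equal(dup2, sim$ann$duplication)
  expr2 <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(expr2, sim$ann$expression, tolerance = 1e-12)
})

test_that("expression signal follows the edge-correlation knob", {
  cfg_on <- sim_config(n_proteins = 60L, n_true_interactions = 150L,
                       expression_edge_cor = 0.9, seed = 71L)
  prot <- simulate_proteome(cfg_on)
  net <- simulate_interactions(prot, cfg_on)
  ann <- simulate_annotations(prot, net, cfg_on)
  res <- coexpression_enrichment(net$interactions[c("a", "b")],
                                 ann$expression, n_boot = 0L, n_random = 30L,
                                 seed = 5L)
  expect_gt(res$observed, res$null_range[2])

  cfg_off <- sim_config(n_proteins = 60L, n_true_interactions = 150L,
                        expression_edge_cor = 0, pathway_coherence = 0,
                        seed = 72L)
  prot0 <- simulate_proteome(cfg_off)
  net0 <- simulate_interactions(prot0, cfg_off)
  ann0 <- simulate_annotations(prot0, net0, cfg_off)
  res0 <- coexpression_enrichment(net0$interactions[c("a", "b")],
                                  ann0$expression, n_boot = 0L,
                                  n_random = 30L, seed = 5L)
  expect_lte(res0$observed, res0$null_range[2])
})
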
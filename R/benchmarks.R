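# End-to-end planted-signal workflows: the full pipeline run on synthetic
# proteomes with known ground truth. These back the package's positive- and
# negative-control experiments and the reproduction script.

#' Planted-signal classification benchmark
#'
#' Runs the complete training protocol on one synthetic proteome: simulate a
#' proteome with planted domain-affinity and co-localization signal, reserve
#' a held-out test split before any odds counting, compute the domain-pair
#' LOD table, build forward/reversed design matrices, train the forest and
#' score (i) the held-out positives against sampled non-interacting pairs
#' and (ii) a random sample of candidate pairs against their generative
#' probabilities.
#'
#' @param seed integer seed driving every stochastic step.
#' @param cfg a [sim_config()]; defaults to the generator defaults at this
#'   seed.
#' @param n_test held-out interacting pairs (excluded from odds and
#'   training).
#' @param neg_ratio negatives per positive in training.
#' @param n_test_neg sampled non-interacting test pairs.
#' @param n_spearman_pairs candidate pairs scored against generative
#'   probabilities.
#' @param n_trees forest size.
#' @return list with `auc` (held-out ROC area), `spearman` (rank correlation
#'   of forest score with generative probability), `n_train_pos`,
#'   `n_test_pos`, `n_test_neg`, `forest`, and the simulated tables.
#' @export
planted_classification_benchmark <- function(seed,
                                             cfg = sim_config(seed = seed),
                                             n_test = 100L, neg_ratio = 10L,
                                             n_test_neg = 1900L,
                                             n_spearman_pairs = 2000L,
                                             n_trees = 400L) {
  prot <- simulate_proteome(cfg)
  net <- simulate_interactions(prot, cfg)
  dom_tab <- simulate_domain_evidence(net$affinity, seed = cfg$seed + 3L)
  key <- pair_key(dom_tab$d1, dom_tab$d2)
  merged <- tapply(dom_tab$conf, key, max)
  domine <- structure(as.numeric(merged), names = names(merged),
                      class = "domine_table")

  sp <- holdout_split(net$interactions, n_test, seed = seed + 10L)
  odds <- compute_lod(count_domain_pairs(sp$odds_set, prot$proteome))
  ids <- names(prot$proteome)
  npos <- nrow(sp$odds_set)
  tcfg <- training_config(n_pos_train = npos, n_neg_random = neg_ratio * npos,
                          n_neg_spiked = max(1L, npos %/% 10L),
                          n_trees = n_trees, seed = seed + 20L)
  samp <- sample_training_sets(sp$odds_set, ids, cfg = tcfg)
  pairs <- rbind(samp$pos_pairs[c("a", "b")], samp$neg_pairs[c("a", "b")])
  labels <- rep(1:0, c(nrow(samp$pos_pairs), nrow(samp$neg_pairs)))
  design <- build_design_matrix(pairs, labels, prot$proteome, prot$loc,
                                odds, domine)
  forest <- train_forest(design, tcfg)

  known <- pair_key(net$interactions$a, net$interactions$b)
  trained <- pair_key(pairs$a, pairs$b)
  cand <- enumerate_candidate_pairs(ids, include_self = FALSE)
  free <- cand[!pair_key(cand$a, cand$b) %in% c(known, trained), , drop = FALSE]
  negs <- free[.with_seed(seed + 30L,
                          sample.int(nrow(free), min(n_test_neg, nrow(free)))), ]
  test_pairs <- rbind(sp$test_set[c("a", "b")], negs)
  test_labels <- rep(1:0, c(nrow(sp$test_set), nrow(negs)))
  pred <- predict_pairs(forest, test_pairs, prot$proteome, prot$loc, odds,
                        domine, threshold = 0)
  keyed <- stats::setNames(pred$score, pair_key(pred$a, pred$b))
  auc <- roc_auc(unname(keyed[pair_key(test_pairs$a, test_pairs$b)]),
                 test_labels)

  rnd <- cand[.with_seed(seed + 40L,
                         sample.int(nrow(cand), n_spearman_pairs)), ]
  pr <- predict_pairs(forest, rnd, prot$proteome, prot$loc, odds, domine,
                      threshold = 0)
  rho <- stats::cor(pr$score, net$prob[pair_key(pr$a, pr$b)],
                    method = "spearman")
  list(auc = auc, spearman = rho, n_train_pos = npos,
       n_test_pos = nrow(sp$test_set), n_test_neg = nrow(negs),
       forest = forest, prot = prot, net = net, odds = odds, domine = domine)
}

#' Pathway-linkage recovery experiment for one seed
#'
#' Under the null condition (`planted = FALSE`) pathway membership is
#' independent of the network (`pathway_coherence = 0`) and the predictions
#' are background edges only, so any significant linkage is a false
#' positive. Under the planted condition the predictions consist solely of
#' supporting edges between the planted pathway pairs, and recovery means
#' retaining exactly those pairs.
#'
#' @param seed integer seed.
#' @param planted plant linked pathway pairs?
#' @param n_planted_pairs number of planted pathway pairs.
#' @param n_random,quantile significance-test parameters.
#' @return list with `n_significant`, `n_planted`, `n_recovered`,
#'   `n_spurious`.
#' @export
pathway_linkage_experiment <- function(seed, planted = FALSE,
                                       n_planted_pairs = 2L,
                                       n_random = 200L, quantile = 0.995) {
  # 6 pathways keep the candidate-pair space small enough that the ~0.25%
  # per-pair retention floor of the 0.995/200 rule stays negligible
  cfg <- sim_config(seed = seed, pathway_coherence = 0, n_pathways = 6L)
  prot <- simulate_proteome(cfg)
  net <- simulate_interactions(prot, cfg)
  ann <- simulate_annotations(prot, net, cfg)
  pw <- names(ann$pathways)
  planted_pairs <- if (planted)
    data.frame(p1 = pw[seq_len(n_planted_pairs) * 2 - 1],
               p2 = pw[seq_len(n_planted_pairs) * 2])
  else NULL
  pred <- simulate_pathway_signal(ann$pathways, planted_pairs,
                                  n_background = if (planted) 0L else 40L,
                                  proteins = names(prot$proteome),
                                  seed = seed + 1L)
  lk <- significant_linkages(pred, ann$pathways, n_random = n_random,
                             quantile = quantile, seed = seed + 2L)
  got <- pair_key(lk$links$a, lk$links$b)
  want <- if (planted) pair_key(planted_pairs$p1, planted_pairs$p2)
  else character(0)
  list(n_significant = nrow(lk$links),
       n_planted = length(want),
       n_recovered = sum(want %in% got),
       n_spurious = length(setdiff(got, want)))
}

#' Disease-network literature significance experiment for one seed
#'
#' Builds a disease association network from predictions planted across
#' module-coherent disease gene sets, then tests whether the literature
#' similarity of associated disease pairs is stochastically larger than in
#' degree-proportional random networks.
#'
#' @param seed integer seed.
#' @param n_random randomizations for edge retention.
#' @param n_literature_null random disease networks for the KS comparison.
#' @return list with `D`, `p`, `n_links`, `n_components`.
#' @export
disease_network_experiment <- function(seed, n_random = 200L,
                                       n_literature_null = 100L) {
  cfg <- sim_config(seed = seed, n_diseases = 30L)
  prot <- simulate_proteome(cfg)
  net <- simulate_interactions(prot, cfg)
  ann <- simulate_annotations(prot, net, cfg)
  pred <- as.data.frame(net$interactions)[c("a", "b")]
  pred$score <- 1
  obs <- build_disease_network(pred, ann$diseases, n_random = n_random,
                               quantile = 0.9, seed = seed + 2L)
  if (!nrow(obs$links)) return(list(D = NA_real_, p = NA_real_,
                                    n_links = 0L, n_components = 0L))
  sig <- disease_network_significance(obs, ann$diseases,
                                      n = n_literature_null, seed = seed + 3L)
  list(D = sig$D, p = sig$p, n_links = nrow(obs$links),
       n_components = sig$n_components)
}
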
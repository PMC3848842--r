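test_that("training-set sampler honors counts, disjointness and exclusions", {
  pos <- interaction_set(paste0("A", 1:40), paste0("B", 1:40))
  ids <- c(paste0("A", 1:40), paste0("B", 1:40), paste0("C", 1:40))
  cfg <- training_config(n_pos_train = 30L, n_neg_random = 100L,
                         n_neg_spiked = 20L, n_trees = 10L, seed = 4L)
  s <- sample_training_sets(pos, ids, cfg = cfg)
  expect_equal(nrow(s$pos_pairs), 30L)
  expect_equal(nrow(s$neg_pairs), 120L)
  expect_equal(table(s$neg_origin)[["spiked"]], 20L)
  kp <- pair_key(pos$a, pos$b)
  kn <- pair_key(s$neg_pairs$a, s$neg_pairs$b)
  expect_length(intersect(kp, kn), 0L)
  expect_false(any(duplicated(kn)))
  # spiked endpoints come from proteins of the positive set
  spiked <- s$neg_pairs[s$neg_origin == "spiked", ]
  expect_true(all(c(spiked$a, spiked$b) %in% c(pos$a, pos$b)))
  # reproducible
  expect_equal(sample_training_sets(pos, ids, cfg = cfg), s)
})

test_that("spiked endpoint draws are proportional to positive-set degree", {
  # one protein in 10 positive pairs vs 40 proteins in 1 pair each
  pos <- interaction_set(c(rep("HUB", 10), paste0("Z", 1:20)),
                         c(paste0("Y", 1:10), paste0("W", 1:20)))
  ids <- c(unique(c(pos$a, pos$b)), paste0("Q", 1:30))
  cfg <- training_config(n_pos_train = 5L, n_neg_random = 1L,
                         n_neg_spiked = 60L, n_trees = 10L, seed = 8L)
  s <- sample_training_sets(pos, ids, cfg = cfg)
  ends <- c(s$neg_pairs$a, s$neg_pairs$b)[rep(s$neg_origin == "spiked", 2)]
  f_hub <- sum(ends == "HUB")
  f_single <- mean(table(factor(ends[ends != "HUB"],
                                levels = setdiff(unique(c(pos$a, pos$b)),
                                                 "HUB"))))
  # HUB carries 10x the endpoint weight of any single-pair protein
  expect_gt(f_hub / f_single, 4)
})

test_that("candidate-pair enumeration counts n(n+1)/2 with self-pairs", {
  ids <- paste0("P", 1:7)
  expect_equal(nrow(enumerate_candidate_pairs(ids)), 7 * 8 / 2)
  noself <- enumerate_candidate_pairs(ids, include_self = FALSE)
  expect_equal(nrow(noself), 7 * 6 / 2)
  expect_false(any(noself$a == noself$b))
})

test_that("prediction is deterministic, symmetric and thread-invariant", {
  pl <- small_pipeline()
  ids <- names(pl$prot$proteome)
  cand <- enumerate_candidate_pairs(ids[1:25])
  args <- list(pl$forest, cand, pl$prot$proteome, pl$prot$loc, pl$odds,
               pl$domine)
  p1 <- do.call(predict_pairs, c(args, threshold = 0, threads = 1L))
  p4 <- do.call(predict_pairs, c(args, threshold = 0, threads = 4L))
  expect_identical(p1, p4)
  # flipping the input orientation changes nothing (canonical storage + union)
  flipped <- data.frame(a = cand$b, b = cand$a)
  p_rev <- predict_pairs(pl$forest, flipped, pl$prot$proteome, pl$prot$loc,
                         pl$odds, pl$domine, threshold = 0)
  expect_identical(p1$score, p_rev$score)
  expect_true(all(p1$score >= 0 & p1$score <= 1))
})

test_that("threshold views are nested across the confidence ladder", {
  pl <- small_pipeline()
  cand <- enumerate_candidate_pairs(names(pl$prot$proteome)[1:30])
  pred <- predict_pairs(pl$forest, cand, pl$prot$proteome, pl$prot$loc,
                        pl$odds, pl$domine, threshold = 0)
  cuts <- c(0.55, 0.65, 0.75, 0.85)
  views <- lapply(cuts, threshold_view, predictions = pred)
  for (i in 2:4) {
    expect_true(all(pair_key(views[[i]]$a, views[[i]]$b) %in%
                      pair_key(views[[i - 1]]$a, views[[i - 1]]$b)))
  }
})

test_that("manifest mismatch between model and inputs is refused", {
  pl <- small_pipeline()
  loc_bad <- pl$prot$loc[, -1]
  expect_error(
    predict_pairs(pl$forest, enumerate_candidate_pairs(names(pl$prot$proteome)[1:5]),
                  pl$prot$proteome, loc_bad, pl$odds, pl$domine),
    "manifest")
})

test_that("label permutation destroys the held-out signal", {
  pl <- small_pipeline()
  d <- pl$design
  perm <- d
  set.seed(99)
  perm$y <- sample(d$y)
  forest0 <- train_forest(perm, training_config(n_trees = 100L, seed = 13L))
  sp <- pl$split
  ids <- names(pl$prot$proteome)
  negs <- enumerate_candidate_pairs(ids, include_self = FALSE)
  known <- pair_key(pl$net$interactions$a, pl$net$interactions$b)
  negs <- negs[!pair_key(negs$a, negs$b) %in% known, ][1:300, ]
  test_pairs <- rbind(sp$test_set[c("a", "b")], negs)
  labs <- rep(1:0, c(nrow(sp$test_set), nrow(negs)))
  pr <- predict_pairs(forest0, test_pairs, pl$prot$proteome, pl$prot$loc,
                      pl$odds, pl$domine, threshold = 0)
  sc <- stats::setNames(pr$score, pair_key(pr$a, pr$b))
  auc <- roc_auc(unname(sc[pair_key(test_pairs$a, test_pairs$b)]), labs)
  expect_lt(abs(auc - 0.5), 0.07)
})

test_that("training refuses one-class labels and reproduces under a seed", {
  pl <- small_pipeline()
  bad <- pl$design; bad$y <- rep(1L, length(bad$y))
  expect_error(train_forest(bad, training_config(n_trees = 10L, seed = 1L)),
               "both classes")
  f1 <- train_forest(pl$design, training_config(n_trees = 50L, seed = 21L))
  f2 <- train_forest(pl$design, training_config(n_trees = 50L, seed = 21L))
  cand <- enumerate_candidate_pairs(names(pl$prot$proteome)[1:10])
  p1 <- predict_pairs(f1, cand, pl$prot$proteome, pl$prot$loc, pl$odds,
                      pl$domine, threshold = 0)
  p2 <- predict_pairs(f2, cand, pl$prot$proteome, pl$prot$loc, pl$odds,
                      pl$domine, threshold = 0)
  expect_identical(p1, p2)
})
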
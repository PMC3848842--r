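# Random-forest training with the degree-proportional spiked-negative
# sampling protocol, and parallel all-pairs scoring of a proteome.
#
# The randomForest import keeps the namespace (and its S3 predict method)
# loaded for models deserialized from disk.
#' @importFrom randomForest randomForest
NULL

#' Training configuration
#'
#' Defaults reproduce the published protocol: 1,330 positive pairs, 101,300
#' uniformly drawn negative pairs, 1,300 spiked negatives whose endpoints are
#' drawn in proportion to their representation among the interacting pairs,
#' and 400 fully grown trees.
#'
#' @param n_pos_train number of positive training pairs.
#' @param n_neg_random number of uniformly drawn negative pairs.
#' @param n_neg_spiked number of degree-proportional spiked negatives.
#' @param n_trees number of trees in the forest.
#' @param seed integer RNG seed.
#' @return list of class `"training_config"`.
#' @export
training_config <- function(n_pos_train = 1330L, n_neg_random = 101300L,
                            n_neg_spiked = 1300L, n_trees = 400L, seed = 1L) {
  stopifnot(n_pos_train > 0, n_neg_random > 0, n_neg_spiked >= 0, n_trees > 0)
  structure(list(n_pos_train = as.integer(n_pos_train),
                 n_neg_random = as.integer(n_neg_random),
                 n_neg_spiked = as.integer(n_neg_spiked),
                 n_trees = as.integer(n_trees),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Sample positive and negative training pairs
#'
#' Positives are drawn uniformly from the supplied verified interactions.
#' Random negatives are unordered pairs of distinct proteome proteins drawn
#' uniformly, rejecting anything in `positives`, `exclusions`, or already
#' drawn. Spiked negatives guard against the classifier keying on the
#' localization profile of well-studied proteins: both endpoints are sampled
#' from the proteins of the positive set with probability proportional to the
#' number of interacting pairs they appear in, again rejecting known or
#' excluded pairs.
#'
#' @param positives an `"interaction_set"` of verified interactions.
#' @param proteome_ids character vector of all protein ids.
#' @param exclusions optional `"interaction_set"` of pairs that must never be
#'   sampled as negatives (e.g. predicted interactions from a pathway
#'   database).
#' @param cfg a [training_config()].
#' @param budget_factor rejection-sampling budget multiplier.
#' @return list with `pos_pairs` and `neg_pairs` (both `"interaction_set"`s,
#'   disjoint) and `neg_origin` (character: "random"/"spiked" per negative).
#' @export
sample_training_sets <- function(positives, proteome_ids, exclusions = NULL,
                                 cfg = training_config(), budget_factor = 1000L) {
  if (cfg$n_pos_train > nrow(positives))
    stop("fewer positives available than n_pos_train")
  forbidden <- pair_key(positives$a, positives$b)
  if (!is.null(exclusions))
    forbidden <- c(forbidden, pair_key(exclusions$a, exclusions$b))
  .with_seed(cfg$seed, {
    pos_idx <- sample.int(nrow(positives), cfg$n_pos_train)
    pos <- interaction_set(positives$a[pos_idx], positives$b[pos_idx],
                           source_label = "training-positives")

    draw_pairs <- function(n, sampler, what) {
      seen <- character(0)
      ea <- character(n); eb <- character(n)
      got <- 0L; tries <- 0L; budget <- budget_factor * max(n, 1L)
      while (got < n) {
        tries <- tries + 1L
        if (tries > budget)
          stop("rejection budget exhausted drawing ", what,
               " negatives; reduce the requested count")
        pick <- sampler()
        if (pick[1] == pick[2]) next
        k <- pair_key(pick[1], pick[2])
        if (k %in% forbidden || k %in% seen) next
        seen <- c(seen, k)
        got <- got + 1L
        ea[got] <- pick[1]; eb[got] <- pick[2]
      }
      forbidden <<- c(forbidden, seen)
      data.frame(a = ea, b = eb, stringsAsFactors = FALSE)
    }

    rand_neg <- draw_pairs(cfg$n_neg_random,
                           function() sample(proteome_ids, 2L), "random")
    pos_proteins <- c(positives$a, positives$b)  # multiplicity = degree weight
    spike_neg <- if (cfg$n_neg_spiked > 0)
      draw_pairs(cfg$n_neg_spiked,
                 function() sample(pos_proteins, 2L), "spiked")
    else data.frame(a = character(0), b = character(0))

    neg <- interaction_set(c(rand_neg$a, spike_neg$a),
                           c(rand_neg$b, spike_neg$b),
                           source_label = "training-negatives")
    list(pos_pairs = pos, neg_pairs = neg,
         neg_origin = rep(c("random", "spiked"),
                          c(nrow(rand_neg), nrow(spike_neg))))
  })
}

#' Train the random-forest interaction classifier
#'
#' Fits an ensemble of fully grown classification trees (`nodesize = 1`, no
#' depth limit) on a design matrix built with forward/reversed duplication.
#' The feature manifest travels with the model; prediction refuses matrices
#' whose manifest differs.
#'
#' @param design output of [build_design_matrix()] with labels.
#' @param cfg a [training_config()]; `n_trees` and `seed` are used here.
#' @return list of class `"trained_forest"` with elements `model`,
#'   `manifest`, `config`, `importance` (mean decrease in Gini per feature).
#' @export
train_forest <- function(design, cfg = training_config()) {
  if (is.null(design$y)) stop("design matrix has no labels")
  y <- factor(design$y, levels = c(0L, 1L))
  if (any(table(y) == 0L)) stop("both classes must be present for training")
  model <- .with_seed(cfg$seed,
    randomForest::randomForest(x = design$x, y = y, ntree = cfg$n_trees,
                               nodesize = 1, importance = FALSE))
  imp <- model$importance[, "MeanDecreaseGini"]
  structure(list(model = model, manifest = design$manifest, config = cfg,
                 importance = sort(imp, decreasing = TRUE)),
            class = "trained_forest")
}

#' Enumerate all candidate pairs of a proteome
#'
#' With self-pairs included this is the n(n+1)/2 comparisons of a
#' whole-genome run; without, n(n-1)/2.
#'
#' @param ids character vector of protein ids.
#' @param include_self include (P, P) pairs?
#' @return data.frame with columns `a`, `b` (canonical order).
#' @export
enumerate_candidate_pairs <- function(ids, include_self = TRUE) {
  ids <- sort(unique(ids))
  n <- length(ids)
  start <- if (include_self) 0L else 1L
  j <- unlist(lapply(seq_len(n), function(k)
    if (k + start <= n) seq.int(k + start, n) else integer(0)),
    use.names = FALSE)
  i <- rep(seq_len(n), times = pmax(n - seq_len(n) - start + 1L, 0L))
  data.frame(a = ids[i], b = ids[j], stringsAsFactors = FALSE)
}

#' Score candidate pairs with a trained forest
#'
#' Each pair is scored in both orientations (forward and
#' localization-swapped) and the final confidence is the union rule: the
#' maximum of the two orientation scores, so that a pair called at a given
#' threshold by either orientation is called by the combined score. `mean`
#' combination is available behind a flag. Work is split into deterministic
#' chunks merged in fixed order, so the result is independent of `threads`.
#'
#' @param forest a `"trained_forest"`.
#' @param candidate_pairs data.frame with columns `a`, `b`.
#' @param proteome,loc,odds,domine feature-building tables.
#' @param threshold retain only pairs with confidence >= threshold.
#' @param threads number of worker processes.
#' @param combine `"max"` (union rule, default) or `"mean"`.
#' @param allow_missing_loc passed to the feature builder.
#' @return data.frame `a`, `b`, `score`, class `"prediction_set"`, sorted by
#'   pair key; also records skipped unknown-protein pairs in attribute
#'   `n_skipped`.
#' @export
predict_pairs <- function(forest, candidate_pairs, proteome, loc, odds, domine,
                          threshold = 0, threads = 1L,
                          combine = c("max", "mean"),
                          allow_missing_loc = FALSE) {
  combine <- match.arg(combine)
  stopifnot(inherits(forest, "trained_forest"))
  known <- candidate_pairs$a %in% names(proteome) &
    candidate_pairs$b %in% names(proteome)
  n_skipped <- sum(!known)
  if (n_skipped) warning(n_skipped, " pair(s) skipped: unknown protein id")
  cp <- candidate_pairs[known, , drop = FALSE]
  if (!nrow(cp)) stop("no scoreable candidate pairs")

  score_chunk <- function(idx) {
    design <- build_design_matrix(cp[idx, , drop = FALSE], labels = NULL,
                                  proteome = proteome, loc = loc, odds = odds,
                                  domine = domine,
                                  allow_missing_loc = allow_missing_loc)
    if (!identical(design$manifest, forest$manifest))
      stop("feature manifest mismatch between model and inputs")
    p <- stats::predict(forest$model, design$x, type = "prob")[, "1"]
    fwd <- p[seq(1L, length(p), by = 2L)]
    rev <- p[seq(2L, length(p), by = 2L)]
    if (combine == "max") pmax(fwd, rev) else (fwd + rev) / 2
  }

  threads <- max(1L, as.integer(threads))
  chunks <- split(seq_len(nrow(cp)),
                  ceiling(seq_len(nrow(cp)) / ceiling(nrow(cp) / (4L * threads))))
  scores_list <- if (threads == 1L) lapply(chunks, score_chunk)
  else parallel::mclapply(chunks, score_chunk, mc.cores = threads,
                          mc.preschedule = TRUE)
  scores <- unlist(scores_list, use.names = FALSE)

  out <- canonical_pairs(cp$a, cp$b)
  out$score <- scores
  out <- out[out$score >= threshold, , drop = FALSE]
  out <- out[order(pair_key(out$a, out$b)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("prediction_set", "data.frame"),
            n_skipped = n_skipped, threshold = threshold)
}

#' Threshold view of a prediction set
#' @param predictions a `"prediction_set"`.
#' @param threshold confidence cut-off in [0,1].
#' @return the subset with `score >= threshold`, still a `"prediction_set"`.
#' @export
threshold_view <- function(predictions, threshold) {
  out <- predictions[predictions$score >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}

#' Read / write prediction sets
#' @param path TSV path with columns protein1, protein2, confidence.
#' @return a `"prediction_set"`.
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          col.names = c("a", "b", "score"))
  out <- canonical_pairs(df$a, df$b)
  out$score <- df$score
  structure(out, class = c("prediction_set", "data.frame"))
}

#' @rdname read_predictions
#' @param predictions a `"prediction_set"`.
#' @export
write_predictions <- function(predictions, path) {
  df <- data.frame(protein1 = predictions$a, protein2 = predictions$b,
                   confidence = format(predictions$score, digits = 17))
  write_pair_table(df, path)
}
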
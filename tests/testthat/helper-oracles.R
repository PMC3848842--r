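# Independent brute-force oracles and tiny fixture builders used across the
# suite. Oracles deliberately share no code with the implementation paths
# they check.

# --- brute-force domain-pair odds ------------------------------------------
# Materializes every cross combination explicitly with nested loops and
# string keys, then applies the frequency definitions directly.
oracle_lod <- function(pairs_a, pairs_b, proteome) {
  key <- function(x, y) paste(sort(c(x, y)), collapse = "|")
  pair_counts <- list()
  for (i in seq_along(pairs_a)) {
    da <- proteome[[pairs_a[i]]]; db <- proteome[[pairs_b[i]]]
    combos <- character(0)
    for (dx in da) for (dy in db) combos <- c(combos, key(dx, dy))
    for (k in unique(combos)) {
      pair_counts[[k]] <- (if (is.null(pair_counts[[k]])) 0 else pair_counts[[k]]) + 1
    }
  }
  members <- unique(c(pairs_a, pairs_b))
  domain_counts <- list()
  for (p in members) for (d in unique(proteome[[p]])) {
    domain_counts[[d]] <- (if (is.null(domain_counts[[d]])) 0 else domain_counts[[d]]) + 1
  }
  np <- sum(unlist(pair_counts)); nd <- sum(unlist(domain_counts))
  lod <- list()
  for (k in names(pair_counts)) {
    ds <- strsplit(k, "|", fixed = TRUE)[[1]]
    f_pair <- pair_counts[[k]] / np
    lod[[k]] <- log(f_pair / ((domain_counts[[ds[1]]] / nd) *
                                (domain_counts[[ds[2]]] / nd)))
  }
  list(pair_counts = pair_counts, domain_counts = domain_counts,
       np = np, nd = nd, lod = lod,
       lookup = function(x, y) {
         v <- lod[[key(x, y)]]
         if (is.null(v)) 0 else v
       })
}

# random toy instance for odds oracle checks
random_toy_instance <- function(seed) {
  set.seed(seed)
  n_prot <- sample(3:10, 1)
  doms <- paste0("D", seq_len(sample(2:5, 1)))
  proteome <- lapply(seq_len(n_prot), function(i)
    sample(doms, sample(0:min(3, length(doms)), 1)))
  names(proteome) <- paste0("P", seq_len(n_prot))
  n_int <- sample(2:8, 1)
  a <- sample(names(proteome), n_int, replace = TRUE)
  b <- sample(names(proteome), n_int, replace = TRUE)
  keep <- !duplicated(paste(pmin(a, b), pmax(a, b)))
  list(proteome = proteome, a = a[keep], b = b[keep])
}

# --- O(n^2) AUC oracle ------------------------------------------------------
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (if (p > q) 1 else if (p == q) 0.5 else 0)
  total / (length(pos) * length(neg))
}

# --- exhaustive ontology-similarity oracle ----------------------------------
# Recursive ancestor enumeration straight off the parent lists, and the
# minimal shared-ancestor probability by direct scan.
oracle_ancestors <- function(parents, term) {
  out <- term
  for (p in parents[[term]]) out <- union(out, oracle_ancestors(parents, p))
  out
}

oracle_go_sim <- function(parents, annotations, cx, cy) {
  terms <- names(parents)
  occ <- unlist(annotations, use.names = FALSE)
  desc_count <- function(t) {
    # count occurrences annotated to t or any descendant: scan every term
    sum(vapply(occ, function(o) t %in% oracle_ancestors(parents, o), logical(1)))
  }
  p <- vapply(terms, desc_count, numeric(1)) / length(occ)
  names(p) <- terms
  shared <- intersect(oracle_ancestors(parents, cx), oracle_ancestors(parents, cy))
  pm <- min(p[shared][p[shared] > 0])
  -log(pm)
}

# random toy DAG: a root plus layered terms with random parents in earlier
# layers (guarantees rootedness and acyclicity)
random_toy_dag <- function(seed, max_terms = 30) {
  set.seed(seed)
  n <- sample(5:max_terms, 1)
  ids <- paste0("T", seq_len(n))
  parents <- list()
  parents[[ids[1]]] <- character(0)
  for (i in 2:n) {
    k <- sample(1:min(2, i - 1), 1)
    parents[[ids[i]]] <- sample(ids[seq_len(i - 1)], k)
  }
  genes <- paste0("g", 1:6)
  annotations <- lapply(genes, function(g) sample(ids, sample(1:2, 1)))
  names(annotations) <- genes
  list(ids = ids, parents = parents, annotations = annotations)
}

# --- exhaustive hypergeometric tail ----------------------------------------
# Enumerates every way to choose M_g of M_tot annotations and counts draws
# with at least M_gt on-branch, as an exact ratio of counts.
oracle_enrichment_p <- function(M_gt, M_g, M_t, M_tot) {
  items <- c(rep(1, M_t), rep(0, M_tot - M_t))
  draws <- utils::combn(M_tot, M_g)
  hits <- 0
  for (j in seq_len(ncol(draws)))
    if (sum(items[draws[, j]]) >= M_gt) hits <- hits + 1
  hits / ncol(draws)
}

# --- brute-force one-sided KS ----------------------------------------------
oracle_ks_D <- function(obs, ref) {
  grid <- c(obs, ref)
  D <- 0
  for (x in grid) {
    d <- mean(ref <= x) - mean(obs <= x)
    if (d > D) D <- d
  }
  D
}

# --- small fixture builders -------------------------------------------------
empty_domine <- function() structure(numeric(0), class = "domine_table")

# construct a domain_odds object directly from a named lod vector
# (names like "A|B" with "|" separator for readability)
make_odds <- function(lod_spec) {
  keys <- vapply(strsplit(names(lod_spec), "|", fixed = TRUE), function(d)
    pair_key(d[1], d[2]), character(1))
  structure(list(pair_counts = stats::setNames(rep(1L, length(keys)), keys),
                 domain_counts = integer(0),
                 total_pair_observations = length(keys),
                 total_domain_observations = 0L,
                 lod = stats::setNames(as.numeric(lod_spec), keys)),
            class = "domain_odds")
}

make_domine <- function(conf_spec) {
  keys <- vapply(strsplit(names(conf_spec), "|", fixed = TRUE), function(d)
    pair_key(d[1], d[2]), character(1))
  structure(stats::setNames(as.numeric(conf_spec), keys), class = "domine_table")
}

# uniform localization matrix for fixture proteomes
make_loc <- function(ids, n_feat = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(round(stats::runif(length(ids) * n_feat), 3), nrow = length(ids),
              dimnames = list(ids, paste0("f", seq_len(n_feat))))
  m
}

write_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# shared small simulated pipeline (memoised per session) for tests that need
# a trained forest without re-running the full end-to-end protocol
small_pipeline <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(n_proteins = 60L, n_true_interactions = 120L, seed = 77L)
    prot <- simulate_proteome(cfg)
    net <- simulate_interactions(prot, cfg)
    dom_tab <- simulate_domain_evidence(net$affinity, seed = 80L)
    domine <- read_domine(write_tmp(
      paste(dom_tab$d1, dom_tab$d2, round(dom_tab$conf, 6), sep = "\t")))
    sp <- holdout_split(net$interactions, 30L, seed = 78L)
    odds <- compute_lod(count_domain_pairs(sp$odds_set, prot$proteome))
    npos <- nrow(sp$odds_set)
    tcfg <- training_config(n_pos_train = npos, n_neg_random = 5L * npos,
                            n_neg_spiked = 10L, n_trees = 100L, seed = 79L)
    samp <- sample_training_sets(sp$odds_set, names(prot$proteome), cfg = tcfg)
    pairs <- rbind(samp$pos_pairs[c("a", "b")], samp$neg_pairs[c("a", "b")])
    labels <- rep(1:0, c(nrow(samp$pos_pairs), nrow(samp$neg_pairs)))
    design <- build_design_matrix(pairs, labels, prot$proteome, prot$loc,
                                  odds, domine)
    forest <- train_forest(design, tcfg)
    cache <<- list(cfg = cfg, prot = prot, net = net, domine = domine,
                   split = sp, odds = odds, design = design, forest = forest,
                   train_pairs = pairs)
    cache
  }
})
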
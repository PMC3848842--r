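# Pairwise domain log-of-odds scores learned from interacting protein pairs.
#
# For each unordered domain pair (Dx, Dy) observed across the cross product of
# the two domain sets of an interacting protein pair:
#   f(Dx,Dy) = n(Dx,Dy) / n_p        (n_p = total pair observations)
#   f(Dx)    = n(Dx)    / n_d        (n_d = total domain occurrences among
#                                     proteins appearing in >= 1 interaction)
#   LOD      = ln( f(Dx,Dy) / (f(Dx) * f(Dy)) )
# Domain pairs never observed in any interacting pair score exactly 0.

# Unique unordered domain pairs arising from the cross product of two domain
# sets. Returns a character vector of canonical keys (possibly empty).
.cross_domain_keys <- function(da, db) {
  if (!length(da) || !length(db)) return(character(0))
  g <- expand.grid(da, db, stringsAsFactors = FALSE)
  unique(pair_key(g[[1]], g[[2]]))
}

#' Count domain-pair and domain occurrences over an interaction set
#'
#' For each interacting protein pair (P, Q), every unique unordered domain
#' combination from the cross product domains(P) x domains(Q) increments that
#' pair's count once. Domain occurrences are counted at the set level: over
#' the set of proteins appearing in at least one counted interaction, each
#' protein contributes each of its unique domains once, regardless of how many
#' interactions it appears in. Self-interactions are included.
#'
#' @param interactions an `"interaction_set"` of verified interacting pairs.
#' @param proteome named list mapping protein id to its unique domains
#'   (see [read_protein_domains()]).
#' @return list with `pair_counts` (named integer, canonical domain-pair
#'   keys), `domain_counts` (named integer), `total_pair_observations`,
#'   `total_domain_observations`, and `n_skipped` (interactions whose proteins
#'   were unresolvable).
#' @export
count_domain_pairs <- function(interactions, proteome) {
  if (!nrow(interactions)) stop("empty interaction set: no odds computable")
  known <- interactions$a %in% names(proteome) & interactions$b %in% names(proteome)
  n_skipped <- sum(!known)
  if (n_skipped > 0) {
    warning(n_skipped, " interaction(s) skipped: protein(s) not in proteome")
  }
  ia <- interactions$a[known]; ib <- interactions$b[known]
  if (!length(ia)) stop("no interaction resolvable against the proteome")

  keys <- unlist(lapply(seq_along(ia), function(i) {
    .cross_domain_keys(proteome[[ia[i]]], proteome[[ib[i]]])
  }), use.names = FALSE)
  pair_counts <- if (length(keys)) table(keys) else integer(0)
  pair_counts <- structure(as.integer(pair_counts), names = names(pair_counts))

  members <- unique(c(ia, ib))
  doms <- unlist(proteome[members], use.names = FALSE)  # unique per protein upstream
  domain_counts <- table(doms)
  domain_counts <- structure(as.integer(domain_counts), names = names(domain_counts))

  list(pair_counts = pair_counts,
       domain_counts = domain_counts,
       total_pair_observations = sum(pair_counts),
       total_domain_observations = sum(domain_counts),
       n_skipped = n_skipped)
}

#' Compute the domain-pair log-of-odds table
#'
#' @param counts output of [count_domain_pairs()].
#' @return object of class `"domain_odds"`: the count tables plus `lod`, a
#'   named numeric vector of natural-log odds scores keyed by canonical
#'   domain-pair key. Query with [lod_score()]; absent pairs score 0.
#' @export
compute_lod <- function(counts) {
  np <- counts$total_pair_observations
  nd <- counts$total_domain_observations
  if (np <= 0 || nd <= 0) stop("totals must be positive to compute odds")
  keys <- names(counts$pair_counts)
  parts <- strsplit(keys, "\t", fixed = TRUE)
  d1 <- vapply(parts, `[`, character(1), 1L)
  d2 <- vapply(parts, `[`, character(1), 2L)
  f_pair <- counts$pair_counts / np
  f1 <- counts$domain_counts[d1] / nd
  f2 <- counts$domain_counts[d2] / nd
  lod <- log(f_pair / (f1 * f2))
  names(lod) <- keys
  structure(c(counts, list(lod = lod)), class = "domain_odds")
}

#' Look up log-of-odds scores for domain pairs
#'
#' @param odds a `"domain_odds"` table.
#' @param d1,d2 domain accession vectors (recycled).
#' @return numeric vector; exactly 0 for pairs absent from the table.
#' @export
lod_score <- function(odds, d1, d2) {
  v <- odds$lod[pair_key(d1, d2)]
  v[is.na(v)] <- 0
  unname(v)
}

#' Reserve interactions for testing before odds computation
#'
#' Splits an interaction set into a disjoint (odds, test) partition so that
#' held-out pairs never contribute to domain-pair counting. Reproducible under
#' `seed`.
#'
#' @param interactions an `"interaction_set"`.
#' @param n_test number of pairs to reserve (must be < number of pairs).
#' @param seed integer RNG seed.
#' @return list with `odds_set` and `test_set`, both `"interaction_set"`s.
#' @export
holdout_split <- function(interactions, n_test, seed) {
  n <- nrow(interactions)
  if (n_test >= n) stop("n_test must be smaller than the interaction set")
  idx <- .with_seed(seed, sample.int(n, n_test))
  keep <- setdiff(seq_len(n), idx)
  lab <- attr(interactions, "source_label")
  list(odds_set = interaction_set(interactions$a[keep], interactions$b[keep],
                                  source_label = lab),
       test_set = interaction_set(interactions$a[idx], interactions$b[idx],
                                  source_label = paste0(lab, ":held-out")))
}

# Evaluate an expression under a local RNG seed without disturbing the
# caller's RNG state.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Write / read a domain odds table as a flat TSV
#'
#' Columns: `domain1`, `domain2`, `lod`, `n_pair`. A sidecar of the marginal
#' domain counts and the two totals is written alongside (suffix
#' `.counts.tsv`) so the table round-trips exactly.
#'
#' @param odds a `"domain_odds"` object.
#' @param path output path for the LOD table.
#' @export
write_domain_odds <- function(odds, path) {
  parts <- strsplit(names(odds$lod), "\t", fixed = TRUE)
  df <- data.frame(domain1 = vapply(parts, `[`, character(1), 1L),
                   domain2 = vapply(parts, `[`, character(1), 2L),
                   lod = format(unname(odds$lod), digits = 17),
                   n_pair = unname(odds$pair_counts[names(odds$lod)]))
  write_pair_table(df, path)
  side <- data.frame(domain = names(odds$domain_counts),
                     n = unname(odds$domain_counts))
  side_path <- paste0(path, ".counts.tsv")
  con <- file(side_path, "w")
  writeLines(paste0("# total_pair_observations=", odds$total_pair_observations), con)
  writeLines(paste0("# total_domain_observations=", odds$total_domain_observations), con)
  utils::write.table(side, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_domain_odds
#' @param path path of a LOD table written by `write_domain_odds()`.
#' @return for `read_domain_odds()`, a `"domain_odds"` object.
#' @export
read_domain_odds <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  side_path <- paste0(path, ".counts.tsv")
  hdr <- readLines(side_path, n = 2L)
  np <- as.integer(sub(".*=", "", hdr[1]))
  nd <- as.integer(sub(".*=", "", hdr[2]))
  side <- utils::read.delim(side_path, comment.char = "#", stringsAsFactors = FALSE)
  keys <- pair_key(df$domain1, df$domain2)
  counts <- list(pair_counts = structure(as.integer(df$n_pair), names = keys),
                 domain_counts = structure(as.integer(side$n), names = side$domain),
                 total_pair_observations = np,
                 total_domain_observations = nd,
                 n_skipped = 0L)
  compute_lod(counts)
}
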
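# Turns one ordered protein pair into the fixed-order numeric feature vector
# consumed by the classifier, and batch-builds design matrices with the
# forward/reversed duplication scheme.
#
# Feature families:
#   * domain block (order-invariant): lod_sum, lod_max, lod_min_ceil0,
#     n_pairs_scored, n_pairs_unscored, n_domine_interacting, domine_max_conf
#   * localization block of slot A, then of slot B (order-sensitive)

.DOMAIN_FEATURES <- c("lod_sum", "lod_max", "lod_min_ceil0",
                      "n_pairs_scored", "n_pairs_unscored",
                      "n_domine_interacting", "domine_max_conf")

#' Build the feature vector for one ordered protein pair
#'
#' The unique unordered domain combinations of the pair's cross product are
#' scored against the odds table and the domain-interaction catalogue.
#' Combinations present in the odds table contribute to `lod_sum`, `lod_max`
#' and `lod_min_ceil0` (the minimum scored LOD capped at 0, so the feature
#' never exceeds 0); absent combinations carry the neutral LOD of 0 and are
#' only counted in `n_pairs_unscored`. With no scored combination at all the
#' three LOD features are 0. The localization blocks are taken from the
#' supplied matrix in slot order (a first, b second).
#'
#' @param a,b protein ids (slot A / slot B of the ordered pair).
#' @param proteome named list of unique-domain vectors.
#' @param loc localization matrix (proteins x features).
#' @param odds a `"domain_odds"` table.
#' @param domine a `"domine_table"`.
#' @param allow_missing_loc zero-fill missing localization rows instead of
#'   erroring; adds nothing here, the presence indicator lives in the batch
#'   builder's manifest contract.
#' @return named numeric vector: domain block, then `locA_*`, then `locB_*`.
#' @export
build_pair_features <- function(a, b, proteome, loc, odds, domine,
                                allow_missing_loc = FALSE) {
  da <- proteome[[a]]; db <- proteome[[b]]
  if (is.null(da) || is.null(db)) stop("unknown protein id: ",
                                       if (is.null(da)) a else b)
  keys <- .cross_domain_keys(da, db)
  scored <- keys[keys %in% names(odds$lod)]
  lods <- unname(odds$lod[scored])
  dconf <- if (length(keys)) unclass(domine)[keys] else numeric(0)
  dconf <- dconf[!is.na(dconf)]
  dom <- c(lod_sum = if (length(lods)) sum(lods) else 0,
           lod_max = if (length(lods)) max(lods) else 0,
           lod_min_ceil0 = if (length(lods)) min(0, min(lods)) else 0,
           n_pairs_scored = length(scored),
           n_pairs_unscored = length(keys) - length(scored),
           n_domine_interacting = length(dconf),
           domine_max_conf = if (length(dconf)) max(dconf) else 0)
  la <- .loc_row(loc, a, allow_missing_loc)
  lb <- .loc_row(loc, b, allow_missing_loc)
  c(dom,
    stats::setNames(la, paste0("locA_", colnames(loc))),
    stats::setNames(lb, paste0("locB_", colnames(loc))),
    locA_present = as.numeric(a %in% rownames(loc)),
    locB_present = as.numeric(b %in% rownames(loc)))
}

.loc_row <- function(loc, id, allow_missing) {
  if (id %in% rownames(loc)) return(loc[id, ])
  if (!allow_missing) stop("missing localization features for protein: ", id)
  stats::setNames(numeric(ncol(loc)), colnames(loc))
}

#' Feature names in the frozen order of one run
#' @param loc localization matrix (its column set defines the schema).
#' @return character vector: the feature manifest.
#' @export
feature_manifest <- function(loc) {
  c(.DOMAIN_FEATURES,
    paste0("locA_", colnames(loc)), paste0("locB_", colnames(loc)),
    "locA_present", "locB_present")
}

#' Build a design matrix with forward/reversed pair duplication
#'
#' Every pair enters the matrix twice: once forward and once with the
#' localization blocks of the two proteins swapped (the reversed set). Domain
#' features are order-invariant and identical between the two rows. This
#' duplication prevents the classifier from keying on which protein happens
#' to occupy slot A.
#'
#' @param pairs an `"interaction_set"` (or data.frame with columns `a`, `b`).
#' @param labels 0/1 vector, one per pair (duplicated onto both rows), or
#'   NULL for prediction-time matrices.
#' @inheritParams build_pair_features
#' @return list with `x` (numeric matrix, 2 rows per pair), `y` (labels or
#'   NULL), `row_index` (data.frame pair/a/b/orientation), and `manifest`.
#' @export
build_design_matrix <- function(pairs, labels = NULL, proteome, loc, odds,
                                domine, allow_missing_loc = FALSE) {
  n <- nrow(pairs)
  if (n == 0L) stop("empty pair list")
  if (!is.null(labels) && length(labels) != n)
    stop("labels must match the number of pairs")
  manifest <- feature_manifest(loc)
  x <- matrix(0, nrow = 2L * n, ncol = length(manifest),
              dimnames = list(NULL, manifest))
  for (i in seq_len(n)) {
    fwd <- build_pair_features(pairs$a[i], pairs$b[i], proteome, loc, odds,
                               domine, allow_missing_loc)
    rev <- build_pair_features(pairs$b[i], pairs$a[i], proteome, loc, odds,
                               domine, allow_missing_loc)
    x[2L * i - 1L, ] <- fwd[manifest]
    x[2L * i, ] <- rev[manifest]
  }
  row_index <- data.frame(
    pair = rep(pair_key(pairs$a, pairs$b), each = 2L),
    a = rep(pairs$a, each = 2L), b = rep(pairs$b, each = 2L),
    orientation = rep(c("forward", "reversed"), n),
    stringsAsFactors = FALSE)
  list(x = x,
       y = if (!is.null(labels)) rep(as.integer(labels), each = 2L) else NULL,
       row_index = row_index, manifest = manifest)
}
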
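# Logistic regression of duplicate-gene retention after a whole-genome
# duplication (WGD) on predicted-network topology:
#   retained ~ log(degree centrality) + duplicated-neighbor fraction
#              + their interaction
# with percentile confidence intervals from case-resampling bootstrap. A
# positive duplicated-neighbor coefficient is the signature predicted by the
# gene balance hypothesis: genes whose interaction partners kept their
# duplicates tend to keep theirs.

#' Fraction of a gene's neighbors retained in duplicate
#'
#' @param g a `"ppi_graph"`.
#' @param retained named 0/1 vector: gene -> retention flag. Neighbors
#'   without a flag count as not retained.
#' @param gene a gene id with at least one neighbor.
#' @return numeric in [0,1].
#' @export
duplicated_neighbor_fraction <- function(g, retained, gene) {
  nb <- graph_neighbors(g, gene)
  if (!length(nb)) stop("gene has no neighbors: ", gene)
  flags <- retained[nb]
  flags[is.na(flags)] <- 0
  mean(flags == 1)
}

#' Covariate table for the retention model
#'
#' Restricts to genes present in both the network and the flag table with
#' degree at least `min_degree`, and computes the natural log of degree
#' centrality and the duplicated-neighbor fraction.
#'
#' @inheritParams duplicated_neighbor_fraction
#' @param min_degree drop genes with fewer interactions (the published
#'   analysis fits both 1 and 10). A gene with a single neighbor can only
#'   score 0 or 1 on the duplicated-neighbor fraction, which motivates the
#'   stricter fit.
#' @return data.frame with columns `gene`, `y`, `log_dc`, `dn`.
#' @export
wgd_covariates <- function(g, retained, min_degree = 1L) {
  deg <- graph_degree(g)
  genes <- intersect(names(retained), names(deg)[deg >= max(1L, min_degree)])
  if (!length(genes)) stop("no gene passes the degree filter")
  dc <- degree_centrality(g)[genes]
  dn <- vapply(genes, function(gn) duplicated_neighbor_fraction(g, retained, gn),
               numeric(1))
  data.frame(gene = genes, y = as.integer(retained[genes]),
             log_dc = log(dc), dn = dn,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit the duplicate-retention logistic model with bootstrap CIs
#'
#' Maximum-likelihood logistic fit of
#' `y ~ log_dc + dn + log_dc:dn`, followed by case-resampling bootstrap
#' (genes resampled with replacement; replicates where only one response
#' class survives are redrawn, counted and capped) and percentile confidence
#' intervals at the 95, 99 and 99.9 percent levels. A coefficient earns one
#' star per level whose interval excludes 0.
#'
#' @param g a `"ppi_graph"` (typically the thresholded predicted network).
#' @param retained named 0/1 retention-flag vector for one WGD event.
#' @param min_degree degree filter (1 or 10 in the published analysis).
#' @param n_boot bootstrap replicates (published protocol: 10,000).
#' @param seed integer RNG seed.
#' @return object of class `"wgd_glm"`: `coefficients` (data.frame with
#'   estimate, the six CI bounds and `stars`), `boot` (replicate coefficient
#'   matrix), `n_redrawn`, `fit` (the glm object), `n`, `min_degree`,
#'   `converged`.
#' @export
fit_retention_glm <- function(g, retained, min_degree = 1L, n_boot = 10000L,
                              seed = 1L) {
  dat <- wgd_covariates(g, retained, min_degree)
  fit <- fit_retention_model(dat, n_boot = n_boot, seed = seed)
  fit$min_degree <- min_degree
  fit
}

#' @rdname fit_retention_glm
#' @param dat covariate data.frame with columns `y`, `log_dc`, `dn` (e.g.
#'   from [wgd_covariates()] or [simulate_retention_data()]).
#' @export
fit_retention_model <- function(dat, n_boot = 10000L, seed = 1L) {
  if (length(unique(dat$y)) < 2L)
    stop("both response classes required after degree filtering")
  fit <- stats::glm(y ~ log_dc * dn, family = stats::binomial(), data = dat)
  if (!fit$converged) warning("logistic fit did not converge")
  est <- stats::coef(fit)
  coef_names <- names(est)

  boot <- .with_seed(seed, {
    out <- matrix(NA_real_, nrow = n_boot, ncol = length(est),
                  dimnames = list(NULL, coef_names))
    n_redrawn <- 0L
    for (b in seq_len(n_boot)) {
      for (try in seq_len(20L)) {
        idx <- sample.int(nrow(dat), replace = TRUE)
        if (length(unique(dat$y[idx])) == 2L) break
        n_redrawn <- n_redrawn + 1L
      }
      rb <- suppressWarnings(
        stats::glm(y ~ log_dc * dn, family = stats::binomial(),
                   data = dat[idx, , drop = FALSE]))
      out[b, ] <- stats::coef(rb)
    }
    list(mat = out, n_redrawn = n_redrawn)
  })

  levels <- c(0.95, 0.99, 0.999)
  ci <- lapply(levels, function(lv) {
    apply(boot$mat, 2, stats::quantile,
          probs = c((1 - lv) / 2, 1 - (1 - lv) / 2), na.rm = TRUE)
  })
  stars <- vapply(seq_along(est), function(j) {
    excl <- vapply(ci, function(m) m[1, j] > 0 | m[2, j] < 0, logical(1))
    c("", "*", "**", "***")[1L + sum(excl)]
  }, character(1))
  coefficients <- data.frame(
    term = coef_names, estimate = unname(est),
    ci95_lo = ci[[1]][1, ], ci95_hi = ci[[1]][2, ],
    ci99_lo = ci[[2]][1, ], ci99_hi = ci[[2]][2, ],
    ci999_lo = ci[[3]][1, ], ci999_hi = ci[[3]][2, ],
    stars = stars, stringsAsFactors = FALSE, row.names = NULL)
  structure(list(coefficients = coefficients, boot = boot$mat,
                 n_redrawn = boot$n_redrawn, fit = fit, n = nrow(dat),
                 min_degree = NA_integer_, converged = fit$converged),
            class = "wgd_glm")
}

#' @export
print.wgd_glm <- function(x, ...) {
  cat("duplicate-retention logistic model (n =", x$n,
      ", min degree", x$min_degree, ")\n")
  print(x$coefficients[, c("term", "estimate", "ci95_lo", "ci95_hi", "stars")],
        digits = 4)
  invisible(x)
}

#' Fit the retention model at both published degree filters
#'
#' Convenience wrapper producing the min-degree-1 and min-degree-10 fits for
#' one WGD event.
#'
#' @inheritParams fit_retention_glm
#' @return list with elements `deg1` and `deg10`, each a `"wgd_glm"`.
#' @export
fit_retention_both <- function(g, retained, n_boot = 10000L, seed = 1L) {
  list(deg1 = fit_retention_glm(g, retained, 1L, n_boot, seed),
       deg10 = fit_retention_glm(g, retained, 10L, n_boot, seed))
}
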
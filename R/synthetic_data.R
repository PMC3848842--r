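# Synthetic-data generator: every input table of the pipeline, with
# configurable planted signal, so the whole workflow is buildable and
# testable without any external database.
#
# The generative model mirrors the classifier's two feature families by
# design. A hidden symmetric domain-affinity matrix plays the role the
# domain-pair odds estimate; subcellular co-localization contributes a
# second, weaker term; the interaction probability of a protein pair is a
# logistic function of the two. Downstream annotation tables (pathways, GO
# terms, expression, diseases, duplicate-retention flags) are derived from a
# module structure propagated along the true edges, with one knob per stage
# that switches its planted signal on or off.

#' Simulation configuration
#'
#' @param n_proteins number of proteins in the synthetic proteome.
#' @param n_domains size of the domain vocabulary.
#' @param domains_per_protein integer vector sampled uniformly per protein
#'   (a scalar fixes the count).
#' @param n_true_interactions expected number of true interacting pairs; the
#'   logistic intercept is calibrated to hit it.
#' @param affinity_strength weight of the hidden domain-affinity term.
#' @param affinity_density fraction of domain pairs given a planted affinity.
#' @param loc_strength weight of the co-localization (same compartment) term.
#' @param loc_noise s.d. of per-protein localization noise around the
#'   compartment archetype.
#' @param interaction_mode `"domain"` (default) or `"motif"` — the
#'   misspecified mode in which interactions follow hidden motif labels
#'   invisible to domain features.
#' @param n_pathways,n_compounds,n_diseases,n_samples sizes of the
#'   annotation-side tables.
#' @param pathway_coherence probability in [0,1] that a protein adopts a
#'   true-interaction partner's pathway label (0 = membership independent of
#'   the network, the null of the linkage test).
#' @param pathway_coverage fraction of each module's proteins that carry a
#'   pathway annotation (pathway databases cover a minority of a proteome).
#' @param expression_edge_cor share of expression variance carried by the
#'   module archetype (0 = i.i.d. noise, the null of the co-expression test).
#' @param disease_literature_signal fraction of a disease's PubMed ids drawn
#'   from its module's literature pool (0 = no literature structure).
#' @param wgd_coef named numeric generator coefficients of the retention
#'   model `(intercept, log_dc, dn, interaction)`; default signs follow the
#'   gene-balance expectation: sparser, duplicate-surrounded genes retain.
#' @param seed mandatory integer RNG seed.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_proteins = 200L, n_domains = 40L,
                       domains_per_protein = 1:3,
                       n_true_interactions = 400L,
                       affinity_strength = 2, affinity_density = 0.08,
                       loc_strength = 1, loc_noise = 0.25,
                       interaction_mode = c("domain", "motif"),
                       n_pathways = 12L, n_compounds = 30L,
                       n_diseases = 15L, n_samples = 20L,
                       pathway_coherence = 0.9,
                       pathway_coverage = 0.4,
                       expression_edge_cor = 0.8,
                       disease_literature_signal = 0.8,
                       wgd_coef = c(intercept = -2.2, log_dc = -0.5,
                                    dn = 2, interaction = 0.5),
                       seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_proteins > 1, n_domains > 1, n_true_interactions > 0,
            all(domains_per_protein >= 0))
  structure(list(n_proteins = as.integer(n_proteins),
                 n_domains = as.integer(n_domains),
                 domains_per_protein = as.integer(domains_per_protein),
                 n_true_interactions = as.integer(n_true_interactions),
                 affinity_strength = affinity_strength,
                 affinity_density = affinity_density,
                 loc_strength = loc_strength, loc_noise = loc_noise,
                 interaction_mode = match.arg(interaction_mode),
                 n_pathways = as.integer(n_pathways),
                 n_compounds = as.integer(n_compounds),
                 n_diseases = as.integer(n_diseases),
                 n_samples = as.integer(n_samples),
                 pathway_coherence = pathway_coherence,
                 pathway_coverage = pathway_coverage,
                 expression_edge_cor = expression_edge_cor,
                 disease_literature_signal = disease_literature_signal,
                 wgd_coef = wgd_coef,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.sim_ids <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))

#' Simulate a proteome: domain content and localization features
#'
#' Domains are drawn uniformly from the vocabulary (unique within a
#' protein). Each protein belongs to one of the compartments of the default
#' plant localization schema; its localization vector is the compartment
#' archetype (a dominant compartment probability plus archetype-specific
#' subprogram scores) plus Gaussian noise of s.d. `loc_noise`, so
#' co-localized proteins have similar vectors and zero noise makes them
#' identical.
#'
#' @param cfg a [sim_config()].
#' @return list with `proteome` (`"protein_domains"`), `loc` (matrix),
#'   `compartment` (named integer archetype index per protein).
#' @export
simulate_proteome <- function(cfg) {
  .with_seed(cfg$seed, {
    ids <- .sim_ids("P", cfg$n_proteins)
    dom_ids <- .sim_ids("PF", cfg$n_domains)
    ndom <- if (length(cfg$domains_per_protein) == 1L)
      rep(cfg$domains_per_protein, cfg$n_proteins)
    else sample(cfg$domains_per_protein, cfg$n_proteins, replace = TRUE)
    doms <- lapply(ndom, function(k) sort(sample(dom_ids, min(k, cfg$n_domains))))
    names(doms) <- ids
    proteome <- structure(doms, class = "protein_domains")

    schema <- default_localization_schema("plant")
    n_comp <- 7L  # compartments of the plant schema
    n_sub <- length(schema) - n_comp
    comp <- sample.int(n_comp, cfg$n_proteins, replace = TRUE)
    sub_arch <- matrix(stats::rnorm(n_comp * n_sub), n_comp, n_sub)
    loc <- t(vapply(seq_len(cfg$n_proteins), function(i) {
      pr <- rep(0.3 / (n_comp - 1), n_comp)
      pr[comp[i]] <- 0.7
      v <- c(pr, sub_arch[comp[i], ])
      v + stats::rnorm(length(v), sd = cfg$loc_noise)
    }, numeric(length(schema))))
    dimnames(loc) <- list(ids, schema)
    list(proteome = proteome, loc = loc,
         compartment = stats::setNames(comp, ids))
  })
}

#' Simulate true interactions with planted domain/localization signal
#'
#' A hidden symmetric affinity matrix assigns a positive affinity to a
#' random `affinity_density` fraction of domain pairs. The interaction score
#' of a protein pair is `affinity_strength` times the summed affinity over
#' the cross product of the two domain sets, plus `loc_strength` when the
#' pair shares a compartment; an intercept calibrated so that the expected
#' edge count equals `n_true_interactions` turns scores into probabilities
#' through the logistic function, and edges are drawn Bernoulli. With both
#' strengths 0 every pair has the same probability (the null model). In
#' `"motif"` mode the score instead follows hidden per-protein motif labels,
#' a signal invisible to domain-derived features.
#'
#' @param prot output of [simulate_proteome()].
#' @param cfg the same [sim_config()].
#' @return list with `interactions` (`"interaction_set"` of true edges),
#'   `prob` (named vector of generative probabilities per candidate pair
#'   key), `affinity` (the hidden matrix), `intercept`.
#' @export
simulate_interactions <- function(prot, cfg) {
  .with_seed(cfg$seed + 1L, {
    ids <- names(prot$proteome)
    dom_ids <- .sim_ids("PF", cfg$n_domains)
    aff <- matrix(0, cfg$n_domains, cfg$n_domains,
                  dimnames = list(dom_ids, dom_ids))
    up <- which(upper.tri(aff, diag = TRUE))
    planted <- sample(up, max(1L, round(cfg$affinity_density * length(up))))
    aff[planted] <- stats::rnorm(length(planted), mean = 3, sd = 0.5)
    aff[lower.tri(aff)] <- t(aff)[lower.tri(aff)]

    M <- matrix(0, length(ids), cfg$n_domains, dimnames = list(ids, dom_ids))
    for (i in seq_along(ids)) M[i, prot$proteome[[i]]] <- 1
    S_dom <- M %*% aff %*% t(M)          # ordered cross-product affinity sum

    pairs <- enumerate_candidate_pairs(ids, include_self = FALSE)
    ia <- match(pairs$a, ids); ib <- match(pairs$b, ids)
    score <- cfg$affinity_strength * S_dom[cbind(ia, ib)] +
      cfg$loc_strength * (prot$compartment[pairs$a] == prot$compartment[pairs$b])
    if (cfg$interaction_mode == "motif") {
      motif <- sample.int(8L, length(ids), replace = TRUE)
      score <- 4 * (motif[ia] == motif[ib])
    }
    target <- cfg$n_true_interactions
    intercept <- stats::uniroot(function(cst)
      sum(stats::plogis(score + cst)) - target,
      lower = -50, upper = 50, tol = 1e-10)$root
    prob <- stats::plogis(score + intercept)
    names(prob) <- pair_key(pairs$a, pairs$b)
    edge <- stats::rbinom(length(prob), 1L, prob) == 1L
    list(interactions = interaction_set(pairs$a[edge], pairs$b[edge],
                                        source_label = "simulated"),
         prob = prob, affinity = aff, intercept = intercept)
  })
}

# Module labels propagated along the true edges: with probability
# `coherence` a protein adopts the label of a random true-interaction
# partner, otherwise keeps a uniformly random label. Three sweeps suffice to
# align most of a connected module.
.propagate_modules <- function(ids, edges, n_modules, coherence) {
  lab <- sample.int(n_modules, length(ids), replace = TRUE)
  names(lab) <- ids
  if (coherence <= 0 || !nrow(edges)) return(lab)
  nb <- split(c(edges$b, edges$a), c(edges$a, edges$b))
  for (sweep in 1:3) {
    for (p in sample(ids)) {
      partners <- nb[[p]]
      if (!is.null(partners) && stats::runif(1) < coherence)
        lab[p] <- lab[[sample(partners, 1L)]]
    }
  }
  lab
}

# Small rooted tree ontology: one root, `n_internal` children of the root,
# `n_leaves` leaves attached round-robin to the internal nodes.
.simulate_ontology <- function(prefix, n_internal, n_leaves) {
  root <- paste0(prefix, ":ROOT")
  internal <- sprintf("%s:I%02d", prefix, seq_len(n_internal))
  leaves <- sprintf("%s:L%03d", prefix, seq_len(n_leaves))
  parents <- c(stats::setNames(list(character(0)), root),
               stats::setNames(rep(list(root), n_internal), internal),
               stats::setNames(as.list(internal[(seq_len(n_leaves) - 1L) %%
                                                  n_internal + 1L]), leaves))
  ontology_dag(c(root, internal, leaves), parents)
}

#' Simulate every annotation-side table
#'
#' Pathway membership follows module labels propagated along the true edges
#' (the `pathway_coherence` knob; 0 makes membership independent of the
#' network). Compounds are drawn per pathway, with network-linked pathway
#' pairs sharing one extra compound when coherence is on. GO-style
#' annotations assign each protein its module's leaf term with probability
#' `pathway_coherence`. Expression mixes a per-module archetype with noise
#' according to `expression_edge_cor`. Diseases draw causative genes within
#' one module and PubMed ids partly from a per-module literature pool
#' (`disease_literature_signal`). Retention flags are drawn from the
#' logistic retention model on the true-interaction network with the
#' generator coefficients of `cfg$wgd_coef`.
#'
#' @param prot output of [simulate_proteome()].
#' @param net output of [simulate_interactions()].
#' @param cfg the same [sim_config()].
#' @return list with `pathways` (`"pathway_set"`), `pathway_ontology` and
#'   `go_dag` (`"ontology_dag"`s), `go_annotations` (named list),
#'   `expression` (matrix), `diseases` (`"disease_table"`), `duplication`
#'   (data.frame gene/event/retained), `retained` (named 0/1 vector),
#'   `modules` (named integer).
#' @export
simulate_annotations <- function(prot, net, cfg) {
  .with_seed(cfg$seed + 2L, {
    ids <- names(prot$proteome)
    edges <- net$interactions[c("a", "b")]
    modules <- .propagate_modules(ids, edges, cfg$n_pathways,
                                  cfg$pathway_coherence)

    # pathways: one per module label actually present
    compounds <- .sim_ids("CPD", cfg$n_compounds)
    pathway_ontology <- .simulate_ontology("PCL", 3L, cfg$n_pathways)
    leaves <- grep(":L", pathway_ontology$terms, value = TRUE)
    present <- sort(unique(modules))
    pathways <- lapply(seq_along(present), function(k) {
      m <- present[k]
      mem <- ids[modules == m]
      n_ann <- max(2L, round(cfg$pathway_coverage * length(mem)))
      list(members = sort(sample(mem, min(n_ann, length(mem)))),
           compounds = sort(sample(compounds, 3L)),
           classes = leaves[(m - 1L) %% length(leaves) + 1L])
    })
    names(pathways) <- sprintf("PWY%03d", present)
    class(pathways) <- "pathway_set"

    # GO-style DAG and annotations
    go_dag <- .simulate_ontology("GO", 4L, cfg$n_pathways)
    go_leaves <- grep(":L", go_dag$terms, value = TRUE)
    go_annotations <- lapply(ids, function(p) {
      own <- go_leaves[(modules[[p]] - 1L) %% length(go_leaves) + 1L]
      if (stats::runif(1) < cfg$pathway_coherence) own
      else sample(go_leaves, 1L)
    })
    names(go_annotations) <- ids

    # expression: module archetype + noise
    arch <- matrix(stats::rnorm(cfg$n_pathways * cfg$n_samples),
                   cfg$n_pathways, cfg$n_samples)
    rho <- cfg$expression_edge_cor
    expr <- t(vapply(ids, function(p) {
      sqrt(rho) * arch[modules[[p]], ] +
        sqrt(1 - rho) * stats::rnorm(cfg$n_samples)
    }, numeric(cfg$n_samples)))
    colnames(expr) <- .sim_ids("S", cfg$n_samples)

    # diseases: causative genes within one module. Literature is built by
    # co-citation: every true interaction contributes one shared paper cited
    # by both endpoint genes (with probability = the literature-signal
    # knob), so diseases whose genes interact share literature while
    # unrelated diseases cite disjoint private papers.
    mesh <- .sim_ids("MESH", cfg$n_diseases)
    pool_global <- .sim_ids("PM", 400L)
    sig <- cfg$disease_literature_signal
    prot_pmids <- lapply(ids, function(p) paste0("PMP_", p, "_", 1:2))
    names(prot_pmids) <- ids
    if (nrow(edges)) {
      cocited <- stats::runif(nrow(edges)) < sig
      for (i in which(cocited)) {
        pm <- sprintf("PME%05d", i)
        prot_pmids[[edges$a[i]]] <- c(prot_pmids[[edges$a[i]]], pm)
        prot_pmids[[edges$b[i]]] <- c(prot_pmids[[edges$b[i]]], pm)
      }
    }
    diseases <- lapply(seq_len(cfg$n_diseases), function(d) {
      m <- sample(present, 1L)
      mem <- ids[modules == m]
      genes <- sample(mem, min(4L, length(mem)))
      list(genes = sort(genes), term = mesh[d],
           p_om = stats::runif(1, 1e-4, 0.05),
           pmids = unique(c(unlist(prot_pmids[genes], use.names = FALSE),
                            sample(pool_global, 2L))))
    })
    names(diseases) <- sprintf("OMIM%04d", seq_len(cfg$n_diseases))
    class(diseases) <- "disease_table"

    # duplicate-retention flags from the generator coefficients, two Gibbs
    # sweeps so the duplicated-neighbor fraction feeds back on itself
    g <- ppi_graph(edges$a, edges$b, nodes = ids)
    deg <- graph_degree(g)
    dc <- pmax(deg, 1L) / (length(ids) - 1L)  # floor so log is finite
    b <- cfg$wgd_coef
    retained <- stats::setNames(stats::rbinom(length(ids), 1L, 0.5), ids)
    for (sweep in 1:2) {
      dn <- vapply(ids, function(p) {
        nbg <- graph_neighbors(g, p)
        if (!length(nbg)) 0 else mean(retained[nbg] == 1)
      }, numeric(1))
      eta <- b[["intercept"]] + b[["log_dc"]] * log(dc) + b[["dn"]] * dn +
        b[["interaction"]] * log(dc) * dn
      retained <- stats::setNames(stats::rbinom(length(ids), 1L,
                                                stats::plogis(eta)), ids)
    }
    duplication <- data.frame(gene = ids, event = "alpha",
                              retained = as.integer(retained),
                              stringsAsFactors = FALSE)

    list(pathways = pathways, pathway_ontology = pathway_ontology,
         go_dag = go_dag, go_annotations = go_annotations,
         expression = expr, diseases = diseases,
         duplication = duplication, retained = retained, modules = modules)
  })
}

#' Simulate covariates and response directly from the retention model
#'
#' Draws degrees from a heavy-tailed (negative-binomial) distribution, as in
#' real interactomes, so the log degree centrality spans several units and
#' the interaction term is identifiable; duplicated-neighbor fractions come
#' from a Beta distribution and the response from the logistic model with
#' the supplied coefficients. This is the exogenous generator used for
#' parameter-recovery checks of the retention fit.
#'
#' @param n number of genes.
#' @param coef named coefficients `(intercept, log_dc, dn, interaction)`.
#' @param n_nodes nominal network size fixing the centrality denominator.
#' @param seed integer RNG seed.
#' @return data.frame with columns `gene`, `y`, `log_dc`, `dn`.
#' @export
simulate_retention_data <- function(n, coef, n_nodes = 1000L, seed = 1L) {
  .with_seed(seed, {
    deg <- pmin(1L + stats::rnbinom(n, size = 0.8, mu = 10), n_nodes %/% 3L)
    log_dc <- log(deg / (n_nodes - 1L))
    dn <- stats::rbeta(n, 2, 2)
    eta <- coef[["intercept"]] + coef[["log_dc"]] * log_dc +
      coef[["dn"]] * dn + coef[["interaction"]] * log_dc * dn
    data.frame(gene = .sim_ids("G", n), y = stats::rbinom(n, 1L, stats::plogis(eta)),
               log_dc = log_dc, dn = dn, stringsAsFactors = FALSE)
  })
}

#' Simulate a domain-interaction evidence table from the hidden affinities
#'
#' Emulates a catalogue of known and predicted domain-domain interactions: a
#' noisy view of the planted affinity matrix with `recall` of the planted
#' pairs included (confidence = the logistic-squashed affinity, monotone in
#' the true strength) plus `n_false` spurious low-confidence entries.
#'
#' @param affinity the hidden symmetric affinity matrix of
#'   [simulate_interactions()].
#' @param recall fraction of planted pairs included.
#' @param n_false number of spurious entries on unplanted pairs.
#' @param seed integer RNG seed.
#' @return data.frame `d1`, `d2`, `conf`; pass through [read_domine()] (or
#'   write and re-read) before feature building.
#' @export
simulate_domain_evidence <- function(affinity, recall = 0.7, n_false = 10L,
                                     seed = 1L) {
  .with_seed(seed, {
    idx <- which(upper.tri(affinity, diag = TRUE) & affinity > 0,
                 arr.ind = TRUE)
    keep <- stats::runif(nrow(idx)) < recall
    idx <- idx[keep, , drop = FALSE]
    out <- data.frame(d1 = rownames(affinity)[idx[, 1]],
                      d2 = colnames(affinity)[idx[, 2]],
                      conf = stats::plogis(affinity[idx]),
                      stringsAsFactors = FALSE)
    zero <- which(upper.tri(affinity, diag = TRUE) & affinity == 0,
                  arr.ind = TRUE)
    if (n_false > 0 && nrow(zero)) {
      fi <- zero[sample.int(nrow(zero), min(n_false, nrow(zero))), ,
                 drop = FALSE]
      out <- rbind(out, data.frame(d1 = rownames(affinity)[fi[, 1]],
                                   d2 = colnames(affinity)[fi[, 2]],
                                   conf = stats::runif(nrow(fi), 0.1, 0.4),
                                   stringsAsFactors = FALSE))
    }
    out
  })
}

#' Construct a prediction set with planted pathway linkages
#'
#' Builds an edge list for linkage-recovery experiments: `n_background`
#' edges drawn uniformly over distinct protein pairs, plus `n_per_planted`
#' edges between the member proteins of every planted pathway pair. With
#' `n_per_planted = 0` the pathway-linkage null holds exactly.
#'
#' @param pathways a `"pathway_set"`.
#' @param planted_pairs two-column matrix or data.frame of pathway-id pairs
#'   to link (NULL for none).
#' @param n_background uniform background edges.
#' @param n_per_planted supporting edges per planted pathway pair.
#' @param proteins protein universe the background edges are drawn from;
#'   defaults to the pathway members, but a whole-proteome universe is the
#'   realistic choice when the pathway set covers only part of it.
#' @param seed integer RNG seed.
#' @return `"prediction_set"` with all scores 1.
#' @export
simulate_pathway_signal <- function(pathways, planted_pairs = NULL,
                                    n_background = 40L, n_per_planted = 12L,
                                    proteins = NULL, seed = 1L) {
  .with_seed(seed, {
    all_prot <- if (!is.null(proteins)) sort(unique(proteins))
    else sort(unique(unlist(lapply(pathways, `[[`, "members"),
                            use.names = FALSE)))
    ea <- character(0); eb <- character(0)
    got <- 0L
    seen <- character(0)
    while (got < n_background) {
      pick <- sample(all_prot, 2L)
      k <- pair_key(pick[1], pick[2])
      if (k %in% seen) next
      seen <- c(seen, k); got <- got + 1L
      ea <- c(ea, pick[1]); eb <- c(eb, pick[2])
    }
    if (!is.null(planted_pairs) && nrow(planted_pairs) > 0) {
      for (i in seq_len(nrow(planted_pairs))) {
        A <- setdiff(pathways[[planted_pairs[i, 1]]]$members,
                     pathways[[planted_pairs[i, 2]]]$members)
        B <- setdiff(pathways[[planted_pairs[i, 2]]]$members,
                     pathways[[planted_pairs[i, 1]]]$members)
        for (j in seq_len(n_per_planted)) {
          pa <- sample(A, 1L); pb <- sample(B, 1L)
          k <- pair_key(pa, pb)
          if (k %in% seen) next
          seen <- c(seen, k)
          ea <- c(ea, pa); eb <- c(eb, pb)
        }
      }
    }
    out <- canonical_pairs(ea, eb)
    out$score <- rep(1, nrow(out))
    out <- out[order(pair_key(out$a, out$b)), , drop = FALSE]
    rownames(out) <- NULL
    structure(out, class = c("prediction_set", "data.frame"))
  })
}

#' Write a full simulated input bundle to a directory
#'
#' Emits every table through the package's writers so each file round-trips
#' through the matching reader: protein domains, localization, true
#' interactions, generative edge probabilities, a domain-interaction
#' confidence table derived from the hidden affinity matrix, pathway tables,
#' both ontologies, GO annotations, expression, disease tables and
#' duplicate-retention flags.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list of generated objects.
#' @export
simulate_bundle <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prot <- simulate_proteome(cfg)
  net <- simulate_interactions(prot, cfg)
  ann <- simulate_annotations(prot, net, cfg)
  p <- function(f) file.path(dir, f)
  write_protein_domains(prot$proteome, p("domains.tsv"))
  write_localization(prot$loc, p("localization.tsv"))
  write_interactions(net$interactions, p("interactions.tsv"))
  write_pair_table(data.frame(pair = names(net$prob),
                              prob = format(net$prob, digits = 17)),
                   p("edge_probabilities.tsv"))
  dom_tab <- simulate_domain_evidence(net$affinity, seed = cfg$seed + 3L)
  writeLines(paste(dom_tab$d1, dom_tab$d2, round(dom_tab$conf, 6), sep = "\t"),
             p("domine.tsv"))
  write_pathways(ann$pathways, p("pathway_members.tsv"),
                 p("pathway_compounds.tsv"), p("pathway_classes.tsv"))
  write_ontology(ann$pathway_ontology, p("pathway_ontology.obo"))
  write_ontology(ann$go_dag, p("go.obo"))
  writeLines(unlist(lapply(names(ann$go_annotations), function(g)
    paste(g, ann$go_annotations[[g]], sep = "\t"))), p("go_annotations.tsv"))
  write_expression(ann$expression, p("expression.tsv"))
  writeLines(unlist(lapply(names(ann$diseases), function(d)
    paste(d, ann$diseases[[d]]$genes, sep = "\t"))), p("disease_genes.tsv"))
  writeLines(vapply(names(ann$diseases), function(d)
    paste(d, ann$diseases[[d]]$term,
          format(ann$diseases[[d]]$p_om, digits = 17), sep = "\t"),
    character(1)), p("disease_terms.tsv"))
  writeLines(unlist(lapply(names(ann$diseases), function(d)
    paste(ann$diseases[[d]]$term, ann$diseases[[d]]$pmids, sep = "\t"))),
    p("disease_pmids.tsv"))
  write_duplication(ann$duplication, p("duplication.tsv"))
  invisible(list(prot = prot, net = net, ann = ann))
}
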
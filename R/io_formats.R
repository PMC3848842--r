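# Readers and writers for every external table the pipeline touches.
# Dialect everywhere: UTF-8, TAB-separated, lines starting with "#" ignored.

.read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Canonical key for an unordered pair
#'
#' Unordered pairs (protein pairs, domain pairs, pathway pairs) are keyed by
#' the lexicographically sorted id tuple joined by a tab, so that (a, b) and
#' (b, a) always map to the same key.
#'
#' @param a,b character vectors of ids (recycled to common length).
#' @return character vector of canonical keys.
#' @export
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}

#' Canonicalize a two-column pair table
#'
#' @param a,b character vectors of endpoint ids.
#' @return data.frame with columns `a`, `b`, sorted within each row.
#' @keywords internal
canonical_pairs <- function(a, b) {
  data.frame(a = pmin(a, b), b = pmax(a, b), stringsAsFactors = FALSE)
}

#' Read a protein -> PFAM domain table
#'
#' Each line is `protein_id TAB domain TAB domain ...`; a line with only a
#' protein id records a domain-less protein. Domains repeated within one
#' protein are collapsed: only the unique domains of each protein are kept,
#' preserving first-occurrence order.
#'
#' @param path path to a tab-delimited file.
#' @return named list of character vectors (one element per protein, possibly
#'   empty), class `"protein_domains"`.
#' @export
read_protein_domains <- function(path) {
  tl <- .read_tsv_lines(path)
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[`, character(1), 1L)
  bad <- which(is.na(ids) | !nzchar(ids))
  if (length(bad)) {
    stop("malformed protein line at line ", tl$lineno[bad[1]])
  }
  if (anyDuplicated(ids)) {
    stop("duplicate protein id: ", ids[duplicated(ids)][1])
  }
  doms <- lapply(fields, function(f) {
    d <- f[-1]
    unique(d[nzchar(d)])
  })
  names(doms) <- ids
  structure(doms, class = "protein_domains")
}

#' Write a protein -> domain table
#' @param domains object as returned by [read_protein_domains()].
#' @param path output path.
#' @export
write_protein_domains <- function(domains, path) {
  lines <- vapply(seq_along(domains), function(i) {
    paste(c(names(domains)[i], domains[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an undirected interaction pair list
#'
#' Each line is `protein_id TAB protein_id`. Pairs are stored unordered
#' (canonically sorted); with `dedupe = TRUE` (the default) the pairs (A,B)
#' and (B,A) collapse to one entry. Self-pairs are retained and flagged in the
#' `self` column so downstream stages can drop them.
#'
#' @param path path to a two-column tab-delimited file.
#' @param dedupe collapse duplicate unordered pairs?
#' @param source_label free-text provenance label stored as an attribute.
#' @return data.frame with columns `a`, `b`, `self`, class
#'   `"interaction_set"`.
#' @export
read_interactions <- function(path, dedupe = TRUE, source_label = basename(path)) {
  tl <- .read_tsv_lines(path)
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 2L)) {
    stop("interaction line with fewer than two columns at line ",
         tl$lineno[which(n < 2L)[1]])
  }
  a <- vapply(fields, `[`, character(1), 1L)
  b <- vapply(fields, `[`, character(1), 2L)
  interaction_set(a, b, dedupe = dedupe, source_label = source_label)
}

#' Construct an interaction set from endpoint vectors
#' @param a,b endpoint protein ids.
#' @inheritParams read_interactions
#' @return `"interaction_set"` data.frame.
#' @export
interaction_set <- function(a, b, dedupe = TRUE, source_label = "") {
  df <- canonical_pairs(as.character(a), as.character(b))
  if (dedupe) df <- df[!duplicated(pair_key(df$a, df$b)), , drop = FALSE]
  rownames(df) <- NULL
  df$self <- df$a == df$b
  structure(df, class = c("interaction_set", "data.frame"),
            source_label = source_label)
}

#' Write an interaction set
#' @param x an `"interaction_set"`.
#' @param path output path.
#' @export
write_interactions <- function(x, path) {
  writeLines(paste(x$a, x$b, sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

#' Read a localization feature table
#'
#' A rectangular table whose header names the features (typically
#' per-compartment localization probabilities plus raw subprogram scores of a
#' localization predictor) and whose first column holds protein ids.
#' Compartment probabilities need not sum to one: raw subprogram scores are
#' unnormalized by nature and the reader enforces only rectangularity and
#' numeric cells.
#'
#' @param path path to a tab-delimited table with a header row.
#' @return numeric matrix, proteins in rows (rownames = protein ids),
#'   features in columns.
#' @export
read_localization <- function(path) {
  tl <- .read_tsv_lines(path)
  if (!length(tl$lines)) stop("empty localization table: ", path)
  header <- strsplit(tl$lines[1], "\t", fixed = TRUE)[[1]]
  feat <- header[-1]
  rows <- strsplit(tl$lines[-1], "\t", fixed = TRUE)
  n <- lengths(rows)
  if (any(n != length(header))) {
    stop("localization row arity mismatch at line ",
         tl$lineno[-1][which(n != length(header))[1]])
  }
  ids <- vapply(rows, `[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(rows, function(r) as.numeric(r[-1]), numeric(length(feat))))
  if (anyNA(vals)) {
    bad <- which(apply(if (is.matrix(vals)) vals else rbind(vals), 2, anyNA))[1]
    stop("non-numeric localization value at line ", tl$lineno[-1][bad])
  }
  m <- matrix(vals, ncol = length(feat), byrow = TRUE,
              dimnames = list(ids, feat))
  m
}

#' Write a localization feature table
#' @param loc numeric matrix with protein rownames.
#' @param path output path.
#' @export
write_localization <- function(loc, path) {
  header <- paste(c("id", colnames(loc)), collapse = "\t")
  body <- vapply(seq_len(nrow(loc)), function(i) {
    paste(c(rownames(loc)[i], format(loc[i, ], digits = 15, trim = TRUE,
                                     scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' The default localization feature schema
#'
#' Column names emulating a high-resolution subcellular localization
#' predictor: per-compartment probabilities plus raw subprogram scores. Any
#' consistent named numeric vector is accepted by the pipeline; this schema is
#' only a documented default used by the synthetic-data generator.
#'
#' @param kingdom `"plant"`, `"animal"` or `"fungal"`; controls which
#'   kingdom-specific compartments are present.
#' @return character vector of feature names.
#' @export
default_localization_schema <- function(kingdom = c("plant", "animal", "fungal")) {
  kingdom <- match.arg(kingdom)
  comp <- c("cytoplasm", "nucleus", "peroxisome", "ER", "mitochondria",
            switch(kingdom,
                   plant  = c("chloroplast", "vacuole"),
                   fungal = "vacuole",
                   animal = "lysosome"))
  sub <- c("SVMTarget", "SVMSA", "SVMaac", "PhyloLoc", "GOLoc", "MotifSearch")
  c(comp, sub)
}

#' Read a domain-domain interaction confidence table
#'
#' Lines are `domain TAB domain TAB confidence` with confidence in [0,1]
#' (e.g. an export of a domain-interaction catalogue such as DOMINE). Lookup
#' is symmetric; a pair repeated with different confidences keeps the maximum.
#'
#' @param path path to the table.
#' @return named numeric vector keyed by canonical domain-pair key, class
#'   `"domine_table"`. Query with [domine_conf()].
#' @export
read_domine <- function(path) {
  tl <- .read_tsv_lines(path)
  if (!length(tl$lines)) {
    return(structure(numeric(0), class = "domine_table"))
  }
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3L)) {
    stop("malformed domain-confidence line at line ", tl$lineno[which(n < 3L)[1]])
  }
  d1 <- vapply(fields, `[`, character(1), 1L)
  d2 <- vapply(fields, `[`, character(1), 2L)
  conf <- as.numeric(vapply(fields, `[`, character(1), 3L))
  if (anyNA(conf) || any(conf < 0 | conf > 1)) {
    stop("confidence outside [0,1] at line ",
         tl$lineno[which(is.na(conf) | conf < 0 | conf > 1)[1]])
  }
  key <- pair_key(d1, d2)
  merged <- tapply(conf, key, max)
  structure(as.numeric(merged), names = names(merged), class = "domine_table")
}

#' Symmetric confidence lookup in a domain-interaction table
#' @param tab a `"domine_table"`.
#' @param d1,d2 domain accession vectors.
#' @return numeric vector of confidences; 0 for absent pairs.
#' @export
domine_conf <- function(tab, d1, d2) {
  v <- unclass(tab)[pair_key(d1, d2)]
  v[is.na(v)] <- 0
  unname(v)
}

#' Write a domain-domain confidence table
#' @param tab a `"domine_table"`.
#' @param path output path.
#' @export
write_domine <- function(tab, path) {
  keys <- strsplit(names(tab), "\t", fixed = TRUE)
  lines <- vapply(seq_along(tab), function(i) {
    paste(c(keys[[i]], format(unclass(tab)[[i]], digits = 15)), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a gene x sample expression matrix
#'
#' Header row: `gene` followed by sample ids; one row per gene. Correlation
#' analyses downstream require at least three samples.
#'
#' @param path path to the table.
#' @return numeric matrix, genes in rows.
#' @export
read_expression <- function(path) {
  m <- read_localization(path)  # same rectangular numeric layout
  if (anyDuplicated(rownames(m))) stop("duplicated gene ids in expression matrix")
  m
}

#' @rdname read_expression
#' @param expr numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @export
write_expression <- function(expr, path) write_localization(expr, path)

#' Read an OBO-lite ontology into a rooted DAG
#'
#' Parses only `[Term]` stanzas and their `id:`, `name:` and `is_a:` tags —
#' enough for GO-style and pathway-class ontologies. The result stores, per
#' term, its direct parents; terms without parents are roots.
#'
#' @param path path to an OBO file.
#' @return list with elements `terms` (character), `parents` (named list of
#'   character vectors) and `names` (named character), class
#'   `"ontology_dag"`.
#' @export
read_ontology <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  terms <- character(0); parents <- list(); nm <- character(0)
  cur <- NULL; in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && nzchar(cur$id)) {
      terms[[length(terms) + 1L]] <<- cur$id
      parents[[cur$id]] <<- cur$parents
      nm[[cur$id]] <<- cur$name
    }
  }
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (ln == "[Term]") { flush(); cur <- list(id = "", name = "", parents = character(0)); in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "name:")) cur$name <- trimws(sub("^name:", "", ln))
    else if (startsWith(ln, "is_a:")) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$parents <- c(cur$parents, tgt)
    }
  }
  flush()
  ontology_dag(terms, parents, nm)
}

#' Construct an ontology DAG from parent lists
#' @param terms character vector of term ids.
#' @param parents named list: term id -> character vector of direct parents.
#' @param names optional named character vector of term names.
#' @return `"ontology_dag"` object; errors if the relation graph has a cycle.
#' @export
ontology_dag <- function(terms, parents, names = NULL) {
  terms <- unique(terms)
  parents <- parents[intersect(base::names(parents), terms)]
  missing <- setdiff(terms, base::names(parents))
  parents[missing] <- list(character(0))
  parents <- lapply(parents, function(p) intersect(unique(p), terms))
  dag <- structure(list(terms = terms, parents = parents[terms], names = names),
                   class = "ontology_dag")
  # cycle check via topological elimination
  indeg_src <- dag$parents
  remaining <- terms
  repeat {
    roots <- remaining[vapply(indeg_src[remaining], length, integer(1)) == 0L]
    if (!length(roots)) break
    remaining <- setdiff(remaining, roots)
    indeg_src[remaining] <- lapply(indeg_src[remaining], setdiff, roots)
    if (!length(remaining)) break
  }
  if (length(remaining)) stop("cycle detected in ontology among: ",
                              paste(utils::head(remaining, 5), collapse = ", "))
  dag
}

#' Write an ontology DAG in OBO-lite format
#' @param dag an `"ontology_dag"`.
#' @param path output path.
#' @export
write_ontology <- function(dag, path) {
  out <- character(0)
  for (t in dag$terms) {
    out <- c(out, "[Term]", paste0("id: ", t))
    n <- if (!is.null(dag$names) && t %in% names(dag$names)) dag$names[[t]] else t
    out <- c(out, paste0("name: ", n),
             paste0("is_a: ", dag$parents[[t]]), "")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Ancestors of a term (including the term itself)
#' @param dag an `"ontology_dag"`.
#' @param term a term id.
#' @return character vector of ancestor term ids.
#' @export
dag_ancestors <- function(dag, term) {
  if (!term %in% dag$terms) stop("unknown term: ", term)
  seen <- character(0); frontier <- term
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier], use.names = FALSE)), seen)
  }
  seen
}

#' Descendants of a term (including the term itself)
#' @inheritParams dag_ancestors
#' @export
dag_descendants <- function(dag, term) {
  if (!term %in% dag$terms) stop("unknown term: ", term)
  children <- split(rep(names(dag$parents), lengths(dag$parents)),
                    unlist(dag$parents, use.names = FALSE))
  seen <- character(0); frontier <- term
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(children[frontier], use.names = FALSE)), seen)
  }
  seen
}

#' Read pathway definition tables
#'
#' Three two-column tables keyed by pathway id: members (`pathway TAB
#' protein`), compounds (`pathway TAB compound`) and ontology class
#' annotations (`pathway TAB class_term`). Compounds and classes are optional.
#'
#' @param members_path required path of the pathway-membership table.
#' @param compounds_path,classes_path optional companion tables.
#' @return list of per-pathway lists with elements `members`, `compounds`,
#'   `classes`; class `"pathway_set"`.
#' @export
read_pathways <- function(members_path, compounds_path = NULL, classes_path = NULL) {
  read2 <- function(p) {
    tl <- .read_tsv_lines(p)
    f <- strsplit(tl$lines, "\t", fixed = TRUE)
    if (any(lengths(f) < 2L)) stop("two columns required at line ",
                                   tl$lineno[which(lengths(f) < 2L)[1]], " of ", p)
    data.frame(key = vapply(f, `[`, character(1), 1L),
               val = vapply(f, `[`, character(1), 2L), stringsAsFactors = FALSE)
  }
  mem <- read2(members_path)
  cmp <- if (!is.null(compounds_path)) read2(compounds_path) else NULL
  cls <- if (!is.null(classes_path)) read2(classes_path) else NULL
  ids <- unique(mem$key)
  ps <- lapply(ids, function(id) {
    list(members = unique(mem$val[mem$key == id]),
         compounds = if (is.null(cmp)) character(0) else unique(cmp$val[cmp$key == id]),
         classes = if (is.null(cls)) character(0) else unique(cls$val[cls$key == id]))
  })
  names(ps) <- ids
  if (any(vapply(ps, function(p) length(p$members) == 0L, logical(1))))
    stop("pathway with empty member set")
  structure(ps, class = "pathway_set")
}

#' Write a pathway set back to its three two-column tables
#' @param ps a `"pathway_set"`.
#' @inheritParams read_pathways
#' @export
write_pathways <- function(ps, members_path, compounds_path = NULL, classes_path = NULL) {
  w2 <- function(field, path) {
    lines <- unlist(lapply(names(ps), function(id)
      if (length(ps[[id]][[field]])) paste(id, ps[[id]][[field]], sep = "\t")),
      use.names = FALSE)
    writeLines(lines, path, useBytes = TRUE)
  }
  w2("members", members_path)
  if (!is.null(compounds_path)) w2("compounds", compounds_path)
  if (!is.null(classes_path)) w2("classes", classes_path)
  invisible(members_path)
}

#' Read disease tables
#'
#' Three snapshot tables describing diseases and their literature context:
#' `genes_path` maps `disease TAB causative_gene`; `terms_path` maps
#' `disease TAB term TAB p_assoc` where `p_assoc` in (0,1] is the significance
#' of the disease-term association; `pmids_path` maps `term TAB pmid`. Only
#' the most significant term per disease is retained; diseases without a
#' mapped term are dropped.
#'
#' @param genes_path,terms_path,pmids_path table paths.
#' @return list of per-disease lists with elements `genes`, `term`, `p_om`,
#'   `pmids`; class `"disease_table"`.
#' @export
read_diseases <- function(genes_path, terms_path, pmids_path) {
  tl <- .read_tsv_lines(genes_path)
  f <- strsplit(tl$lines, "\t", fixed = TRUE)
  gene_df <- data.frame(d = vapply(f, `[`, character(1), 1L),
                        g = vapply(f, `[`, character(1), 2L))
  tl <- .read_tsv_lines(terms_path)
  f <- strsplit(tl$lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 3L)) stop("terms table needs 3 columns")
  term_df <- data.frame(d = vapply(f, `[`, character(1), 1L),
                        term = vapply(f, `[`, character(1), 2L),
                        p = as.numeric(vapply(f, `[`, character(1), 3L)))
  if (anyNA(term_df$p) || any(term_df$p <= 0 | term_df$p > 1))
    stop("association p-values must lie in (0,1]")
  tl <- .read_tsv_lines(pmids_path)
  f <- strsplit(tl$lines, "\t", fixed = TRUE)
  pmid_map <- split(vapply(f, `[`, character(1), 2L),
                    vapply(f, `[`, character(1), 1L))
  pmid_map <- lapply(pmid_map, unique)
  ids <- intersect(unique(gene_df$d), unique(term_df$d))
  dt <- lapply(ids, function(id) {
    sub <- term_df[term_df$d == id, , drop = FALSE]
    best <- sub[which.min(sub$p), , drop = FALSE]
    pm <- pmid_map[[best$term]]
    list(genes = unique(gene_df$g[gene_df$d == id]),
         term = best$term, p_om = best$p,
         pmids = if (is.null(pm)) character(0) else pm)
  })
  names(dt) <- ids
  structure(dt, class = "disease_table")
}

#' Read a duplicate-retention flag table
#'
#' Lines are `gene TAB event TAB flag` with flag 0/1 marking absence/presence
#' of a retained paralog from the named whole-genome duplication event.
#'
#' @param path table path.
#' @return data.frame with columns `gene`, `event`, `retained` (integer 0/1).
#' @export
read_duplication <- function(path) {
  tl <- .read_tsv_lines(path)
  f <- strsplit(tl$lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 3L)) stop("duplication table needs 3 columns")
  flag <- as.integer(vapply(f, `[`, character(1), 3L))
  if (anyNA(flag) || any(!flag %in% c(0L, 1L))) stop("retention flags must be 0 or 1")
  data.frame(gene = vapply(f, `[`, character(1), 1L),
             event = vapply(f, `[`, character(1), 2L),
             retained = flag, stringsAsFactors = FALSE)
}

#' @rdname read_duplication
#' @param dup data.frame as returned by `read_duplication()`.
#' @param path output path.
#' @export
write_duplication <- function(dup, path) {
  writeLines(paste(dup$gene, dup$event, dup$retained, sep = "\t"), path,
             useBytes = TRUE)
  invisible(path)
}

#' Write a generic numeric pair table (e.g. predictions, LOD scores)
#' @param df data.frame whose first columns are ids and remaining numeric.
#' @param path output path.
#' @param col.names write a header line?
#' @export
write_pair_table <- function(df, path, col.names = TRUE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = col.names)
  invisible(path)
}
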
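#' Define a study set for enrichment
#'
#' @param label description, e.g. `"gains at Metazoa branch"`.
#' @param domains character vector of domain accessions.
#' @return An object of class `study_set`.
#' @export
study_set <- function(label, domains) {
  structure(list(label = as.character(label)[1L],
                 domains = sort(unique(as.character(domains)))),
            class = "study_set")
}

#' One-sided upper-tail hypergeometric test
#'
#' Probability of observing at least `k` annotated domains in a study of
#' size `n`, drawn without replacement from a population of size `N`
#' containing `K` annotated domains.
#'
#' @param k study hits.
#' @param n study size.
#' @param K population hits.
#' @param N population size.
#' @return P(X >= k).
#' @export
hypergeom_test <- function(k, n, K, N) {
  if (any(k < 0 | k > n | n > N | k > K | K > N | (n - k) > (N - K)))
    stop(sprintf("inconsistent counts: k=%d n=%d K=%d N=%d", k, n, K, N))
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# restrict study/population to domains carrying >= 1 propagated annotation
# in the namespace, and invert the map to term -> domains
enrich_prepare <- function(study, population, dag, map, namespace) {
  pmap <- propagate(dag, map)
  ns_terms <- dag$terms$id[dag$terms$namespace == namespace &
                             !dag$terms$obsolete]
  pmap <- lapply(unclass(pmap), function(ts) ts[ts %in% ns_terms])
  annotated <- names(pmap)[lengths(pmap) > 0L]
  pop <- intersect(population, annotated)
  if (length(pop) == 0L) stop("empty population after annotation restriction")
  st <- intersect(study$domains, pop)
  t2d <- term_to_domains(structure(pmap, class = "domain_go_map"), pop)
  list(study = st, pop = pop, t2d = t2d, ns_terms = ns_terms)
}

result_frame <- function(dag, term, study_count, population_count,
                         study_size, population_size, p, method) {
  out <- data.frame(
    term = term,
    name = dag$terms$name[match(term, dag$terms$id)],
    study_count = study_count, population_count = population_count,
    study_size = study_size, population_size = population_size,
    p = p, p_adjusted = p, method = rep_len(method, length(term)),
    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Term-for-term GO enrichment
#'
#' Independent one-sided hypergeometric test per term, on propagated
#' annotations, for every term with at least one annotated population
#' domain. The population defaults (at the caller's level) to the union
#' of all annotated domains present across the genomes analyzed.
#'
#' @param study a [study_set()].
#' @param population character vector of population domain accessions.
#' @param dag a [go_dag()].
#' @param map a [domain_go_map()] of direct annotations.
#' @param namespace ontology namespace to test (default
#'   biological_process).
#' @return Data frame of class `enrichment_result`, ascending by p-value:
#'   `term`, `name`, `study_count`, `population_count`, `study_size`,
#'   `population_size`, `p`, `p_adjusted` (raw copy until [adjust()]),
#'   `method`.
#' @export
term_for_term <- function(study, population, dag, map,
                          namespace = "biological_process") {
  pr <- enrich_prepare(study, population, dag, map, namespace)
  if (length(pr$study) == 0L) {
    warning("empty study set after annotation restriction")
    return(result_frame(dag, character(0), integer(0), integer(0),
                        integer(0), integer(0), numeric(0), "tft"))
  }
  terms <- names(pr$t2d)
  n <- length(pr$study); N <- length(pr$pop)
  K <- lengths(pr$t2d)
  k <- vapply(pr$t2d, function(d) length(intersect(d, pr$study)), 0L)
  p <- mapply(hypergeom_test, k, n, K, N)
  result_frame(dag, terms, k, unname(K), n, N, unname(p), "tft")
}

#' Topology-elim GO enrichment
#'
#' DAG-aware enrichment: terms are tested from most specific to least
#' specific (descending longest-path depth, ties by id) on their current
#' annotation sets; when a term's p-value falls below `sig_threshold`,
#' its annotated study and population domains are removed from all of its
#' ancestors' annotation sets before those are tested, so parents are not
#' flagged merely for inheriting a significant child's signal.
#'
#' @inheritParams term_for_term
#' @param sig_threshold elimination threshold in (0, 1); default 0.01.
#' @return An `enrichment_result` data frame (method `"elim"`).
#' @export
topology_elim <- function(study, population, dag, map,
                          sig_threshold = 0.01,
                          namespace = "biological_process") {
  if (!(sig_threshold > 0 && sig_threshold < 1))
    stop("sig_threshold must be in (0, 1)")
  pr <- enrich_prepare(study, population, dag, map, namespace)
  if (length(pr$study) == 0L) {
    warning("empty study set after annotation restriction")
    return(result_frame(dag, character(0), integer(0), integer(0),
                        integer(0), integer(0), numeric(0), "elim"))
  }
  terms <- names(pr$t2d)
  ord <- terms[order(-dag$depth[terms], terms)]
  cur_pop <- pr$t2d
  cur_study <- lapply(pr$t2d, function(d) intersect(d, pr$study))
  n <- length(pr$study); N <- length(pr$pop)
  p <- k <- K <- stats::setNames(numeric(length(ord)), ord)
  for (t in ord) {
    k[t] <- length(cur_study[[t]])
    K[t] <- length(cur_pop[[t]])
    p[t] <- if (K[t] == 0L) 1.0
            else hypergeom_test(k[t], n, K[t], N)
    if (p[t] < sig_threshold) {
      for (a in intersect(dag$ancestors[[t]], ord)) {
        cur_study[[a]] <- setdiff(cur_study[[a]], cur_study[[t]])
        cur_pop[[a]] <- setdiff(cur_pop[[a]], cur_pop[[t]])
      }
    }
  }
  result_frame(dag, ord, as.integer(k), as.integer(K), n, N, unname(p),
               "elim")
}

#' Parent-child GO enrichment
#'
#' Tests each term against the background of its parents' annotations
#' rather than the whole population: the conditioning set is the union
#' (or intersection) of the parents' propagated annotation sets, and the
#' hypergeometric table is formed inside it. Terms without parents (the
#' namespace root) fall back to the term-for-term test.
#'
#' @inheritParams term_for_term
#' @param mode `"union"` or `"intersection"` of the parents' sets.
#' @return An `enrichment_result` data frame (method `"pcu"` / `"pci"`).
#' @export
parent_child <- function(study, population, dag, map,
                         mode = c("union", "intersection"),
                         namespace = "biological_process") {
  mode <- match.arg(mode)
  pr <- enrich_prepare(study, population, dag, map, namespace)
  if (length(pr$study) == 0L) {
    warning("empty study set after annotation restriction")
    return(result_frame(dag, character(0), integer(0), integer(0),
                        integer(0), integer(0), numeric(0),
                        if (mode == "union") "pcu" else "pci"))
  }
  terms <- names(pr$t2d)
  parents_of <- split(dag$edges$parent,
                      factor(dag$edges$child, levels = dag$terms$id))
  n_all <- length(pr$study); N_all <- length(pr$pop)
  res <- lapply(terms, function(t) {
    annot <- pr$t2d[[t]]
    ps <- parents_of[[t]]
    if (length(ps) == 0L) {
      k <- length(intersect(annot, pr$study)); K <- length(annot)
      return(c(k, K, n_all, N_all,
               hypergeom_test(k, n_all, K, N_all)))
    }
    psets <- lapply(ps, function(a) {
      d <- pr$t2d[[a]]
      if (is.null(d)) character(0) else d
    })
    cond <- if (mode == "union") Reduce(union, psets)
            else Reduce(intersect, psets)
    N <- length(cond)
    st_c <- intersect(cond, pr$study)
    n <- length(st_c)
    an_c <- intersect(annot, cond)
    K <- length(an_c)
    k <- length(intersect(an_c, st_c))
    p <- if (N == 0L || n == 0L || K == 0L) 1.0
         else hypergeom_test(k, n, K, N)
    c(k, K, n, N, p)
  })
  res <- do.call(rbind, res)
  result_frame(dag, terms, as.integer(res[, 1L]), as.integer(res[, 2L]),
               as.integer(res[, 3L]), as.integer(res[, 4L]), res[, 5L],
               if (mode == "union") "pcu" else "pci")
}

#' Multiple-testing adjustment of enrichment results
#'
#' @param results an `enrichment_result` data frame.
#' @param method `"none"`, `"bonferroni"`, or `"bh"`
#'   (Benjamini-Hochberg).
#' @return The input with `p_adjusted` replaced.
#' @export
adjust <- function(results, method = c("none", "bonferroni", "bh")) {
  method <- match.arg(method)
  results$p_adjusted <- switch(method,
    none = results$p,
    bonferroni = stats::p.adjust(results$p, method = "bonferroni"),
    bh = stats::p.adjust(results$p, method = "BH"))
  results
}

#' Write enrichment results as TSV
#' @param results an `enrichment_result` data frame.
#' @param path output path.
#' @export
write_enrichment_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
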
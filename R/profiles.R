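#' Default GO term choices for profiles and flux
#'
#' Two-dimensional profile axes default to signal transduction
#' (GO:0007165) versus catalytic activity (GO:0003824); per-branch flux
#' categories default to biological regulation (GO:0065007) versus
#' metabolic process (GO:0008152). All are configurable in the functions
#' that use them.
#'
#' @name go-defaults
NULL

#' @rdname go-defaults
#' @export
GO_SIGNAL_TRANSDUCTION <- "GO:0007165"
#' @rdname go-defaults
#' @export
GO_CATALYTIC_ACTIVITY <- "GO:0003824"
#' @rdname go-defaults
#' @export
GO_BIOLOGICAL_REGULATION <- "GO:0065007"
#' @rdname go-defaults
#' @export
GO_METABOLIC_PROCESS <- "GO:0008152"

#' Functional profile of a domainome
#'
#' For each selected GO term, the percentage of the domainome's annotated
#' domains that are annotated (after true-path propagation) to that term.
#' The denominator for a term is the number of domains carrying at least
#' one propagated annotation in that term's namespace, so profiles are
#' comparable across genomes with differing annotation coverage. A zero
#' denominator flags the fraction undefined (reported `NA`).
#'
#' @param domainome a [domainome()].
#' @param dag a [go_dag()].
#' @param map a [domain_go_map()] of direct annotations (propagated
#'   internally).
#' @param terms character vector of GO term ids.
#' @return An object of class `functional_profile`: list with `label`,
#'   `terms`, `fraction` (named percentages, `NA` where undefined),
#'   `denominator` (named counts per term), `n_domains`.
#' @export
profile <- function(domainome, dag, map, terms) {
  if (!all(dag_has_term(dag, terms)))
    stop("unknown GO term id(s): ",
         paste(terms[!dag_has_term(dag, terms)], collapse = ", "))
  pmap <- propagate(dag, map)
  doms <- domainome$domains
  ann <- unclass(pmap)[intersect(doms, names(pmap))]
  ann <- ann[lengths(ann) > 0L]
  # per-term hit counts over the annotated domains, in one pass
  flat <- data.frame(dom = rep(names(ann), lengths(ann)),
                     term = unlist(ann, use.names = FALSE))
  counts <- table(flat$term)
  # per-namespace denominators: domains with >= 1 annotation there
  flat$ns <- term_namespace(dag, flat$term)
  denom_ns <- vapply(split(flat$dom, flat$ns),
                     function(d) length(unique(d)), 0L)
  frac <- den <- stats::setNames(numeric(length(terms)), terms)
  for (t in terms) {
    ns <- term_namespace(dag, t)
    denom <- if (ns %in% names(denom_ns)) denom_ns[[ns]] else 0L
    den[t] <- denom
    if (denom == 0L) {
      frac[t] <- NA_real_
    } else {
      hits <- if (t %in% names(counts)) counts[[t]] else 0L
      frac[t] <- 100 * hits / denom
    }
  }
  structure(list(label = domainome$label, terms = terms,
                 fraction = frac, denominator = den,
                 n_domains = length(doms)),
            class = "functional_profile")
}

#' @export
print.functional_profile <- function(x, ...) {
  cat(sprintf("functional_profile '%s' over %d terms:\n", x$label,
              length(x$terms)))
  print(round(x$fraction, 2))
  invisible(x)
}

#' Per-branch functional flux along a lineage
#'
#' For every branch on a connected root-to-node path, counts the gained
#' and lost domains annotated (post-propagation) to a GO category — each
#' domain counted once per category — and returns the per-branch vectors
#' plus their arithmetic means.
#'
#' @param ledger an `event_ledger` from [reconstruct()].
#' @param path character vector of node names forming a parent-to-child
#'   chain starting anywhere (typically the root) and walking leafward.
#' @param dag a [go_dag()].
#' @param map a [domain_go_map()] of direct annotations.
#' @param category GO term id of the category.
#' @return List with `category`, `branches` (child node names),
#'   `gains`, `losses` (per-branch counts), `mean_gains`, `mean_losses`.
#' @export
category_flux <- function(ledger, path, dag, map,
                          category = GO_BIOLOGICAL_REGULATION) {
  if (!all(dag_has_term(dag, category))) stop("unknown GO term: ", category)
  if (length(path) < 2L) stop("path must contain at least one branch")
  tree <- ledger$tree
  idx <- node_index(tree, path)
  for (i in 2:length(path))
    if (tree$parent[idx[i]] != idx[i - 1L])
      stop(sprintf("path is not a connected chain: '%s' is not the parent of '%s'",
                   path[i - 1L], path[i]))
  pmap <- propagate(dag, map)
  in_cat <- function(doms) {
    if (length(doms) == 0L) return(0L)
    sum(vapply(doms, function(d) {
      ts <- pmap[[d]]
      !is.null(ts) && category %in% ts
    }, TRUE))
  }
  branches <- path[-1L]
  g <- vapply(ledger$gains[branches], in_cat, 0L)
  l <- vapply(ledger$losses[branches], in_cat, 0L)
  list(category = category, branches = branches,
       gains = g, losses = l,
       mean_gains = mean(g), mean_losses = mean(l))
}

#' Two-dimensional profile coordinates
#'
#' Extracts an (x, y) percentage pair per profile, e.g. signal
#' transduction versus catalytic activity, for plotting genomes and
#' ancestors in a functional plane.
#'
#' @param profiles list of [profile()] results over a common term vector.
#' @param x_term,y_term GO term ids present in every profile.
#' @return Data frame with columns `label`, `x`, `y`.
#' @export
profile_coordinates <- function(profiles,
                                x_term = GO_SIGNAL_TRANSDUCTION,
                                y_term = GO_CATALYTIC_ACTIVITY) {
  rows <- lapply(profiles, function(p) {
    for (t in c(x_term, y_term))
      if (!t %in% p$terms)
        stop(sprintf("profile '%s' lacks term %s", p$label, t))
    data.frame(label = p$label, x = unname(p$fraction[x_term]),
               y = unname(p$fraction[y_term]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cluster genomes by functional profile and score tree congruence
#'
#' Average-linkage hierarchical clustering on the Euclidean distance
#' between percentage vectors, compared against a reference species tree
#' by Robinson-Foulds distance normalized to [0, 1] (0 = identical
#' topology).
#'
#' @param profiles list of at least three [profile()] results over a
#'   common term vector.
#' @param reference a [rooted_tree()] whose leaf set is contained in the
#'   profile labels.
#' @return List with `hclust` (the dendrogram), `phylo` (its tree form,
#'   restricted to the reference leaves), `congruence` (normalized RF).
#' @export
cluster_profiles <- function(profiles, reference) {
  stopifnot(length(profiles) >= 3L)
  terms <- profiles[[1L]]$terms
  for (p in profiles)
    if (!identical(p$terms, terms))
      stop("profiles must share one term vector (mismatch at '",
           p$label, "')")
  m <- do.call(rbind, lapply(profiles, function(p) p$fraction))
  rownames(m) <- vapply(profiles, function(p) p$label, "")
  if (anyNA(m)) stop("undefined fractions (zero denominator) in profiles")
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "average")
  phy <- ape::as.phylo(hc)
  ref_leaves <- leaf_labels(reference)
  miss <- setdiff(ref_leaves, rownames(m))
  if (length(miss))
    stop("reference leaves without profiles: ", paste(miss, collapse = ", "))
  phy_r <- ape::keep.tip(phy, ref_leaves)
  rf <- phangorn::RF.dist(ape::unroot(phy_r), ape::unroot(reference$phy),
                          normalize = TRUE, check.labels = TRUE)
  list(hclust = hc, phylo = phy_r, congruence = unname(rf))
}
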
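#' Build a GO DAG from term and edge tables
#'
#' The ontology is held as an acyclic directed graph with child-to-parent
#' edges of kind `is_a` or `part_of` (other relationship types, e.g.
#' regulates, are outside the true-path convention used here and are
#' ignored at load). Obsolete terms carry no edges.
#'
#' @param terms data frame with columns `id`, `name`, `namespace`
#'   (one of biological_process / molecular_function /
#'   cellular_component), `obsolete` (logical).
#' @param edges data frame with columns `child`, `parent`, `rel`
#'   (`is_a` or `part_of`).
#' @return An object of class `go_dag`: the input tables plus a named
#'   list `ancestors` (strict ancestors per term), integer `depth`
#'   (longest path from a namespace root) and `roots`.
#' @export
go_dag <- function(terms, edges) {
  stopifnot(all(c("id", "name", "namespace", "obsolete") %in% names(terms)),
            all(c("child", "parent", "rel") %in% names(edges)))
  terms <- terms[!duplicated(terms$id), , drop = FALSE]
  edges <- edges[edges$rel %in% c("is_a", "part_of"), , drop = FALSE]
  keep <- edges$child %in% terms$id & edges$parent %in% terms$id
  edges <- edges[keep, , drop = FALSE]
  obs <- terms$id[terms$obsolete]
  edges <- edges[!(edges$child %in% obs) & !(edges$parent %in% obs),
                 , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")], directed = TRUE,
    vertices = terms$id)
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1L)]
    stop("cyclic ontology; terms on a cycle: ",
         paste(sort(cyc), collapse = ", "))
  }
  ord <- names(igraph::topo_sort(g, mode = "out"))  # parents after children
  parents_of <- split(edges$parent, factor(edges$child, levels = terms$id))
  ancestors <- stats::setNames(vector("list", nrow(terms)), terms$id)
  depth <- stats::setNames(integer(nrow(terms)), terms$id)
  for (t in rev(ord)) {  # parents first
    ps <- parents_of[[t]]
    if (length(ps) == 0L) {
      ancestors[[t]] <- character(0)
      depth[[t]] <- 0L
    } else {
      ancestors[[t]] <- sort(unique(c(ps, unlist(ancestors[ps],
                                                 use.names = FALSE))))
      depth[[t]] <- 1L + max(depth[ps])
    }
  }
  roots <- terms$id[!terms$obsolete &
                      vapply(parents_of[terms$id], length, 0L) == 0L]
  structure(list(terms = terms, edges = edges, ancestors = ancestors,
                 depth = depth, roots = roots),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("go_dag: %d terms (%d obsolete), %d is_a/part_of edges\n",
              nrow(x$terms), sum(x$terms$obsolete), nrow(x$edges)))
  invisible(x)
}

dag_has_term <- function(dag, ids) ids %in% dag$terms$id

term_namespace <- function(dag, ids)
  dag$terms$namespace[match(ids, dag$terms$id)]

#' Read a (minimal-dialect) OBO 1.2 ontology file
#'
#' Parses `[Term]` stanzas: `id`, `name`, `namespace`, `is_a`,
#' `relationship: part_of`, `is_obsolete`. Trailing `!` comments are
#' stripped. Other stanza types and tags are ignored.
#'
#' @param path OBO file path.
#' @return A [go_dag()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stanza_start <- grep("^\\[", lines)
  is_term <- lines[stanza_start] == "[Term]"
  ids <- names <- nss <- character(0)
  obso <- logical(0)
  ch <- pa <- rel <- character(0)
  strip <- function(v) trimws(sub("!.*$", "", v))
  for (k in which(is_term)) {
    from <- stanza_start[k] + 1L
    to <- if (k < length(stanza_start)) stanza_start[k + 1L] - 1L
          else length(lines)
    block <- lines[from:to]
    getv <- function(tag) strip(sub(paste0("^", tag, ":\\s*"), "",
                                    grep(paste0("^", tag, ":"), block,
                                         value = TRUE)))
    id <- getv("id")
    if (length(id) != 1L)
      stop(sprintf("malformed [Term] stanza near line %d of %s (no id)",
                   stanza_start[k], path))
    nm <- getv("name"); ns <- getv("namespace")
    ids <- c(ids, id)
    names <- c(names, if (length(nm)) nm[1L] else id)
    nss <- c(nss, if (length(ns)) ns[1L] else NA_character_)
    obso <- c(obso, any(getv("is_obsolete") == "true"))
    isa <- getv("is_a")
    if (length(isa)) {
      ch <- c(ch, rep(id, length(isa))); pa <- c(pa, isa)
      rel <- c(rel, rep("is_a", length(isa)))
    }
    rl <- getv("relationship")
    po <- grep("^part_of\\s", rl, value = TRUE)
    if (length(po)) {
      tgt <- strip(sub("^part_of\\s+", "", po))
      ch <- c(ch, rep(id, length(tgt))); pa <- c(pa, tgt)
      rel <- c(rel, rep("part_of", length(tgt)))
    }
  }
  go_dag(
    terms = data.frame(id = ids, name = names, namespace = nss,
                       obsolete = obso, stringsAsFactors = FALSE),
    edges = data.frame(child = ch, parent = pa, rel = rel,
                       stringsAsFactors = FALSE))
}

#' Write a GO DAG as (minimal) OBO 1.2
#' @param dag a [go_dag()].
#' @param path output path.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    writeLines(c("", "[Term]",
                 paste0("id: ", id),
                 paste0("name: ", dag$terms$name[i]),
                 paste0("namespace: ", dag$terms$namespace[i])), con)
    if (dag$terms$obsolete[i]) writeLines("is_obsolete: true", con)
    e <- dag$edges[dag$edges$child == id, , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      if (e$rel[j] == "is_a")
        writeLines(paste0("is_a: ", e$parent[j]), con)
      else
        writeLines(paste0("relationship: part_of ", e$parent[j]), con)
    }
  }
  invisible(path)
}

#' Construct a domain-to-GO annotation map
#'
#' @param map named list: domain accession -> character vector of GO ids
#'   (direct annotations).
#' @param dag a [go_dag()]; annotations to unknown or obsolete terms are
#'   dropped with a warning.
#' @return An object of class `domain_go_map` (a named list).
#' @export
domain_go_map <- function(map, dag) {
  known <- dag$terms$id[!dag$terms$obsolete]
  dropped <- 0L
  map <- lapply(map, function(ts) {
    ts <- unique(as.character(ts))
    bad <- !(ts %in% known)
    dropped <<- dropped + sum(bad)
    sort(ts[!bad])
  })
  if (dropped > 0L)
    warning(sprintf("dropped %d annotation(s) to unknown/obsolete terms",
                    dropped))
  structure(map, class = "domain_go_map")
}

#' Read a pfam2go / external2go mapping file
#'
#' Line format:
#' `Pfam:PF00069 Pkinase > GO:protein kinase activity ; GO:0004672`.
#' `!` comment lines are skipped; the accession's `Pfam:` prefix and any
#' version suffix are removed.
#'
#' @param path mapping file path.
#' @param dag a [go_dag()] used to validate term ids.
#' @return A [domain_go_map()].
#' @export
read_pfam2go <- function(path, dag) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^!", lines) & nzchar(trimws(lines))]
  m <- regmatches(lines,
                  regexec("^\\S+:(\\S+).*>\\s*.*;\\s*(GO:\\d+)\\s*$", lines))
  bad <- which(vapply(m, length, 1L) != 3L)
  if (length(bad))
    stop(sprintf("malformed external2go line %d of %s", bad[1L], path))
  acc <- strip_acc_version(vapply(m, `[[`, "", 2L))
  term <- vapply(m, `[[`, "", 3L)
  domain_go_map(split(term, acc), dag)
}

#' Write a domain-to-GO map in external2go format
#' @param map a `domain_go_map` of direct annotations.
#' @param dag a [go_dag()] (for term names).
#' @param path output path.
#' @export
write_pfam2go <- function(map, dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!version date: synthetic", con)
  for (acc in names(map)) {
    for (t in map[[acc]]) {
      nm <- dag$terms$name[match(t, dag$terms$id)]
      writeLines(sprintf("Pfam:%s %s > GO:%s ; %s", acc, acc, nm, t), con)
    }
  }
  invisible(path)
}

#' Propagate annotations through the ontology (true-path closure)
#'
#' Each domain's term set is closed under `is_a`/`part_of` ancestry:
#' annotation to a term implies annotation to all of its ancestors.
#' Idempotent.
#'
#' @param dag a [go_dag()].
#' @param map a [domain_go_map()].
#' @return A `domain_go_map` of propagated annotations.
#' @export
propagate <- function(dag, map) {
  out <- lapply(unclass(map), function(ts) {
    if (length(ts) == 0L) return(character(0))
    sort(unique(c(ts, unlist(dag$ancestors[ts], use.names = FALSE))))
  })
  structure(out, class = "domain_go_map")
}

# invert a propagated map restricted to a domain universe:
# term -> character vector of annotated domains
term_to_domains <- function(map, universe = names(map)) {
  m <- unclass(map)[intersect(universe, names(map))]
  doms <- rep(names(m), lengths(m))
  split(doms, unlist(m, use.names = FALSE))
}
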
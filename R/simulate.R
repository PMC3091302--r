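#' Seeded evaluation helper
#'
#' Every stochastic operation in the package takes a mandatory seed and
#' restores the caller's RNG state afterwards, so identical configuration
#' plus seed gives byte-identical output and independent calls do not
#' perturb each other.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) stop("a seed is required")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Simulate single-gain / multi-loss domain evolution on a tree
#'
#' The generative model Dollo parsimony assumes: each domain originates
#' exactly once at a node drawn from the origin distribution, is
#' inherited along every branch of the origin clade, and on each branch
#' is lost with the branch's loss probability; once lost it is absent in
#' the entire subtree (no regain). Losses are only sampled inside the
#' origin clade, where they are observable in principle. Domains with no
#' surviving carrier leaf are retained in the truth record but flagged
#' unobservable (they cannot enter a presence matrix).
#'
#' @param tree a [rooted_tree()].
#' @param n_domains number of domains to evolve.
#' @param loss_prob per-branch loss probability in [0, 1): a single
#'   scalar, or a named vector keyed by child node covering every
#'   non-root node.
#' @param origin_weights named nonnegative weights over node names for
#'   the origin distribution; default puts half the mass on the root
#'   (most domains are ancient) and spreads the rest uniformly.
#' @param seed mandatory RNG seed.
#' @param acc_prefix accession prefix for the synthetic domains.
#' @return An object of class `sim_truth`: list with `tree`, `domains`,
#'   `origin` (named), `loss_edges` (named list of child-node names),
#'   `leaf_presence` (named list), `observable` (named logical),
#'   `matrix` (presence matrix over observable domains), `domainomes`
#'   (per-leaf [domainome()] list), `n_events` (1 gain + losses per
#'   domain, observable accounting).
#' @export
simulate_domain_evolution <- function(tree, n_domains, loss_prob = 0.1,
                                      origin_weights = NULL, seed,
                                      acc_prefix = "SD") {
  nodes <- tree$labels
  if (length(loss_prob) == 1L && is.null(names(loss_prob))) {
    lp <- stats::setNames(rep(as.numeric(loss_prob), tree$n_nodes), nodes)
  } else {
    lp <- stats::setNames(rep(NA_real_, tree$n_nodes), nodes)
    lp[names(loss_prob)] <- as.numeric(loss_prob)
    if (anyNA(lp[-tree$root]))
      stop("per-branch loss_prob must cover every non-root node")
  }
  if (any(lp < 0 | lp >= 1, na.rm = TRUE))
    stop("loss probabilities must lie in [0, 1)")
  if (is.null(origin_weights)) {
    w <- rep(0.5 / (tree$n_nodes - 1L), tree$n_nodes)
    w[tree$root] <- 0.5
  } else {
    w <- rep(0, tree$n_nodes)
    w[node_index(tree, names(origin_weights))] <- as.numeric(origin_weights)
    if (any(w < 0) || sum(w) <= 0) stop("invalid origin weights")
  }
  domains <- sprintf("%s%05d", acc_prefix, seq_len(n_domains))
  with_seed(seed, {
    origin_idx <- sample.int(tree$n_nodes, n_domains, replace = TRUE,
                             prob = w)
    origin <- stats::setNames(nodes[origin_idx], domains)
    loss_edges <- stats::setNames(vector("list", n_domains), domains)
    leaf_presence <- stats::setNames(vector("list", n_domains), domains)
    for (d in seq_len(n_domains)) {
      o <- origin_idx[d]
      lost_at <- integer(0)
      leaves <- integer(0)
      stack <- o
      while (length(stack)) {
        nd <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (tree$is_leaf[nd]) leaves <- c(leaves, nd)
        for (ch in tree$children[[nd]]) {
          if (stats::runif(1L) < lp[ch]) lost_at <- c(lost_at, ch)
          else stack <- c(stack, ch)
        }
      }
      loss_edges[[d]] <- sort(nodes[lost_at])
      leaf_presence[[d]] <- sort(nodes[leaves])
    }
    observable <- lengths(leaf_presence) > 0L
    lv <- leaf_labels(tree)
    obs <- which(observable)
    m <- matrix(0L, nrow = length(lv), ncol = length(obs),
                dimnames = list(lv, domains[obs]))
    for (j in seq_along(obs))
      m[leaf_presence[[obs[j]]], j] <- 1L
    m <- m[, order(colnames(m)), drop = FALSE]
    class(m) <- c("presence_matrix", class(m))
    domainomes <- lapply(lv, function(l)
      domainome(l, colnames(m)[m[l, ] == 1L]))
    structure(list(
      tree = tree, domains = domains, origin = origin,
      loss_edges = loss_edges, leaf_presence = leaf_presence,
      observable = stats::setNames(observable, domains),
      matrix = m, domainomes = domainomes,
      n_events = n_domains + sum(lengths(loss_edges))
    ), class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "sim_truth: %d domains on %d-leaf tree; %d observable; %d true events\n",
    length(x$domains), x$tree$n_tips, sum(x$observable), x$n_events))
  invisible(x)
}

#' Simulate a noisy domain-hit table around a known repertoire
#'
#' Emits one low-E-value, cutoff-passing, non-overlapping hit per domain
#' of the given repertoire (1-3 true domains per synthetic protein), plus
#' three kinds of decoy: hits that overlap a true hit with a higher
#' E-value (removed by overlap resolution), hits that fail the cutoffs
#' (high E-value and sub-gathering bit score), and cutoff-passing hits
#' carrying excluded accessions (removed by the exclusion list). The
#' truth record says which role each row plays, so the planted repertoire
#' is recoverable exactly.
#'
#' @param domainome a [domainome()]: the planted true repertoire.
#' @param n_decoys number of decoy hits.
#' @param overlap_rate fraction of decoys that overlap true hits.
#' @param excluded_rate fraction of decoys carrying excluded accessions.
#' @param excluded_accessions accession pool for excluded decoys.
#' @param seed mandatory RNG seed.
#' @return List with `hits` (a `domain_hits` data frame, row order
#'   shuffled), `role` (per-row: true / overlap_decoy / cutoff_decoy /
#'   excluded_decoy), `truth` (list: `domains`, `excluded`), and
#'   `exclusion` (an [exclusion_list()] covering the injected
#'   accessions).
#' @export
simulate_hit_table <- function(domainome, n_decoys = 50L,
                               overlap_rate = 0.4, excluded_rate = 0.2,
                               excluded_accessions = sprintf("XVIR%03d", 1:5),
                               seed) {
  stopifnot(overlap_rate >= 0, excluded_rate >= 0,
            overlap_rate + excluded_rate <= 1)
  doms <- domainome$domains
  if (length(doms) == 0L) stop("empty domainome")
  ga_thr <- 25.0
  with_seed(seed, {
    sizes <- integer(0)
    left <- length(doms)
    while (left > 0L) {
      s <- min(sample.int(3L, 1L), left)
      sizes <- c(sizes, s); left <- left - s
    }
    prot <- rep(sprintf("P%05d", seq_along(sizes)), sizes)
    ord_doms <- sample(doms)
    width <- sample(50:300, length(doms), replace = TRUE)
    start <- integer(length(doms)); endp <- integer(length(doms))
    pos <- 1L; last_prot <- ""
    for (i in seq_along(doms)) {
      if (prot[i] != last_prot) { pos <- 1L; last_prot <- prot[i] }
      start[i] <- pos
      endp[i] <- pos + width[i] - 1L
      pos <- endp[i] + sample(5:40, 1L)
    }
    true_hits <- domain_hits(
      protein_id = prot, domain_acc = ord_doms,
      env_start = start, env_end = endp,
      i_evalue = 10^stats::runif(length(doms), -30, -10),
      bit_score = stats::runif(length(doms), 100, 300),
      ga = ga_thr, nc = ga_thr - 5, tc = ga_thr + 5)
    n_over <- round(n_decoys * overlap_rate)
    n_excl <- round(n_decoys * excluded_rate)
    n_fail <- n_decoys - n_over - n_excl
    decoy <- function(n, acc, role) {
      if (n == 0L) return(NULL)
      tgt <- sample.int(length(doms), n, replace = TRUE)
      if (role == "overlap_decoy") {
        s <- pmax(1L, start[tgt] + sample(-20:20, n, replace = TRUE))
        e <- endp[tgt] + sample(0:30, n, replace = TRUE)
        ev <- 10^stats::runif(n, -6, -3)   # higher than any true E-value
        bs <- stats::runif(n, 30, 80)
      } else if (role == "cutoff_decoy") {
        s <- endp[tgt] + sample(400:600, n, replace = TRUE)
        e <- s + sample(30:120, n, replace = TRUE)
        ev <- stats::runif(n, 0.1, 1.9)    # passes only the raw 2.0 scan
        bs <- stats::runif(n, 5, ga_thr - 1)
      } else {                             # excluded_decoy
        s <- endp[tgt] + sample(700:900, n, replace = TRUE)
        e <- s + sample(30:120, n, replace = TRUE)
        ev <- 10^stats::runif(n, -25, -10)
        bs <- stats::runif(n, 100, 300)
      }
      h <- domain_hits(protein_id = prot[tgt], domain_acc = acc,
                       env_start = s, env_end = e, i_evalue = ev,
                       bit_score = bs, ga = ga_thr, nc = ga_thr - 5,
                       tc = ga_thr + 5)
      list(h = h, role = rep(role, n))
    }
    parts <- list(
      list(h = true_hits, role = rep("true", nrow(true_hits))),
      decoy(n_over, sprintf("DOVL%04d", seq_len(max(n_over, 1L))[seq_len(n_over)]),
            "overlap_decoy"),
      decoy(n_fail, sprintf("DCUT%04d", seq_len(max(n_fail, 1L))[seq_len(n_fail)]),
            "cutoff_decoy"),
      decoy(n_excl, sample(excluded_accessions, n_excl, replace = TRUE),
            "excluded_decoy"))
    parts <- parts[!vapply(parts, is.null, TRUE)]
    hits <- do.call(rbind, lapply(parts, `[[`, "h"))
    role <- unlist(lapply(parts, `[[`, "role"), use.names = FALSE)
    perm <- sample.int(nrow(hits))
    hits <- hits[perm, , drop = FALSE]
    rownames(hits) <- NULL
    class(hits) <- c("domain_hits", "data.frame")
    list(hits = hits, role = role[perm],
         truth = list(domains = doms,
                      excluded = sort(unique(
                        hits$domain_acc[role[perm] == "excluded_decoy"]))),
         exclusion = exclusion_list(excluded_accessions,
                                    "synthetic viral/transposon decoy"))
  })
}

#' Simulate a layered GO DAG with planted enrichment
#'
#' Generates a single-namespace ontology (one root, `is_a` edges, acyclic
#' by layered construction), uniform background annotations of 1-3 direct
#' terms per domain, and a study set drawn so that planted terms reach a
#' target fraction of study members annotated to them.
#'
#' @param n_terms total number of terms (including the root).
#' @param depth number of layers below the root.
#' @param n_domains population size.
#' @param planted named numeric vector: term id -> target fraction of the
#'   study annotated to it, each in (0, 1]; or an unnamed vector, in
#'   which case terms at maximal depth are picked (and reported in the
#'   truth record). Fractions above 1 are an error.
#' @param study_size study-set size.
#' @param seed mandatory RNG seed.
#' @param namespace ontology namespace of all generated terms.
#' @return List with `dag`, `map` (direct annotations), `study`
#'   (a [study_set()]), `population` (all domain accessions), `truth`
#'   (list: `planted` named fractions).
#' @export
simulate_go <- function(n_terms = 60L, depth = 4L, n_domains = 500L,
                        planted = numeric(0), study_size = 30L, seed,
                        namespace = "biological_process") {
  stopifnot(n_terms >= depth + 1L, depth >= 1L)
  if (any(planted > 1 | planted <= 0))
    stop("infeasible enrichment: planted fractions must lie in (0, 1]")
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  # ontologies fan out: few broad terms near the root, many specific
  # terms at the bottom; layer widths grow geometrically with depth
  w <- 4^seq_len(depth)
  sz <- pmax(1L, round((n_terms - 1L) * w / sum(w)))
  sz[depth] <- sz[depth] + (n_terms - 1L) - sum(sz)
  layer <- c(0L, rep(seq_len(depth), sz))
  with_seed(seed, {
    ch <- pa <- character(0)
    for (i in which(layer > 0L)) {
      pool <- ids[layer == layer[i] - 1L]
      ps <- sample(pool, min(length(pool), sample.int(2L, 1L)))
      ch <- c(ch, rep(ids[i], length(ps))); pa <- c(pa, ps)
    }
    dag <- go_dag(
      terms = data.frame(id = ids, name = paste0("synthetic term ", ids),
                         namespace = namespace, obsolete = FALSE,
                         stringsAsFactors = FALSE),
      edges = data.frame(child = ch, parent = pa, rel = "is_a",
                         stringsAsFactors = FALSE))
    doms <- sprintf("D%05d", seq_len(n_domains))
    # direct annotations go to the most specific (childless) terms, as in
    # real external2go mappings; breadth arises via true-path propagation
    specific <- setdiff(ids, dag$edges$parent)
    map <- domain_go_map(stats::setNames(lapply(seq_len(n_domains),
      function(i) sample(specific, sample.int(3L, 1L))), doms), dag)
    if (length(planted) && is.null(names(planted))) {
      # pick the most specific terms that (a) carry enough annotated
      # domains to realize the requested study fraction and (b) are a
      # genuine refinement of their parents: a term whose annotations
      # saturate the parents' overlap is unidentifiable in principle by
      # any method that conditions on parent annotations
      pmap0 <- propagate(dag, map)
      t2d0 <- term_to_domains(pmap0, doms)
      parents_of <- split(dag$edges$parent,
                          factor(dag$edges$child, levels = ids))
      getset <- function(t) {
        d <- t2d0[[t]]
        if (is.null(d)) character(0) else d
      }
      cand <- setdiff(ids, ids[1L])
      cnt <- vapply(cand, function(t) length(getset(t)), 0L)
      refines <- vapply(cand, function(t) {
        cond <- Reduce(intersect, lapply(parents_of[[t]], getset))
        # the conditioning set must be ~3x the term's own annotations,
        # otherwise the term explains its parents and carries no signal
        # of its own under parent-conditioned tests
        length(getset(t)) <= 0.3 * length(cond)
      }, TRUE)
      cand <- cand[refines]
      cand <- cand[order(-dag$depth[cand], -cnt[cand], cand)]
      picked <- character(0)
      for (i in seq_along(planted)) {
        need <- round(planted[i] * study_size)
        ok <- cand[!(cand %in% picked) & cnt[cand] >= need]
        if (length(ok) == 0L)
          stop(sprintf("infeasible enrichment: no refining term carries %d annotated domains",
                       need))
        picked <- c(picked, ok[1L])
      }
      names(planted) <- picked
    }
    if (length(planted) && !all(names(planted) %in% ids))
      stop("planted terms missing from the generated DAG: ",
           paste(setdiff(names(planted), ids), collapse = ", "))
    pmap <- propagate(dag, map)
    t2d <- term_to_domains(pmap, doms)
    study <- character(0)
    for (t in names(planted)) {
      need <- round(planted[[t]] * study_size)
      pool <- setdiff(t2d[[t]], study)
      if (length(pool) < need)
        stop(sprintf("infeasible enrichment: only %d domains annotated to %s",
                     length(pool), t))
      study <- c(study, sample(pool, need))
    }
    rest <- setdiff(doms, study)
    study <- c(study, sample(rest, study_size - length(study)))
    list(dag = dag, map = map,
         study = study_set("synthetic planted study", study),
         population = doms,
         truth = list(planted = planted))
  })
}
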
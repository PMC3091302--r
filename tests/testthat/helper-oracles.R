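# Independent reference implementations used as oracles. These are kept
# deliberately naive (enumeration, repeated scanning, matrix powers) and
# share no code with the package internals they check.

# --- rooted multifurcating tree shapes -------------------------------------

# all integer partitions of n into parts >= 1, as lists (descending)
int_partitions <- function(n, max_part = n) {
  if (n == 0L) return(list(integer(0)))
  out <- list()
  for (p in seq(min(n, max_part), 1L)) {
    for (rest in int_partitions(n - p, p))
      out[[length(out) + 1L]] <- c(p, rest)
  }
  out
}

# all rooted tree shapes (every internal node >= 2 children) with n leaves,
# as canonical nested strings; leaves are "x"
tree_shapes <- local({
  memo <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (n == 1L) return(memo[[key]] <<- "x")
    out <- character(0)
    for (part in int_partitions(n)) {
      if (length(part) < 2L) next
      child_sets <- lapply(part, function(k) tree_shapes(k))
      combos <- do.call(expand.grid,
                        c(child_sets, stringsAsFactors = FALSE))
      for (i in seq_len(nrow(combos))) {
        kids <- sort(unlist(combos[i, ], use.names = FALSE))
        out <- c(out, paste0("(", paste(kids, collapse = ","), ")"))
      }
    }
    memo[[key]] <<- unique(out)
  }
})

# shape string -> rooted_tree with leaves t1..tn
shape_to_tree <- function(shape) {
  n <- 0L
  nw <- gsub("x", "%s", shape, fixed = TRUE)
  k <- lengths(regmatches(shape, gregexpr("x", shape, fixed = TRUE)))
  labs <- paste0("t", seq_len(k))
  rooted_tree(paste0(do.call(sprintf, c(list(nw), as.list(labs))), ";"),
              assume_rooted = TRUE)
}

# --- brute-force Dollo oracle ----------------------------------------------

# enumerate every full 0/1 state assignment with exactly one 0->1
# transition (a single gain), returning leaf-state rows and loss counts
oracle_assignments <- function(tree) {
  n <- tree$n_nodes
  S <- as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
  nonroot <- seq_len(n)[-tree$root]
  P <- S[, tree$parent[nonroot], drop = FALSE]
  Cn <- S[, nonroot, drop = FALSE]
  gains <- rowSums(Cn == 1L & P == 0L) + (S[, tree$root] == 1L)
  valid <- gains == 1L
  list(leaf_states = S[valid, seq_len(tree$n_tips), drop = FALSE],
       losses = rowSums(Cn == 0L & P == 1L)[valid])
}

# minimum loss count over all single-gain assignments matching the column
oracle_min_losses <- function(oa, column) {
  hit <- colSums(abs(t(oa$leaf_states) - column)) == 0L
  if (!any(hit)) stop("no feasible single-gain assignment")
  min(oa$losses[hit])
}

# --- hypergeometric upper tail by log-space pmf summation ------------------

hyper_tail_oracle <- function(k, n, K, N) {
  kk <- k:min(n, K)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

# --- overlap resolution by repeated scanning -------------------------------

overlap_oracle <- function(hits) {
  remaining <- hits[order(hits$i_evalue, -hits$bit_score,
                          hits$domain_acc, hits$env_start), , drop = FALSE]
  accepted <- remaining[0, , drop = FALSE]
  while (nrow(remaining) > 0L) {
    cand <- remaining[1L, , drop = FALSE]
    remaining <- remaining[-1L, , drop = FALSE]
    clash <- FALSE
    for (j in seq_len(nrow(accepted)))
      if (cand$env_start <= accepted$env_end[j] &&
          cand$env_end >= accepted$env_start[j]) { clash <- TRUE; break }
    if (!clash) accepted <- rbind(accepted, cand)
  }
  accepted
}

# --- transitive reachability by boolean matrix powers ----------------------

reachability_oracle <- function(dag) {
  ids <- dag$terms$id
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(nrow(dag$edges)))
    A[dag$edges$child[i], dag$edges$parent[i]] <- TRUE
  R <- A
  repeat {
    R2 <- R | (R %*% A > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

# --- Benjamini-Hochberg step-up, quadratic ---------------------------------

bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[ord[j]] / j, 0)
    adj[ord[i]] <- min(1, min(vals))
  }
  adj
}

# --- misc fixtures ----------------------------------------------------------

# random 0/1 leaf columns with at least one presence
random_columns <- function(n_leaves, n_cols, p = 0.4) {
  m <- matrix(rbinom(n_leaves * n_cols, 1L, p), nrow = n_leaves)
  for (j in which(colSums(m) == 0L))
    m[sample.int(n_leaves, 1L), j] <- 1L
  m
}

# uniform 1-3 direct annotations per domain
random_annotation <- function(dag, domains) {
  terms <- dag$terms$id[dag$depth[dag$terms$id] > 0L & !dag$terms$obsolete]
  domain_go_map(stats::setNames(
    lapply(domains, function(d) sample(terms, sample.int(3L, 1L))),
    domains), dag)
}

mk_hit <- function(protein = "P1", acc = "PF00001", s = 1L, e = 100L,
                   ev = 1e-10, bs = 100, ga = 25) {
  domain_hits(protein, acc, s, e, ev, bs, ga = ga, nc = ga - 5, tc = ga + 5)
}
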
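#' Dollo parsimony for presence/absence characters
#'
#' Under Dollo parsimony a domain is gained exactly once — at the most
#' recent common ancestor of all leaves carrying it — and the
#' reconstruction minimizes the number of subsequent losses. A node inside
#' the gain clade is present iff its subtree retains at least one carrier
#' leaf; each maximal carrier-free subtree hanging off a present node
#' accounts for exactly one loss, on the edge into it.
#'
#' @name dollo
NULL

# preorder rank and subtree size: a clade is a contiguous preorder range
tree_ranges <- function(tree) {
  pre_rank <- integer(tree$n_nodes)
  pre_rank[tree$preorder] <- seq_len(tree$n_nodes)
  size <- rep(1L, tree$n_nodes)
  for (nd in tree$postorder)
    for (ch in tree$children[[nd]]) size[nd] <- size[nd] + size[ch]
  list(pre_rank = pre_rank, size = size)
}

# per-node carrier-leaf counts for every column of a leaf state matrix
subtree_counts <- function(tree, states) {
  C <- matrix(0L, nrow = tree$n_nodes, ncol = ncol(states))
  C[seq_len(tree$n_tips), ] <- states
  for (nd in tree$postorder) {
    kids <- tree$children[[nd]]
    if (length(kids))
      C[nd, ] <- .colSums(C[kids, , drop = FALSE], length(kids), ncol(C))
  }
  C
}

# leaf state matrix (n_tips x n_domains) from a presence matrix, ordered
# to the tree's leaf indexing
leaf_states <- function(tree, matrix) {
  lv <- leaf_labels(tree)
  miss <- setdiff(lv, rownames(matrix))
  extra <- setdiff(rownames(matrix), lv)
  if (length(miss) || length(extra))
    stop("leaf labels do not match matrix taxa; missing from matrix: {",
         paste(miss, collapse = ", "), "}, not in tree: {",
         paste(extra, collapse = ", "), "}")
  unclass(matrix)[lv, , drop = FALSE]
}

#' Infer the Dollo history of one domain
#'
#' @param tree a [rooted_tree()].
#' @param column named 0/1 vector over the tree's leaves (at least one 1).
#' @param domain_acc accession recorded in the result.
#' @return A `domain_history`: list with `domain_acc`, `gain_node`,
#'   `loss_edges` (named by the child node of each loss edge),
#'   `present_nodes`, `n_losses`.
#' @export
infer_history <- function(tree, column, domain_acc = "domain") {
  lv <- leaf_labels(tree)
  if (!all(lv %in% names(column)))
    stop("leaf missing from column: ",
         paste(setdiff(lv, names(column)), collapse = ", "))
  st <- matrix(as.integer(column[lv]), ncol = 1L)
  if (sum(st) == 0L)
    stop("all-absent column: no Dollo history exists (drop it upstream)")
  led <- reconstruct_core(tree, st, domain_acc)
  structure(list(domain_acc = domain_acc,
                 gain_node = led$gain_node[[1L]],
                 loss_edges = led$loss_edges[[1L]],
                 present_nodes = led$present_nodes[[1L]],
                 n_losses = length(led$loss_edges[[1L]])),
            class = "domain_history")
}

reconstruct_core <- function(tree, states, domains) {
  rg <- tree_ranges(tree)
  C <- subtree_counts(tree, states)
  total <- C[tree$root, ]
  if (any(total == 0L))
    stop("all-absent column(s): ",
         paste(domains[total == 0L], collapse = ", "))
  # gain node: deepest node whose subtree holds every carrier leaf
  cand <- C == rep(total, each = nrow(C))
  score <- ifelse(cand, tree$depth, -1L)
  gain <- max.col(t(score), ties.method = "first")
  D <- ncol(states)
  gain_node <- tree$labels[gain]
  loss_edges <- vector("list", D)
  present_nodes <- vector("list", D)
  nonroot <- seq_len(tree$n_nodes)[-tree$root]
  par <- tree$parent
  for (d in seq_len(D)) {
    g <- gain[d]
    lo <- rg$pre_rank[g]; hi <- lo + rg$size[g] - 1L
    in_clade <- rg$pre_rank >= lo & rg$pre_rank <= hi
    present <- which(in_clade & C[, d] > 0L)
    lost <- nonroot[C[nonroot, d] == 0L & C[par[nonroot], d] > 0L &
                      in_clade[par[nonroot]]]
    present_nodes[[d]] <- tree$labels[present]
    loss_edges[[d]] <- tree$labels[lost]
  }
  list(gain_node = gain_node, loss_edges = loss_edges,
       present_nodes = present_nodes)
}

#' Reconstruct ancestral domainomes and per-branch events
#'
#' Applies [infer_history()] to every column of a presence matrix and
#' aggregates the results into an event ledger: per-branch gained and lost
#' domain sets (branches keyed by their child node), per-node present
#' sets, and the total parsimony cost (one gain per domain plus all
#' losses). Domains whose gain node is the root form a distinguished
#' root-origin ("ancestral stock") set, since the root has no parent
#' branch.
#'
#' @param tree a [rooted_tree()] whose leaf set equals the matrix's taxa.
#' @param matrix a `presence_matrix` from [build_matrix()].
#' @return An object of class `event_ledger`: list with `tree`, `domains`,
#'   `gain_node` (named character), `loss_edges` (named list), `gains`,
#'   `losses`, `present` (named lists of sorted accession vectors),
#'   `root_gains`, `n_losses`, `cost`.
#' @export
reconstruct <- function(tree, matrix) {
  st <- leaf_states(tree, matrix)
  domains <- colnames(matrix)
  core <- reconstruct_core(tree, st, domains)
  node_names <- tree$labels
  gains <- losses <- stats::setNames(
    rep(list(character(0)), tree$n_nodes), node_names)
  present <- gains
  root_name <- node_names[tree$root]
  root_gains <- character(0)
  for (d in seq_along(domains)) {
    g <- core$gain_node[d]
    if (g == root_name) root_gains <- c(root_gains, domains[d])
    else gains[[g]] <- c(gains[[g]], domains[d])
    for (l in core$loss_edges[[d]])
      losses[[l]] <- c(losses[[l]], domains[d])
    for (p in core$present_nodes[[d]])
      present[[p]] <- c(present[[p]], domains[d])
  }
  gains <- lapply(gains, sort)
  losses <- lapply(losses, sort)
  present <- lapply(present, sort)
  n_losses <- sum(lengths(core$loss_edges))
  structure(list(
    tree = tree, domains = domains,
    gain_node = stats::setNames(core$gain_node, domains),
    loss_edges = stats::setNames(core$loss_edges, domains),
    gains = gains, losses = losses, present = present,
    root_gains = sort(root_gains),
    n_losses = n_losses,
    cost = length(domains) + n_losses
  ), class = "event_ledger")
}

#' @export
print.event_ledger <- function(x, ...) {
  cat(sprintf(
    "event_ledger: %d domains on %d-leaf tree; %d losses; cost %d\n",
    length(x$domains), x$tree$n_tips, x$n_losses, x$cost))
  cat(sprintf("root ('%s') repertoire: %d domains (%d root-origin)\n",
              x$tree$labels[x$tree$root],
              length(x$present[[x$tree$labels[x$tree$root]]]),
              length(x$root_gains)))
  invisible(x)
}

#' Total Dollo cost of a matrix on a tree
#'
#' One gain per domain plus all inferred losses; the quantity used to rank
#' alternative topologies.
#'
#' @inheritParams reconstruct
#' @return Nonnegative integer cost.
#' @export
tree_cost <- function(tree, matrix) {
  st <- leaf_states(tree, matrix)
  rg <- tree_ranges(tree)
  C <- subtree_counts(tree, st)
  total <- C[tree$root, ]
  if (any(total == 0L)) stop("all-absent column(s) in matrix")
  cand <- C == rep(total, each = nrow(C))
  score <- ifelse(cand, tree$depth, -1L)
  gain <- max.col(t(score), ties.method = "first")
  nonroot <- seq_len(tree$n_nodes)[-tree$root]
  par <- tree$parent
  n_loss <- 0L
  for (d in seq_len(ncol(st))) {
    g <- gain[d]
    lo <- rg$pre_rank[g]; hi <- lo + rg$size[g] - 1L
    in_clade <- rg$pre_rank >= lo & rg$pre_rank <= hi
    n_loss <- n_loss + sum(C[nonroot, d] == 0L & C[par[nonroot], d] > 0L &
                             in_clade[par[nonroot]])
  }
  ncol(st) + n_loss
}

#' Rank alternative topologies by Dollo cost
#'
#' @param trees named or unnamed list of [rooted_tree()] objects sharing
#'   one leaf set.
#' @param matrix a `presence_matrix` over that leaf set.
#' @return Data frame with columns `tree`, `cost`, `rank`, stably sorted
#'   ascending by cost (input order breaks ties).
#' @export
compare_topologies <- function(trees, matrix) {
  stopifnot(length(trees) >= 1L)
  ids <- names(trees)
  if (is.null(ids)) ids <- paste0("tree", seq_along(trees))
  ref <- sort(leaf_labels(trees[[1L]]))
  for (i in seq_along(trees))
    if (!identical(sort(leaf_labels(trees[[i]])), ref))
      stop("leaf-set mismatch between trees[1] and trees[", i, "]")
  costs <- vapply(trees, tree_cost, 0, matrix = matrix)
  ord <- order(costs)  # stable
  data.frame(tree = ids[ord], cost = unname(costs[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Summarize a clade's ancestral and extant repertoires
#'
#' Gains and losses are read from the branch entering the clade root
#' (root-origin domains for the tree root itself); mean and sample
#' standard deviation (n-1 denominator) are taken over the repertoire
#' sizes of the clade's extant genomes.
#'
#' @param tree a [rooted_tree()].
#' @param ledger an `event_ledger` from [reconstruct()].
#' @param domainomes list of leaf [domainome()] objects (labels matching
#'   leaves).
#' @param clade_root node name.
#' @return Data frame of class `clade_summary` with columns `clade`,
#'   `gains`, `losses`, `present`, `extant_mean`, `extant_sd`,
#'   `n_genomes`, `sd_defined` (FALSE for single-genome clades, where the
#'   SD is reported as 0).
#' @export
clade_summary <- function(tree, ledger, domainomes, clade_root) {
  node_index(tree, clade_root)  # errors on unknown node
  leaves <- clade_leaves(tree, clade_root)
  sizes <- stats::setNames(
    vapply(domainomes, function(d) length(d$domains), 0L),
    vapply(domainomes, function(d) d$label, ""))
  miss <- setdiff(leaves, names(sizes))
  if (length(miss))
    stop("no domainome supplied for leaf/leaves: ",
         paste(miss, collapse = ", "))
  sz <- sizes[leaves]
  is_root <- clade_root == tree$labels[tree$root]
  gains <- if (is_root) length(ledger$root_gains)
           else length(ledger$gains[[clade_root]])
  losses <- if (is_root) 0L else length(ledger$losses[[clade_root]])
  sd_def <- length(sz) > 1L
  out <- data.frame(
    clade = clade_root, gains = gains, losses = losses,
    present = length(ledger$present[[clade_root]]),
    extant_mean = mean(sz),
    extant_sd = if (sd_def) stats::sd(sz) else 0,
    n_genomes = length(sz), sd_defined = sd_def,
    stringsAsFactors = FALSE)
  class(out) <- c("clade_summary", "data.frame")
  out
}

#' Export per-branch and per-node ledger tables
#'
#' @param ledger an `event_ledger`.
#' @return Data frame with one row per node: `node`, `parent` (`""` at
#'   the root), `is_leaf`, `n_present`, `n_gained`, `n_lost` (root row
#'   reports root-origin gains).
#' @export
ledger_table <- function(ledger) {
  tree <- ledger$tree
  nodes <- tree$labels[tree$preorder]
  pv <- tree$parent[tree$preorder]
  parent <- character(length(pv))
  parent[pv != 0L] <- tree$labels[pv[pv != 0L]]
  root_name <- tree$labels[tree$root]
  data.frame(
    node = nodes, parent = parent,
    is_leaf = tree$is_leaf[tree$preorder],
    n_present = vapply(ledger$present[nodes], length, 0L),
    n_gained = vapply(nodes, function(n)
      if (n == root_name) length(ledger$root_gains)
      else length(ledger$gains[[n]]), 0L),
    n_lost = vapply(ledger$losses[nodes], length, 0L),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Write ledger exports as TSV files
#'
#' Writes `<prefix>_branches.tsv` (per-branch gain/loss counts and domain
#' lists) and `<prefix>_nodes.tsv` (per-node present counts).
#'
#' @param ledger an `event_ledger`.
#' @param prefix output path prefix.
#' @return Invisibly, the two paths written.
#' @export
write_ledger_tsv <- function(ledger, prefix) {
  tb <- ledger_table(ledger)
  root_name <- ledger$tree$labels[ledger$tree$root]
  br <- tb
  br$gained_domains <- vapply(tb$node, function(n)
    paste(if (n == root_name) ledger$root_gains else ledger$gains[[n]],
          collapse = ","), "")
  br$lost_domains <- vapply(tb$node, function(n)
    paste(ledger$losses[[n]], collapse = ","), "")
  p1 <- paste0(prefix, "_branches.tsv")
  p2 <- paste0(prefix, "_nodes.tsv")
  utils::write.table(br[, c("node", "parent", "n_gained", "n_lost",
                            "gained_domains", "lost_domains")],
                     p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tb[, c("node", "is_leaf", "n_present")],
                     p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
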
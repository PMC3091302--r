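#' Build a rooted species tree
#'
#' Wraps an \pkg{ape} `phylo` object with indexed parent/children links,
#' traversal orders and unique node names. Polytomies are allowed; the
#' tree must be rooted (Dollo parsimony is direction-dependent). Unnamed
#' internal nodes are auto-named `N1..Nk` in preorder, so names are stable
#' across runs.
#'
#' @param phy an `ape::phylo` object, or a Newick string / file path.
#' @param root_on optional outgroup taxon; if `phy` is unrooted the tree
#'   is rooted on this taxon, otherwise unrooted input is rejected.
#' @param assume_rooted treat the outermost Newick node as the root even
#'   when it is a polytomy (which \pkg{ape} reports as unrooted);
#'   published rooted species trees often have a basal polytomy.
#' @return An object of class `rooted_tree`: list with elements `phy`,
#'   `n_tips`, `n_nodes`, `labels`, `parent` (0 at root), `children`,
#'   `root`, `preorder`, `postorder`, `depth`, `is_leaf`.
#' @export
rooted_tree <- function(phy, root_on = NULL, assume_rooted = FALSE) {
  if (is.character(phy)) {
    phy <- if (file.exists(phy)) ape::read.tree(phy)
           else ape::read.tree(text = phy)
    if (is.null(phy)) stop("could not parse Newick input")
  }
  stopifnot(inherits(phy, "phylo"))
  if (!ape::is.rooted(phy) && !assume_rooted) {
    if (is.null(root_on))
      stop("unrooted tree: supply root_on = <outgroup taxon> to root it")
    phy <- ape::root(phy, outgroup = root_on, resolve.root = TRUE)
  }
  n_tips <- length(phy$tip.label)
  n_nodes <- n_tips + phy$Nnode
  parent <- integer(n_nodes)
  children <- vector("list", n_nodes)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; c <- phy$edge[i, 2L]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
  }
  root <- n_tips + 1L
  # preorder: iterative DFS, children in stored order
  preorder <- integer(n_nodes)
  stack <- root; k <- 0L
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    k <- k + 1L; preorder[k] <- nd
    kids <- children[[nd]]
    if (length(kids)) stack <- c(stack, rev(kids))
  }
  depth <- integer(n_nodes)
  for (nd in preorder[-1L]) depth[nd] <- depth[parent[nd]] + 1L
  labels <- character(n_nodes)
  labels[seq_len(n_tips)] <- phy$tip.label
  if (!is.null(phy$node.label))
    labels[(n_tips + 1L):n_nodes] <-
      ifelse(is.na(phy$node.label) | phy$node.label == "",
             "", phy$node.label)
  k <- 0L
  for (nd in preorder) {
    if (nd > n_tips && labels[nd] == "") {
      repeat {
        k <- k + 1L
        cand <- paste0("N", k)
        if (!cand %in% labels) break
      }
      labels[nd] <- cand
    }
  }
  if (anyDuplicated(labels))
    stop("duplicate node names: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  phy$node.label <- labels[(n_tips + 1L):n_nodes]
  structure(list(
    phy = phy, n_tips = n_tips, n_nodes = n_nodes, labels = labels,
    parent = parent, children = children, root = root,
    preorder = preorder, postorder = rev(preorder), depth = depth,
    is_leaf = seq_len(n_nodes) <= n_tips
  ), class = "rooted_tree")
}

#' @export
print.rooted_tree <- function(x, ...) {
  cat(sprintf("rooted_tree: %d leaves, %d internal nodes (root '%s')\n",
              x$n_tips, x$n_nodes - x$n_tips, x$labels[x$root]))
  invisible(x)
}

#' @rdname rooted_tree
#' @param path Newick file path.
#' @export
read_newick <- function(path, root_on = NULL) rooted_tree(path, root_on)

#' Write a rooted tree to Newick
#' @param tree a `rooted_tree`.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree$phy, file = path)
  invisible(path)
}

node_index <- function(tree, name) {
  i <- match(name, tree$labels)
  if (anyNA(i)) stop("unknown node name(s): ",
                     paste(name[is.na(i)], collapse = ", "))
  i
}

#' Leaf labels of a rooted tree, in tip-index order
#' @param tree a `rooted_tree`.
#' @return Character vector of leaf (genome) labels.
#' @export
leaf_labels <- function(tree) tree$labels[seq_len(tree$n_tips)]

#' Leaves of the clade rooted at a node
#' @param tree a `rooted_tree`.
#' @param node node name.
#' @return Character vector of leaf labels in the clade.
#' @export
clade_leaves <- function(tree, node) {
  nd <- node_index(tree, node)
  out <- integer(0); stack <- nd
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (tree$is_leaf[x]) out <- c(out, x)
    else stack <- c(stack, tree$children[[x]])
  }
  tree$labels[sort(out)]
}

#' Path of node names from the root to a node
#' @param tree a `rooted_tree`.
#' @param node node name.
#' @return Character vector of node names, root first.
#' @export
root_path <- function(tree, node) {
  nd <- node_index(tree, node)
  path <- nd
  while (tree$parent[nd] != 0L) {
    nd <- tree$parent[nd]
    path <- c(nd, path)
  }
  tree$labels[path]
}

#' Randomly perturb a tree by subtree prune and regraft
#'
#' Detaches a random non-root clade and reattaches it on a random branch
#' outside that clade, preserving rootedness. Used to generate alternative
#' topologies for parsimony-cost comparison.
#'
#' @param tree a `rooted_tree`.
#' @param moves number of successive SPR moves.
#' @return A new `rooted_tree` over the same leaf set.
#' @export
perturb_tree_spr <- function(tree, moves = 1L) {
  for (m in seq_len(moves)) tree <- spr_once(tree)
  tree
}

subtree_nodes <- function(tree, nd) {
  out <- integer(0); stack <- nd
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, x)
    stack <- c(stack, tree$children[[x]])
  }
  out
}

spr_once <- function(tree) {
  root <- tree$root
  repeat {
    p <- sample(setdiff(seq_len(tree$n_nodes), root), 1L)
    sub <- subtree_nodes(tree, p)
    # regraft edges: any edge whose child lies outside the pruned clade
    # (grafting above the old parent is allowed; unary nodes collapse)
    targets <- setdiff(seq_len(tree$n_nodes), c(sub, root))
    if (length(targets) >= 1L) break
  }
  v <- if (length(targets) == 1L) targets else sample(targets, 1L)
  kids <- tree$children; par <- tree$parent
  pp <- par[p]
  kids[[pp]] <- setdiff(kids[[pp]], p)
  # insert a new node on the edge into v and hang the pruned clade there
  nn <- tree$n_nodes + 1L
  pv <- par[v]
  kids[[pv]][kids[[pv]] == v] <- nn
  kids[[nn]] <- c(v, p)
  # emit Newick, suppressing nodes left with a single child
  emit <- function(nd) {
    k <- kids[[nd]]
    if (length(k) == 0L) return(tree$labels[nd])
    if (length(k) == 1L) return(emit(k[1L]))
    paste0("(", paste(vapply(k, emit, ""), collapse = ","), ")")
  }
  rooted_tree(paste0(emit(root), ";"), assume_rooted = TRUE)
}

#' Simulate a random rooted tree shape
#'
#' Uniform coalescent-style random binary topology over `n_leaves` labelled
#' leaves (no branch lengths used downstream).
#'
#' @param n_leaves number of leaves.
#' @param labels optional leaf labels, default `t1..tn`.
#' @return A `rooted_tree`.
#' @export
simulate_tree <- function(n_leaves, labels = NULL) {
  if (is.null(labels)) labels <- paste0("t", seq_len(n_leaves))
  stopifnot(length(labels) == n_leaves, n_leaves >= 2L)
  phy <- ape::rtree(n_leaves, rooted = TRUE, tip.label = labels, br = NULL)
  phy$node.label <- NULL
  rooted_tree(phy)
}
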
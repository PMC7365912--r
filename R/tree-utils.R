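# Internal rooted-tree representation used by the reconciliation code.
#
# An `rtree` is a plain list:
#   n        total number of nodes
#   n_tip    number of tips
#   parent   integer vector, parent[i] = parent node of i (0 for the root)
#   children list of integer vectors (empty for tips)
#   label    character vector of node labels ("" allowed for internals)
#   root     root node index
#   postorder integer vector: every node appears after all its descendants
#
# Tips are the nodes with no children; indices are arbitrary otherwise.

as_rtree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("expected an ape 'phylo' tree")
  n_tip <- length(phy$tip.label)
  n_all <- n_tip + phy$Nnode
  parent <- integer(n_all)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  children <- rep(list(integer(0)), n_all)
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1]
    children[[a]] <- c(children[[a]], phy$edge[i, 2])
  }
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  label <- c(phy$tip.label,
             if (!is.null(phy$node.label)) phy$node.label else rep("", phy$Nnode))
  label[is.na(label)] <- ""
  tr <- list(n = n_all, n_tip = n_tip, parent = parent, children = children,
             label = label, root = root)
  tr$postorder <- rtree_postorder(tr)
  class(tr) <- "rtree"
  tr
}

rtree_postorder <- function(tr) {
  out <- integer(tr$n)
  stack <- tr$root
  i <- 0L
  while (length(stack) > 0L) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    i <- i + 1L
    out[i] <- nd
    kids <- tr$children[[nd]]
    if (length(kids)) stack <- c(stack, kids)
  }
  rev(out)
}

rtree_is_binary <- function(tr) {
  all(vapply(tr$children, length, 1L) %in% c(0L, 2L))
}

rtree_tips <- function(tr) which(vapply(tr$children, length, 1L) == 0L)

# depth (edges from root) for every node
rtree_depths <- function(tr) {
  depth <- integer(tr$n)
  for (nd in rev(tr$postorder)) {          # preorder
    p <- tr$parent[nd]
    depth[nd] <- if (p == 0L) 0L else depth[p] + 1L
  }
  depth
}

# tip labels below each node, as a list of character vectors
rtree_clades <- function(tr) {
  below <- vector("list", tr$n)
  for (nd in tr$postorder) {
    kids <- tr$children[[nd]]
    below[[nd]] <- if (length(kids) == 0L) tr$label[nd] else
      unlist(below[kids], use.names = FALSE)
  }
  below
}

# LCA of two nodes by walking up with depths; species trees are small
rtree_lca <- function(tr, depth, a, b) {
  while (a != b) {
    if (depth[a] < depth[b]) b <- tr$parent[b]
    else if (depth[b] < depth[a]) a <- tr$parent[a]
    else { a <- tr$parent[a]; b <- tr$parent[b] }
  }
  a
}

# is `anc` an ancestor of (or equal to) `nd`?
rtree_is_ancestor <- function(tr, depth, anc, nd) {
  while (depth[nd] > depth[anc]) nd <- tr$parent[nd]
  nd == anc
}

rtree_sibling <- function(tr, nd) {
  p <- tr$parent[nd]
  if (p == 0L) return(0L)
  setdiff(tr$children[[p]], nd)
}

rtree_newick <- function(tr) {
  build <- function(nd) {
    kids <- tr$children[[nd]]
    if (length(kids) == 0L) return(tr$label[nd])
    paste0("(", paste(vapply(kids, build, ""), collapse = ","), ")",
           tr$label[nd])
  }
  paste0(build(tr$root), ";")
}

rtree_to_phylo <- function(tr) {
  ape::read.tree(text = rtree_newick(tr))
}

# Undirected adjacency view of a tree, used for enumerating root positions.
# A rooted binary tree is first "unrooted" by fusing the two root edges.
tree_adjacency <- function(phy) {
  if (ape::is.rooted(phy) && length(phy$tip.label) > 2L) phy <- ape::unroot(phy)
  n_tip <- length(phy$tip.label)
  n_all <- n_tip + phy$Nnode
  adj <- rep(list(integer(0)), n_all)
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1]; b <- phy$edge[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  list(adj = adj, n_tip = n_tip, n = n_all,
       label = c(phy$tip.label, rep("", phy$Nnode)),
       edges = cbind(phy$edge[, 1], phy$edge[, 2]))
}

# Root the undirected tree on edge (u,v): a new root is created whose two
# children are the u-side and v-side subtrees. Returns an `rtree`.
root_at_edge <- function(und, u, v) {
  env <- new.env(parent = emptyenv())
  env$parent <- integer(0); env$children <- list(); env$label <- character(0)
  new_node <- function(lab) {
    k <- length(env$parent) + 1L
    env$parent[k] <- 0L
    env$children[[k]] <- integer(0)
    env$label[k] <- lab
    k
  }
  build <- function(node, from) {
    idx <- new_node(und$label[node])
    for (nb in und$adj[[node]]) {
      if (nb == from) next
      child <- build(nb, node)
      env$parent[child] <- idx
      env$children[[idx]] <- c(env$children[[idx]], child)
    }
    idx
  }
  root <- new_node("")
  left <- build(u, v); right <- build(v, u)
  env$parent[left] <- root; env$parent[right] <- root
  env$children[[root]] <- c(left, right)
  n <- length(env$parent)
  tr <- list(n = n, n_tip = sum(vapply(env$children, length, 1L) == 0L),
             parent = env$parent, children = env$children,
             label = env$label, root = root)
  tr$postorder <- rtree_postorder(tr)
  class(tr) <- "rtree"
  tr
}
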
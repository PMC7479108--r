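# Shared tree bookkeeping built on ape's phylo representation.
# Branches are identified by the label of their child node throughout the
# package, so shift sets survive re-serialization of the newick.

#' Root-to-node path lengths
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @return Numeric vector over all nodes (tips first, then internals),
#'   distance from the root measured along branches.
#' @keywords internal
node_depths <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  depth <- numeric(n_all)
  root <- n_tip + 1L
  ord <- reorder(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1L]
    c <- ord$edge[k, 2L]
    depth[c] <- depth[p] + ord$edge.length[k]
  }
  depth
}

#' Node ages of a dated tree
#'
#' Ages are measured backwards from the most distant tip (age 0 at the
#' present for ultrametric trees).
#'
#' @param tree A rooted, dated `phylo` object (branch lengths in MY).
#' @return Numeric vector of ages for all nodes (tips first).
#' @export
node_ages <- function(tree) {
  depth <- node_depths(tree)
  max(depth) - depth
}

#' Check ultrametricity within an absolute tolerance
#'
#' @param tree A rooted `phylo` object.
#' @param tol Maximum allowed spread of tip depths.
#' @return Logical.
#' @export
is_ultrametric_tol <- function(tree, tol = 1e-6) {
  depth <- node_depths(tree)
  tip_depth <- depth[seq_along(tree$tip.label)]
  diff(range(tip_depth)) <= tol
}

# Assign stable labels to unlabeled internal nodes.
ensure_node_labels <- function(tree, prefix = "N") {
  n_tip <- length(tree$tip.label)
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", tree$Nnode)
  empty <- is.na(lab) | lab == ""
  lab[empty] <- paste0(prefix, which(empty))
  if (anyDuplicated(lab)) lab <- make.unique(lab, sep = "_")
  tree$node.label <- lab
  tree
}

# Label of any node (tip or internal) by its ape index.
node_label <- function(tree, idx) {
  n_tip <- length(tree$tip.label)
  out <- character(length(idx))
  is_tip <- idx <= n_tip
  out[is_tip] <- tree$tip.label[idx[is_tip]]
  out[!is_tip] <- tree$node.label[idx[!is_tip] - n_tip]
  out
}

# ape index of a node given its label; internal nodes must be labeled.
node_index <- function(tree, label) {
  n_tip <- length(tree$tip.label)
  i <- match(label, tree$tip.label)
  j <- match(label, tree$node.label)
  out <- ifelse(!is.na(i), i, ifelse(!is.na(j), j + n_tip, NA_integer_))
  if (anyNA(out)) stop("unknown node label(s): ",
                       paste(label[is.na(out)], collapse = ", "))
  as.integer(out)
}

#' Branch identifiers of a tree
#'
#' Branches are named by the label of their child node.
#'
#' @param tree A rooted `phylo` object with node labels.
#' @return Character vector, one ID per edge (in `tree$edge` order).
#' @export
branch_ids <- function(tree) {
  node_label(tree, tree$edge[, 2L])
}

# Tip index sets below every node (list over all node indices).
tips_under <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  out <- vector("list", n_all)
  for (i in seq_len(n_tip)) out[[i]] <- i
  ord <- reorder(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1L]
    c <- ord$edge[k, 2L]
    out[[p]] <- c(out[[p]], out[[c]])
  }
  out
}

# Children indices of every node; list indexed by node.
children_of <- function(tree) {
  n_all <- length(tree$tip.label) + tree$Nnode
  out <- vector("list", n_all)
  for (k in seq_len(nrow(tree$edge))) {
    out[[tree$edge[k, 1L]]] <- c(out[[tree$edge[k, 1L]]], tree$edge[k, 2L])
  }
  out
}

# Parent index of every node (0 for the root).
parent_of <- function(tree) {
  n_all <- length(tree$tip.label) + tree$Nnode
  out <- integer(n_all)
  out[tree$edge[, 2L]] <- tree$edge[, 1L]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic 31-bit seed derived from a global seed and string parts.
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h + 1)
}
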
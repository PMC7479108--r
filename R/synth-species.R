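# Synthetic dated species trees. The real analysis consumes a TimeTree-style
# ultrametric species phylogeny; the simulator needs one with the same
# properties (rooted, ultrametric, ages in MY).

#' Simulate a dated species tree
#'
#' Draws a random coalescent topology and rescales it so the root sits at
#' `root_age` million years. Tips are labeled `sp01 ...`, internal nodes
#' `S1 ...`.
#'
#' @param n_species Number of extant species.
#' @param root_age Root age in MY.
#' @param seed Integer seed.
#' @return A rooted ultrametric `phylo` with node labels; branch lengths in MY.
#' @export
sim_species_tree <- function(n_species, root_age = 450, seed = 1) {
  stopifnot(n_species >= 2, root_age > 0)
  set.seed(derive_seed(seed, "species_tree"))
  tree <- ape::rcoal(n_species,
                     tip.label = sprintf("sp%02d", seq_len(n_species)))
  depth <- max(node_depths(tree))
  tree$edge.length <- tree$edge.length * (root_age / depth)
  tree$node.label <- paste0("S", seq_len(tree$Nnode))
  tree
}

#' Validate a dated species tree and extract its ages
#'
#' @param tree A rooted `phylo`, branch lengths in MY.
#' @param tol Ultrametricity tolerance in MY.
#' @return List with `tree` (node-labeled), `newick`, `ages` (named by node
#'   label), and `n_species`.
#' @export
species_tree_spec <- function(tree, tol = 1e-9) {
  if (!inherits(tree, "phylo")) stop("species tree must be a 'phylo' object")
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  tree <- ensure_node_labels(tree, prefix = "S")
  if (!is_ultrametric_tol(tree, tol)) {
    stop("species tree is not ultrametric within ", tol, " MY")
  }
  ages <- node_ages(tree)
  if (any(ages < -tol)) stop("negative node ages")
  n_tip <- length(tree$tip.label)
  root_age <- ages[n_tip + 1L]
  if (root_age <= 0) stop("root age must be positive")
  names(ages) <- node_label(tree, seq_along(ages))
  list(tree = tree, newick = ape::write.tree(tree), ages = ages,
       n_species = n_tip)
}
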
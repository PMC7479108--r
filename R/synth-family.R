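# Gene family simulation: a branch-wise Gillespie birth-death process along
# a dated species tree. Events per gene lineage per MY: DNA-based duplication
# (D), loss, and retrotransposition (R = duplication whose new copy loses all
# introns and relocates to another chromosome). Surviving lineages at species
# tips become genes; speciation nodes in the gene tree are S nodes.

#' Parameters for gene family simulation
#'
#' @param dup_rate DNA-duplication rate, events/gene/MY.
#' @param loss_rate Loss rate, events/gene/MY.
#' @param retro_rate Retrotransposition rate, events/gene/MY.
#' @param seed Integer seed.
#' @param intron_count0 Intron count of the ancestral gene.
#' @param start_chromosome Chromosome of the ancestral gene
#'   (one of "A", "X", "Y").
#' @param subst_rate_mean Mean substitution rate (subst/site/MY) used to turn
#'   MY durations into sequence-scale branch lengths.
#' @param subst_rate_sdlog Log-SD of the per-branch lognormal rate multiplier
#'   (0 gives a strict clock).
#' @return A `family_sim_params` list.
#' @export
family_sim_params <- function(dup_rate = 5e-4, loss_rate = 5e-4,
                              retro_rate = 5e-5, seed = 1,
                              intron_count0 = 5L, start_chromosome = "A",
                              subst_rate_mean = 2e-3, subst_rate_sdlog = 0) {
  stopifnot(dup_rate >= 0, loss_rate >= 0, retro_rate >= 0,
            is.finite(dup_rate + loss_rate + retro_rate),
            intron_count0 >= 0,
            start_chromosome %in% c("A", "X", "Y"),
            subst_rate_mean > 0, subst_rate_sdlog >= 0)
  structure(list(dup_rate = dup_rate, loss_rate = loss_rate,
                 retro_rate = retro_rate, seed = as.integer(seed),
                 intron_count0 = as.integer(intron_count0),
                 start_chromosome = start_chromosome,
                 subst_rate_mean = subst_rate_mean,
                 subst_rate_sdlog = subst_rate_sdlog),
            class = "family_sim_params")
}

# Simulate the fate of one gene lineage along a species-tree edge running
# from age `a0` down to the species node `sp_node` (age a1). Returns NULL if
# the lineage is lost, otherwise a nested node record.
sim_lineage <- function(env, sp_node, a0, state) {
  a1 <- env$sp_ages[sp_node]
  rate <- env$total_rate
  a <- a0
  repeat {
    w <- if (rate > 0) stats::rexp(1, rate) else Inf
    if (a - w <= a1) {
      # reached the species node without an event
      return(sim_species_node(env, sp_node, state))
    }
    a <- a - w
    ev <- sample(c("D", "L", "R"), 1,
                 prob = c(env$p$dup_rate, env$p$loss_rate, env$p$retro_rate))
    if (ev == "L") return(NULL)
    if (ev == "D") {
      left <- sim_lineage(env, sp_node, a, state)
      right <- sim_lineage(env, sp_node, a, state)
      return(join_children(left, right, event = "D", age = a,
                           retro_child = NA))
    }
    # retrotransposition: new copy is intronless and relocates
    new_state <- state
    new_state$introns <- 0L
    new_state$chrom <- sample(setdiff(c("A", "X", "Y"), state$chrom), 1)
    orig <- sim_lineage(env, sp_node, a, state)
    retro <- sim_lineage(env, sp_node, a, new_state)
    return(join_children(orig, retro, event = "R", age = a,
                         retro_child = 2L))
  }
}

sim_species_node <- function(env, sp_node, state) {
  kids <- env$sp_children[[sp_node]]
  if (length(kids) == 0) {
    # species tip: surviving gene
    return(list(type = "tip", species = env$sp_labels[sp_node],
                age = env$sp_ages[sp_node], state = state))
  }
  left <- sim_lineage(env, kids[1], env$sp_ages[sp_node], state)
  right <- sim_lineage(env, kids[2], env$sp_ages[sp_node], state)
  join_children(left, right, event = "S", age = env$sp_ages[sp_node],
                retro_child = NA)
}

# Combine two child subtrees; suppress the node when a side died out.
join_children <- function(left, right, event, age, retro_child) {
  if (is.null(left) && is.null(right)) return(NULL)
  if (is.null(left)) {
    out <- right
    if (!is.na(retro_child) && retro_child == 2L && !is.null(out)) {
      out$retro_orphan <- TRUE  # surviving copy is the retrocopy, node gone
    }
    return(out)
  }
  if (is.null(right)) return(left)
  list(type = event, age = age, children = list(left, right),
       retro_child = retro_child)
}

#' Simulate a gene family along a dated species tree
#'
#' Runs a Gillespie process with duplication, loss, and retrotransposition
#' along the species tree and assembles the surviving lineages into a dated,
#' rooted gene tree. Internal nodes are labeled and annotated as S, D, or R
#' events in the returned truth record; tips carry their species, intron
#' count (0 after any retrotransposition on their path), and chromosome.
#'
#' @param species Output of [species_tree_spec()] (or a `phylo`, which is
#'   validated first).
#' @param params A [family_sim_params()] list.
#' @return A list of class `gene_family`:
#'   \describe{
#'     \item{tree}{dated `phylo` (MY branch lengths, node labels), or `NULL`}
#'     \item{subst_tree}{same topology with substitution-scale lengths}
#'     \item{tip_species, tip_introns, tip_chromosome}{named tip annotations}
#'     \item{events}{named node-label vector in {"S","D","R"}}
#'     \item{branch_category}{named by branch ID; R only for retrocopy
#'       branches, the original copy's branch stays D}
#'     \item{extinct}{TRUE when no lineage survived}
#'     \item{n_tips}{number of surviving genes}
#'   }
#'   Families with fewer than 2 surviving genes have `tree = NULL` (an
#'   explicit empty result, not an error).
#' @export
simulate_gene_family <- function(species, params = family_sim_params()) {
  if (inherits(species, "phylo")) species <- species_tree_spec(species)
  set.seed(derive_seed(params$seed, "gene_family"))
  sp_tree <- species$tree
  n_tip <- length(sp_tree$tip.label)
  env <- new.env(parent = emptyenv())
  env$p <- params
  env$total_rate <- params$dup_rate + params$loss_rate + params$retro_rate
  env$sp_ages <- node_ages(sp_tree)
  env$sp_children <- children_of(sp_tree)
  env$sp_labels <- node_label(sp_tree, seq_len(n_tip + sp_tree$Nnode))
  root <- n_tip + 1L
  state0 <- list(introns = params$intron_count0,
                 chrom = params$start_chromosome)
  rec <- sim_species_node(env, root, state0)
  fam <- assemble_gene_tree(rec, params)
  fam$species_root_age <- env$sp_ages[root]
  fam
}

# Flatten the nested record into a phylo plus annotations.
assemble_gene_tree <- function(rec, params) {
  empty <- list(tree = NULL, subst_tree = NULL, tip_species = character(),
                tip_introns = integer(), tip_chromosome = character(),
                events = character(), branch_category = character(),
                extinct = is.null(rec), n_tips = 0L)
  class(empty) <- "gene_family"
  if (is.null(rec) || rec$type == "tip") {
    if (!is.null(rec)) empty$n_tips <- 1L
    return(empty)
  }
  tips <- list(); nodes <- list(); edges <- list()
  sp_count <- new.env(parent = emptyenv())
  walk <- function(r) {
    if (r$type == "tip") {
      cnt <- (if (is.null(sp_count[[r$species]])) 0L
              else sp_count[[r$species]]) + 1L
      sp_count[[r$species]] <- cnt
      id <- length(tips) + 1L
      tips[[id]] <<- list(label = sprintf("%s_g%d", r$species, cnt),
                          species = r$species, introns = r$state$introns,
                          chrom = r$state$chrom)
      return(list(kind = "tip", id = id, age = r$age))
    }
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(event = r$type, age = r$age,
                         retro_child = r$retro_child)
    kids <- lapply(r$children, walk)
    for (j in seq_along(kids)) {
      is_retro <- !is.na(nodes[[id]]$retro_child) &&
        nodes[[id]]$retro_child == j
      edges[[length(edges) + 1L]] <<- list(
        parent = id, child = kids[[j]], length = r$age - kids[[j]]$age,
        retro = is_retro)
    }
    list(kind = "node", id = id, age = r$age)
  }
  root_ref <- walk(rec)
  n_tip <- length(tips)
  n_node <- length(nodes)
  if (n_tip < 2L) { empty$n_tips <- n_tip; return(empty) }
  edge_mat <- matrix(0L, length(edges), 2L)
  edge_len <- numeric(length(edges))
  retro_edge <- logical(length(edges))
  idx <- function(ref) if (ref$kind == "tip") ref$id else n_tip + ref$id
  for (k in seq_along(edges)) {
    e <- edges[[k]]
    edge_mat[k, ] <- c(n_tip + e$parent, idx(e$child))
    edge_len[k] <- e$length
    retro_edge[k] <- e$retro
  }
  tree <- structure(list(edge = edge_mat, edge.length = edge_len,
                         Nnode = n_node,
                         tip.label = vapply(tips, `[[`, "", "label"),
                         node.label = paste0("N", seq_len(n_node))),
                    class = "phylo")
  events <- vapply(nodes, `[[`, "", "event")
  names(events) <- tree$node.label
  # categories are keyed by branch (child-node) ID, so compute them while
  # retro_edge is still aligned with the original edge order
  bid <- branch_ids(tree)
  parent_ev <- events[node_label(tree, tree$edge[, 1L])]
  category <- ifelse(parent_ev == "S", "S",
                     ifelse(parent_ev == "R" & retro_edge, "R", "D"))
  names(category) <- bid
  tree <- reorder(tree, "cladewise")
  set.seed(derive_seed(params$seed, "subst_rates"))
  rates <- params$subst_rate_mean *
    exp(stats::rnorm(nrow(tree$edge), 0, params$subst_rate_sdlog) -
          params$subst_rate_sdlog^2 / 2)
  subst_tree <- tree
  subst_tree$edge.length <- tree$edge.length * rates
  out <- list(
    tree = tree, subst_tree = subst_tree,
    tip_species = stats::setNames(vapply(tips, `[[`, "", "species"),
                                  tree$tip.label),
    tip_introns = stats::setNames(vapply(tips, `[[`, 0L, "introns"),
                                  tree$tip.label),
    tip_chromosome = stats::setNames(vapply(tips, `[[`, "", "chrom"),
                                     tree$tip.label),
    events = events, branch_category = category,
    extinct = FALSE, n_tips = n_tip)
  class(out) <- "gene_family"
  out
}
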
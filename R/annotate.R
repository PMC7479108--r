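# Branch annotation: ancestral intron and chromosome states by marginal
# posterior inference under continuous-time Markov models with fixed (small)
# rates, and classification of branches into S, D, and R. A retrotransposed
# copy is recognized as a duplication-descended branch whose intron state
# switches from intron-containing to intronless with posterior > 0.5.

#' Discrete-character model with fixed rates
#'
#' @param states Ordered state labels.
#' @param rate_matrix Square rate matrix (per MY; rows sum to 0). If NULL, a
#'   model is built from the convenience rates below.
#' @param loss_rate Intron loss rate (containing -> intronless), 1e-3.
#' @param gain_rate Intron gain rate (intronless -> containing), 1e-4.
#' @param translocation_rate Symmetric chromosome translocation rate, 1e-3.
#' @param kind "intron" (binary) or "chromosome" (A/X/Y symmetric).
#' @return A `discrete_char_model` list with `states`, `Q`, and the
#'   stationary distribution `pi`.
#' @export
discrete_char_model <- function(kind = c("intron", "chromosome"),
                                states = NULL, rate_matrix = NULL,
                                loss_rate = 1e-3, gain_rate = 1e-4,
                                translocation_rate = 1e-3) {
  kind <- match.arg(kind)
  if (is.null(rate_matrix)) {
    if (kind == "intron") {
      states <- c("intronless", "containing")
      Q <- matrix(c(-gain_rate, gain_rate,
                    loss_rate, -loss_rate), 2, 2, byrow = TRUE,
                  dimnames = list(states, states))
    } else {
      states <- c("A", "X", "Y")
      r <- translocation_rate
      Q <- matrix(r, 3, 3, dimnames = list(states, states))
      diag(Q) <- -2 * r
    }
  } else {
    Q <- rate_matrix
    states <- rownames(Q) %||% states
  }
  if (any(Q[row(Q) != col(Q)] < 0) || any(abs(rowSums(Q)) > 1e-12)) {
    stop("invalid rate matrix")
  }
  # stationary distribution: left null vector of Q
  ev <- eigen(t(Q))
  i0 <- which.min(abs(ev$values))
  pi <- Re(ev$vectors[, i0]); pi <- pi / sum(pi)
  structure(list(states = states, Q = Q,
                 pi = stats::setNames(pi, states), kind = kind),
            class = "discrete_char_model")
}

# Transition probability matrix exp(Qt) via eigendecomposition.
char_pmat <- function(model, t) {
  ev <- eigen(model$Q)
  P <- Re(ev$vectors %*% diag(exp(ev$values * t), nrow = length(ev$values))
          %*% solve(ev$vectors))
  P[P < 0] <- 0
  dimnames(P) <- list(model$states, model$states)
  P
}

#' Marginal ancestral-state posteriors at every node
#'
#' Felsenstein pruning (inside probabilities) combined with an outside pass
#' yields the exact marginal posterior of every tip and internal node under
#' the fixed-rate model with a stationary-prior (or uniform-prior) root.
#' Missing tip states are marginalized.
#'
#' @param tree Dated `phylo` (branch lengths in MY) with node labels.
#' @param tip_states Named character vector of tip states (NA = missing).
#' @param model A [discrete_char_model()].
#' @param root_prior "stationary" (default) or "uniform".
#' @return Matrix (tips + nodes) x states of marginal posteriors, rows
#'   named by tip/node label; attribute `loglik` holds the data
#'   log-likelihood.
#' @export
ancestral_binary <- function(tree, tip_states, model,
                             root_prior = c("stationary", "uniform")) {
  root_prior <- match.arg(root_prior)
  tree <- ensure_node_labels(tree)
  ns <- length(model$states)
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  blen <- pmax(tree$edge.length, 1e-9)  # zero durations get epsilon
  P <- lapply(seq_len(nrow(tree$edge)), function(k)
    char_pmat(model, blen[k]))
  down <- matrix(1, n_all, ns)  # inside (Felsenstein) partials
  for (i in seq_len(n_tip)) {
    s <- tip_states[[tree$tip.label[i]]]
    if (!is.na(s)) {
      if (!(s %in% model$states)) stop("unknown state: ", s)
      down[i, ] <- as.numeric(model$states == s)
    }
  }
  post_ord <- reorder(tree, "postorder")
  edge_of_child <- match(seq_len(n_all), tree$edge[, 2L])
  for (k in seq_len(nrow(post_ord$edge))) {
    p <- post_ord$edge[k, 1L]; ch <- post_ord$edge[k, 2L]
    ke <- which(tree$edge[, 2L] == ch)
    down[p, ] <- down[p, ] * as.numeric(P[[ke]] %*% down[ch, ])
  }
  prior <- if (root_prior == "stationary") model$pi else rep(1 / ns, ns)
  root <- n_tip + 1L
  lik <- sum(prior * down[root, ])
  # outside pass
  up <- matrix(1, n_all, ns)
  up[root, ] <- prior
  kids <- children_of(tree)
  pre_edges <- reorder(tree, "cladewise")$edge
  for (k in seq_len(nrow(pre_edges))) {
    p <- pre_edges[k, 1L]; ch <- pre_edges[k, 2L]
    ke <- which(tree$edge[, 2L] == ch)
    sibs <- setdiff(kids[[p]], ch)
    m <- up[p, ]
    for (s in sibs) {
      ks <- which(tree$edge[, 2L] == s)
      m <- m * as.numeric(P[[ks]] %*% down[s, ])
    }
    up[ch, ] <- as.numeric(t(P[[ke]]) %*% m)
  }
  post <- up * down
  post <- post / rowSums(post)
  rownames(post) <- node_label(tree, seq_len(n_all))
  colnames(post) <- model$states
  attr(post, "loglik") <- log(lik)
  post
}

#' Classify branches as S, D, or R with translocation flags
#'
#' A branch's category is its parent node's event (speciation S or
#' duplication D). A duplication-descended branch is relabeled R when the
#' maximum-a-posteriori intron state switches from intron-containing to
#' intronless across the branch with both endpoint posteriors > 0.5; the
#' sister (original) copy stays D. Translocation is flagged when the
#' maximum-posterior chromosome differs across the branch.
#'
#' @param tree Rooted node-labeled `phylo`.
#' @param events Named node-label vector in {"S","D"} (from
#'   [classify_species_overlap()] or simulation truth).
#' @param intron_post Posterior matrix from [ancestral_binary()] (intron
#'   model).
#' @param chrom_post Optional posterior matrix (chromosome model); NULL
#'   when chromosome data are missing (non-therian or unanchored species).
#' @return Data.frame with one row per branch: `branch`, `category`,
#'   `translocation`, `missing_chromosome`.
#' @export
classify_branches <- function(tree, events, intron_post,
                              chrom_post = NULL) {
  tree <- ensure_node_labels(tree)
  n_tip <- length(tree$tip.label)
  bid <- branch_ids(tree)
  parent_lab <- node_label(tree, tree$edge[, 1L])
  if (!all(parent_lab %in% names(events))) {
    stop("unclassified parent node(s)")
  }
  map_state <- function(post, lab) {
    colnames(post)[which.max(post[lab, ])]
  }
  category <- character(length(bid))
  transloc <- logical(length(bid))
  for (k in seq_along(bid)) {
    ev <- events[[parent_lab[k]]]
    if (ev == "S") {
      category[k] <- "S"
    } else {
      p_lab <- parent_lab[k]; c_lab <- bid[k]
      anc <- map_state(intron_post, p_lab)
      der <- map_state(intron_post, c_lab)
      is_retro <- anc == "containing" && der == "intronless" &&
        intron_post[p_lab, "containing"] > 0.5 &&
        intron_post[c_lab, "intronless"] > 0.5
      category[k] <- if (is_retro) "R" else "D"
    }
    if (!is.null(chrom_post)) {
      transloc[k] <- map_state(chrom_post, parent_lab[k]) !=
        map_state(chrom_post, bid[k])
    }
  }
  data.frame(branch = bid, category = category,
             translocation = transloc,
             missing_chromosome = is.null(chrom_post))
}
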
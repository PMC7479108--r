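# Shared fixture builders. Everything is generated in code; no data files.

# Small dated ultrametric tree with labeled nodes.
fixture_tree <- function(n = 8, root_age = 100, seed = 42) {
  exprevo:::ensure_node_labels(sim_species_tree(n, root_age, seed = seed))
}

# A tiny genes x samples truth matrix on the log2 scale, organ-structured.
fixture_truth <- function(n_genes = 40, seed = 1, organ_sd = 1.5) {
  set.seed(seed)
  base <- stats::rnorm(n_genes, 4, 1)
  truth <- matrix(base, n_genes, 6) +
    matrix(stats::rnorm(n_genes * 6, 0, organ_sd), n_genes, 6)
  rownames(truth) <- sprintf("g%03d", seq_len(n_genes))
  colnames(truth) <- organs()
  truth
}

# Deterministic 5-tip newick with a known duplication (species A appears in
# both root subtrees' sister positions).
fixture_dup_tree <- function() {
  ape::read.tree(text =
    "((A_1:10,B_1:10):20,((A_2:12,C_1:12):8,D_1:20):10);")
}

# Brute-force duplication-loss reconciliation oracle: explicit embedding of
# the gene tree into the species tree, counting losses by walking every
# gene-tree edge through the species-tree edges it crosses.
oracle_dl <- function(gtree, tip_species, sp_tree) {
  n_tip <- length(gtree$tip.label)
  under <- exprevo:::tips_under(gtree)
  sp_of <- function(v) {
    sp <- unique(tip_species[gtree$tip.label[under[[v]]]])
    if (length(sp) == 1) match(sp, sp_tree$tip.label) else
      ape::getMRCA(sp_tree, sp)
  }
  kids <- exprevo:::children_of(gtree)
  sp_parent <- exprevo:::parent_of(sp_tree)
  depth_to_root <- function(m) {
    d <- 0
    while (sp_parent[m] != 0) { d <- d + 1; m <- sp_parent[m] }
    d
  }
  dups <- 0; losses <- 0
  for (v in (n_tip + 1L):(n_tip + gtree$Nnode)) {
    mv <- sp_of(v)
    ch <- kids[[v]]
    is_dup <- any(vapply(ch, function(c) sp_of(c) == mv, TRUE))
    if (is_dup) dups <- dups + 1
    for (c in ch) {
      mc <- sp_of(c)
      # number of species-tree edges strictly between mc and mv
      steps <- depth_to_root(mc) - depth_to_root(mv)
      losses <- losses + if (is_dup) steps else max(steps - 1, 0)
    }
  }
  list(dups = dups, losses = losses)
}

# Brute-force OU covariance oracle: numerical path integration.
# V_ij = sigma2 * int_0^{t_ij} exp(-alpha (ti - s)) exp(-alpha (tj - s)) ds
# with sigma2 = 1 (white noise accumulated along the shared root path and
# decayed toward both tips), evaluated without the package's vectorized
# construction. method = "trapezoid" is fast; "quadrature" uses adaptive
# integration to near machine precision.
oracle_ou_cov <- function(tree, alpha, n_steps = 20000,
                          method = c("trapezoid", "quadrature")) {
  method <- match.arg(method)
  n_tip <- length(tree$tip.label)
  depth <- exprevo:::node_depths(tree)
  mr <- ape::mrca(tree)
  V <- matrix(0, n_tip, n_tip)
  for (i in seq_len(n_tip)) {
    for (j in seq_len(n_tip)) {
      t_ij <- depth[mr[i, j]]
      if (t_ij <= 0) { V[i, j] <- 0; next }
      f <- function(s) exp(-alpha * (depth[i] - s)) *
        exp(-alpha * (depth[j] - s))
      V[i, j] <- if (method == "quadrature") {
        stats::integrate(f, 0, t_ij, rel.tol = 1e-13,
                         abs.tol = 1e-14)$value
      } else {
        s <- seq(0, t_ij, length.out = n_steps)
        sum((f(s)[-1] + f(s)[-n_steps]) / 2) * (t_ij / (n_steps - 1))
      }
    }
  }
  V
}

# Exhaustive-sum likelihood oracle for discrete ancestral states: sums over
# all internal-state assignments using transition matrices.
oracle_discrete_post <- function(tree, tip_states, model,
                                 root_prior = "stationary") {
  tree <- exprevo:::ensure_node_labels(tree)
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  states <- model$states
  ns <- length(states)
  P <- lapply(seq_len(nrow(tree$edge)), function(k)
    exprevo:::char_pmat(model, max(tree$edge.length[k], 1e-9)))
  prior <- if (root_prior == "stationary") model$pi else rep(1 / ns, ns)
  combos <- expand.grid(rep(list(seq_len(ns)), n_node))
  lik_of <- function(assign_int) {
    state_of <- function(v) {
      if (v <= n_tip) {
        s <- tip_states[[tree$tip.label[v]]]
        if (is.na(s)) return(NA_integer_)
        return(match(s, states))
      }
      assign_int[v - n_tip]
    }
    l <- prior[assign_int[1]]
    for (k in seq_len(nrow(tree$edge))) {
      p <- state_of(tree$edge[k, 1]); c <- state_of(tree$edge[k, 2])
      if (is.na(c)) next  # missing tip: sum over states = 1
      l <- l * P[[k]][p, c]
    }
    l
  }
  liks <- apply(combos, 1, function(row) lik_of(as.integer(row)))
  post <- matrix(0, n_node, ns,
                 dimnames = list(tree$node.label, states))
  for (v in seq_len(n_node)) {
    for (s in seq_len(ns)) {
      post[v, s] <- sum(liks[combos[[v]] == s])
    }
  }
  sweep(post, 1, rowSums(post), "/")
}

# Independent Brunner-Munzel oracle via placements (empirical CDFs).
oracle_brunner_munzel <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  F1 <- function(t) (sum(x < t) + 0.5 * sum(x == t)) / n1
  F2 <- function(t) (sum(y < t) + 0.5 * sum(y == t)) / n2
  p1 <- vapply(x, F2, 0)  # placements of x in y
  p2 <- vapply(y, F1, 0)
  p_hat <- mean(p2)
  s1 <- stats::var(p1); s2 <- stats::var(p2)
  se <- sqrt(s1 / n1 + s2 / n2)
  stat <- (p_hat - 0.5) / se
  df <- (s1 / n1 + s2 / n2)^2 /
    ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
  list(statistic = stat, df = df,
       p_value = 2 * stats::pt(-abs(stat), df), relative_effect = p_hat)
}
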
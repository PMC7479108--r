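# Study-design helpers for the calibration/power experiments on 64-tip
# trees. Conditions (also documented in the methods vignette):
# - dated coalescent trees, root age 300 MY;
# - OU: alpha = 0.02/MY (half-life ~35 MY), sigma2 = 0.5, theta0 = 4;
# - a planted shift moves every organ's optimum by 4 stationary SDs
#   (random signs), placed on a long branch (length >= the median internal
#   branch) that is deep enough for the new regime to be expressed
#   (>= 2 phylogenetic half-lives from branch start to the tips) and is
#   not a root child (a root-child shift is not identifiable from its
#   sister's under the intercept parameterization);
# - two "metrics" = two amalgamation replicates: the same OU realization
#   observed with independent N(0, 0.2) organ-mean measurement noise;
# - a family's detection = the cross-metric consensus shift set.

power_study_tree <- function(seed, n_tips = 64, root_age = 300) {
  exprevo:::ensure_node_labels(sim_species_tree(n_tips, root_age,
                                                seed = seed))
}

power_study_params <- function(seed) {
  expr_sim_params(alpha = 0.02, sigma2 = 0.5, theta0 = 4,
                  shift_prob = c(S = 0, D = 0, R = 0), seed = seed)
}

# Choose the planted branch; returns its branch ID.
pick_long_branch <- function(tree, seed, min_elapsed = 70) {
  set.seed(seed)
  g <- exprevo:::ou_tree_geometry(tree)
  n_tip <- g$n_tip
  nd <- colSums(g$ind)
  internal <- nd >= 2
  is_root_child <- tree$edge[, 1] == n_tip + 1L
  long <- tree$edge.length >= stats::median(tree$edge.length[internal])
  base <- nd >= 4 & nd <= n_tip / 2 & !is_root_child
  ok <- base & long & (g$T_depth - g$start) >= min_elapsed
  if (!any(ok)) ok <- base & (g$T_depth - g$start) >= min_elapsed
  if (!any(ok)) ok <- base & (g$T_depth - g$start) >= min_elapsed / 2
  if (!any(ok)) ok <- base
  cand <- which(ok)
  branch_ids(tree)[cand[sample.int(length(cand), 1)]]
}

# One calibration/power family: simulate, detect on both metric
# replicates, return the consensus and the target.
consensus_run <- function(seed, plant = TRUE, noise_sd = 0.2) {
  tree <- power_study_tree(seed)
  params <- power_study_params(seed + 7919)
  target <- NA_character_
  planted <- NULL
  if (plant) {
    target <- pick_long_branch(tree, seed)
    gam_sd <- sqrt(params$sigma2 / (2 * params$alpha))
    set.seed(seed + 15017)
    planted <- stats::setNames(
      list(4 * gam_sd * sample(c(-1, 1), 6, replace = TRUE)), target)
  }
  ex <- simulate_ou_expression(tree, params, planted = planted)
  set.seed(seed + 31013)
  observe <- function() ex$traits +
    matrix(stats::rnorm(length(ex$traits), 0, noise_sd),
           nrow(ex$traits))
  m1 <- detect_shifts(tree, observe())
  m2 <- detect_shifts(tree, observe())
  cons <- consensus_shifts(m1, m2)
  list(target = target, consensus = cons$branches,
       m1 = m1$shift_branches, m2 = m2$shift_branches)
}

# Generator-truth shift records for the propensity recovery study: many
# small families under a planted propensity matrix; records built from the
# generator's own regime optima.
propensity_truth_records <- function(seed, propensity, n_min = 300,
                                     max_fams = 400) {
  rows <- list(); n_switch <- 0L; i <- 0L
  spec <- species_tree_spec(sim_species_tree(12, 300,
                                             seed = exprevo:::derive_seed(seed,
                                                                "sp")))
  while (n_switch < n_min && i < max_fams) {
    i <- i + 1L
    # cycle the root's primary organ so every ancestral PEO is populated
    theta0 <- rep(4, 6)
    theta0[1L + (i %% 6L)] <- 6
    p <- expr_sim_params(theta0 = theta0,
                         shift_prob = c(S = 0.25, D = 0.25, R = 0.25),
                         shift_size_sd = 3, propensity = propensity,
                         seed = exprevo:::derive_seed(seed, "fam", i))
    fam <- simulate_gene_family(spec, family_sim_params(
      dup_rate = 1e-3, loss_rate = 5e-4,
      seed = exprevo:::derive_seed(seed, "tree", i)))
    if (fam$extinct || fam$n_tips < 4) next
    ex <- simulate_ou_expression(fam, p)
    if (nrow(ex$shifts) == 0) next
    sh <- ex$shifts
    sh$peo_switch <- sh$peo_anc != sh$peo_der
    rows[[length(rows) + 1L]] <- sh
    n_switch <- n_switch + sum(sh$peo_switch)
  }
  do.call(rbind, rows)
}
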
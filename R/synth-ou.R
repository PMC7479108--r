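# Multivariate OU trait simulation on dated gene trees. Six organ traits
# evolve independently given a shared regime history: planted shifts move
# the optima of all six organs jointly, with the boosted organ drawn from a
# propensity row indexed by the current primary-expressed organ (PEO).

#' Parameters for OU expression simulation
#'
#' @param alpha Per-organ selection strength (1/MY); length 1 or 6.
#' @param sigma2 Per-organ diffusion (trait^2/MY); length 1 or 6.
#' @param theta0 Per-organ root optimum (log2 expression); length 1 or 6.
#' @param shift_prob Named per-branch shift probabilities for the S, D and R
#'   branch categories. Defaults are the per-branch shift frequencies
#'   measured on the full vertebrate data (2.2%, 9.0%, 37.3%).
#' @param shift_size_sd Log2-expression scale of a planted shift.
#' @param propensity 6x6 row-stochastic matrix; row = current PEO, column =
#'   probability that organ is the target of the next shift.
#' @param seed Integer seed.
#' @return An `expr_sim_params` list.
#' @export
expr_sim_params <- function(alpha = 0.02, sigma2 = 0.5, theta0 = 4,
                            shift_prob = c(S = 0.022, D = 0.090, R = 0.373),
                            shift_size_sd = 2,
                            propensity = matrix(1 / 6, 6, 6), seed = 1) {
  alpha <- rep_len(alpha, 6L)
  sigma2 <- rep_len(sigma2, 6L)
  theta0 <- rep_len(theta0, 6L)
  stopifnot(all(alpha > 0), all(sigma2 > 0),
            all(shift_prob >= 0), all(shift_prob <= 1),
            all(c("S", "D", "R") %in% names(shift_prob)),
            is.matrix(propensity), all(dim(propensity) == 6),
            all(propensity >= 0),
            all(abs(rowSums(propensity) - 1) <= 1e-12),
            shift_size_sd >= 0)
  structure(list(alpha = alpha, sigma2 = sigma2, theta0 = theta0,
                 shift_prob = shift_prob, shift_size_sd = shift_size_sd,
                 propensity = propensity, seed = as.integer(seed)),
            class = "expr_sim_params")
}

#' One exact OU transition step
#'
#' Draws the trait value after time `dt` under an OU process with optimum
#' `theta`, selection `alpha` and diffusion `sigma2`, starting from `x0`.
#' Vectorized over all arguments.
#'
#' @param x0 Starting value(s).
#' @param theta Optimum.
#' @param alpha Selection strength (> 0; the Brownian limit is obtained by
#'   passing a very small value).
#' @param sigma2 Diffusion.
#' @param dt Elapsed time.
#' @return Random draw(s) from the exact transition distribution.
#' @export
ou_step <- function(x0, theta, alpha, sigma2, dt) {
  m <- ou_trans_mean(x0, theta, alpha, dt)
  v <- ou_trans_var(alpha, sigma2, dt)
  stats::rnorm(length(m), m, sqrt(pmax(v, 0)))
}

# Closed-form transition moments (numerically stable near alpha = 0).
ou_trans_mean <- function(x0, theta, alpha, dt) {
  theta + (x0 - theta) * exp(-alpha * dt)
}
ou_trans_var <- function(alpha, sigma2, dt) {
  ifelse(alpha * dt < 1e-8, sigma2 * dt,
         sigma2 / (2 * alpha) * (1 - exp(-2 * alpha * dt)))
}

#' Simulate organ expression evolution with regime shifts
#'
#' Traits start at the root optimum `theta0` and evolve branch-wise under
#' the exact OU transition distribution. On each branch, a shift is planted
#' at the branch start with the category-specific probability; a shift
#' jitters all six optima and boosts one target organ (drawn from the
#' propensity row of the current PEO) above the current maximum, so the
#' derived regime's PEO is the target.
#'
#' @param family A `gene_family` (from [simulate_gene_family()]), or a dated
#'   ultrametric `phylo` (all branches then treated as category "S").
#' @param params An [expr_sim_params()] list.
#' @param planted Optional named list, branch ID -> length-6 delta vector:
#'   these shifts are applied deterministically at the branch start
#'   (bypassing `shift_prob` and the propensity draw) so studies can place
#'   shifts of known size on chosen branches.
#' @return List with `traits` (tips x 6 matrix, organs as columns), `shifts`
#'   (data.frame: branch, category, peo_anc, peo_der, plus the 6 deltas),
#'   `node_theta` (regime optima at every node), and `params`.
#' @export
simulate_ou_expression <- function(family, params = expr_sim_params(),
                                   planted = NULL) {
  if (inherits(family, "phylo")) {
    tree <- ensure_node_labels(family)
    category <- stats::setNames(rep("S", nrow(tree$edge)), branch_ids(tree))
  } else {
    tree <- family$tree
    category <- family$branch_category
  }
  if (is.null(tree)) stop("family has no tree (extinct or single-gene)")
  if (!is_ultrametric_tol(tree, 1e-6)) {
    stop("tree must be ultrametric (dated in MY)")
  }
  set.seed(derive_seed(params$seed, "ou_expression"))
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  x <- matrix(NA_real_, n_all, 6L)
  th <- matrix(NA_real_, n_all, 6L)
  root <- n_tip + 1L
  x[root, ] <- params$theta0
  th[root, ] <- params$theta0
  ord <- reorder(tree, "cladewise")
  bid <- node_label(tree, ord$edge[, 2L])
  shifts <- list()
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1L]; ch <- ord$edge[k, 2L]
    theta <- th[p, ]
    cat_k <- category[[bid[k]]]
    if (!is.null(planted) && bid[k] %in% names(planted)) {
      delta <- planted[[bid[k]]]
      peo_anc <- which.max(unlog_expr(theta))
      theta <- theta + delta
      shifts[[length(shifts) + 1L]] <- data.frame(
        branch = bid[k], category = cat_k,
        peo_anc = organs()[peo_anc],
        peo_der = organs()[which.max(unlog_expr(theta))],
        t(stats::setNames(delta, paste0("delta_", organs()))))
    } else if (stats::runif(1) < params$shift_prob[[cat_k]]) {
      peo_anc <- which.max(unlog_expr(theta))
      target <- sample.int(6L, 1L, prob = params$propensity[peo_anc, ])
      delta <- stats::rnorm(6L, 0, params$shift_size_sd / 5)
      delta[target] <- (max(theta) - theta[target]) +
        abs(stats::rnorm(1, params$shift_size_sd, params$shift_size_sd / 4))
      theta <- theta + delta
      shifts[[length(shifts) + 1L]] <- data.frame(
        branch = bid[k], category = cat_k,
        peo_anc = organs()[peo_anc],
        peo_der = organs()[which.max(unlog_expr(theta))],
        t(stats::setNames(delta, paste0("delta_", organs()))))
    }
    th[ch, ] <- theta
    x[ch, ] <- ou_step(x[p, ], theta, params$alpha, params$sigma2,
                       ord$edge.length[k])
  }
  traits <- x[seq_len(n_tip), , drop = FALSE]
  dimnames(traits) <- list(tree$tip.label, organs())
  dimnames(th) <- list(node_label(tree, seq_len(n_all)), organs())
  shifts <- if (length(shifts)) do.call(rbind, shifts) else
    data.frame(branch = character(), category = character(),
               peo_anc = character(), peo_der = character())
  list(traits = traits, shifts = shifts, node_theta = th, params = params)
}

#' Undo the log2(N + 1) expression transform
#'
#' @param x Log2-scale values.
#' @return `2^x - 1`, clamped at 0.
#' @export
unlog_expr <- function(x) {
  pmax(2^x - 1, 0)
}
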
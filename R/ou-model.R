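# Multi-optima OU model machinery: the expectation design and covariance on
# a dated ultrametric tree, per-organ null fitting (alpha, sigma2, theta0 by
# profiled ML on an alpha grid), tree skimming, and the shift-count cap.

#' Maximum number of regime shifts for a tree of N tips
#'
#' Applies the cap `max[min(N/2, 100), sqrt(N)]`, floored to an integer.
#'
#' @param N Tip count (>= 4).
#' @return Integer cap.
#' @export
max_shifts <- function(N) {
  stopifnot(N >= 4)
  as.integer(floor(max(min(N / 2, 100), sqrt(N))))
}

# Precompute the tip geometry of a dated ultrametric tree: root-to-MRCA
# times (t), patristic distances (d), total depth T, and per-branch shift
# start times / descendant indicators for the design matrix.
ou_tree_geometry <- function(tree) {
  n_tip <- length(tree$tip.label)
  depth <- node_depths(tree)
  T_depth <- max(depth[seq_len(n_tip)])
  mr <- ape::mrca(tree, full = FALSE)
  t_mat <- matrix(depth[mr], n_tip, n_tip)
  d_mat <- outer(depth[seq_len(n_tip)], depth[seq_len(n_tip)], "+") -
    2 * t_mat
  under <- tips_under(tree)
  ind <- matrix(0, n_tip, nrow(tree$edge))
  for (k in seq_len(nrow(tree$edge))) {
    ind[under[[tree$edge[k, 2L]]], k] <- 1
  }
  colnames(ind) <- branch_ids(tree)
  list(n_tip = n_tip, T_depth = T_depth, t_mat = t_mat, d_mat = d_mat,
       ind = ind, start = depth[tree$edge[, 1L]])
}

#' OU expectation design and covariance
#'
#' For a dated ultrametric tree and selection strength `alpha`, returns the
#' tip covariance (sigma^2 factored out) and the expectation design: an
#' intercept column plus, per candidate branch, a column that is
#' `1 - exp(-alpha * (T - t_start))` for tips descending from the branch
#' (shift placed at the branch start) and 0 elsewhere.
#'
#' Covariance (fixed-root form, the default):
#' `V_ij = exp(-alpha d_ij) (1 - exp(-2 alpha t_ij)) / (2 alpha)` with
#' `t_ij` the root-to-MRCA time and `d_ij` the patristic distance; the
#' stationary-root form drops the `(1 - exp(-2 alpha t_ij))` factor.
#'
#' @param tree Dated ultrametric `phylo` with node labels.
#' @param alpha Selection strength (> 0).
#' @param root_mode "fixed" (default) or "stationary".
#' @param geometry Optional precomputed [ou_tree_geometry()] (internal).
#' @return List with `X` (tips x (1 + branches); intercept first, branch
#'   columns named by branch ID) and `V` (tips x tips).
#' @export
ou_design <- function(tree, alpha, root_mode = c("fixed", "stationary"),
                      geometry = NULL) {
  root_mode <- match.arg(root_mode)
  if (alpha <= 0) stop("alpha must be positive")
  g <- if (is.null(geometry)) ou_tree_geometry(tree) else geometry
  V <- exp(-alpha * g$d_mat) / (2 * alpha)
  if (root_mode == "fixed") V <- V * (1 - exp(-2 * alpha * g$t_mat))
  fac <- 1 - exp(-alpha * (g$T_depth - g$start))
  X <- cbind(1, sweep(g$ind, 2, fac, "*"))
  colnames(X) <- c("(intercept)", colnames(g$ind))
  rownames(X) <- rownames(V) <- colnames(V) <- tree$tip.label
  list(X = X, V = V)
}

# GLS under covariance chol factor R (V = t(R) %*% R): whitens X and y,
# fits OLS, returns beta, ML sigma2, and the Gaussian log-likelihood.
gls_chol <- function(R, X, y) {
  Xw <- backsolve(R, X, transpose = TRUE)
  yw <- backsolve(R, y, transpose = TRUE)
  qx <- qr(Xw)
  if (qx$rank < ncol(Xw)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    Xw <- Xw[, keep, drop = FALSE]
    qx <- qr(Xw)
    beta_full <- rep(0, ncol(X))
    beta_full[keep] <- qr.coef(qx, yw)
    beta <- beta_full
    dropped <- setdiff(seq_len(ncol(X)), keep)
  } else {
    beta <- qr.coef(qx, yw)
    dropped <- integer()
  }
  res <- yw - Xw %*% qr.coef(qx, yw)
  n <- length(y)
  sigma2 <- max(sum(res^2) / n, 1e-12)
  loglik <- -0.5 * (n * log(2 * pi * sigma2) +
                      2 * sum(log(diag(R))) + n)
  list(beta = as.numeric(beta), sigma2 = sigma2, loglik = loglik,
       dropped = dropped)
}

# Default alpha grid: 32 log-spaced points spanning phylogenetic half-lives
# from 0.1% to 1000% of the tree depth.
alpha_grid_default <- function(T_depth, n = 32) {
  h <- T_depth * exp(seq(log(0.001), log(10), length.out = n))
  rev(log(2) / h)  # increasing alpha
}

# Lean single-(alpha, support, organ) evaluator. `Xsub` holds the raw
# indicator columns of the support (N x s, possibly 0 columns); the design
# is [1, Xsub * fac(alpha)] whitened by the Cholesky factor of V(alpha).
ou_eval <- function(geometry, Xsub, sup_start, y, a, root_mode) {
  V <- exp(-a * geometry$d_mat) / (2 * a)
  if (root_mode == "fixed") V <- V * (1 - exp(-2 * a * geometry$t_mat))
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(list(loglik = -Inf))
  n <- geometry$n_tip
  if (ncol(Xsub)) {
    fac <- 1 - exp(-a * (geometry$T_depth - sup_start))
    X <- cbind(1, Xsub * rep(fac, each = n))
  } else {
    X <- matrix(1, n, 1)
  }
  Xw <- backsolve(R, X, transpose = TRUE)
  yw <- backsolve(R, y, transpose = TRUE)
  fit <- .lm.fit(Xw, yw)
  beta <- numeric(ncol(X))
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  beta[fit$pivot] <- cf  # .lm.fit reports coefficients in pivoted order
  sigma2 <- max(sum(fit$residuals^2) / n, 1e-12)
  loglik <- -0.5 * (n * log(2 * pi * sigma2) + 2 * sum(log(diag(R))) + n)
  list(loglik = loglik, beta = beta, sigma2 = sigma2, alpha = a)
}

# Profiled ML for one organ: optimize alpha on the grid then refine by
# golden search. `Xsub`/`sup_start` define the shift columns (may be empty).
fit_organ_ou <- function(geometry, Xsub, sup_start, y, alpha_grid,
                         root_mode, refine_tol = 0.05) {
  eval_a <- function(la) ou_eval(geometry, Xsub, sup_start, y, exp(la),
                                 root_mode)
  las <- log(alpha_grid)
  lls <- vapply(las, function(la) eval_a(la)$loglik, 0)
  b <- which.max(lls)
  lo <- las[max(b - 1, 1)]; hi <- las[min(b + 1, length(las))]
  opt <- if (hi > lo) {
    stats::optimize(function(la) eval_a(la)$loglik, c(lo, hi),
                    maximum = TRUE, tol = refine_tol)
  } else {
    list(maximum = las[b], objective = lls[b])
  }
  best_la <- if (opt$objective >= lls[b]) opt$maximum else las[b]
  fit <- eval_a(best_la)
  fit$at_boundary <- b == 1L || b == length(las)
  fit
}

#' Fit the no-shift OU model per organ
#'
#' Per organ, maximizes the Gaussian likelihood with mean `theta0` and
#' covariance `sigma2 * V(alpha)` over (alpha, sigma2, theta0): alpha on a
#' log grid refined by golden search, sigma2 and theta0 profiled in closed
#' form by GLS.
#'
#' @param tree Dated ultrametric `phylo` (>= 4 tips).
#' @param traits Tips x 6 matrix (rows matching `tree$tip.label`).
#' @param root_mode "fixed" or "stationary" root handling.
#' @param alpha_grid Optional alpha grid (1/MY).
#' @return Data.frame with one row per organ: alpha, sigma2, theta0, gamma
#'   (= sigma2 / (2 alpha)), loglik, at_boundary (alpha hit the grid edge,
#'   white-noise-like or BM-like), plus attribute `loglik_total`.
#' @export
fit_null <- function(tree, traits, root_mode = "fixed", alpha_grid = NULL) {
  stopifnot(length(tree$tip.label) >= 4)
  traits <- traits[tree$tip.label, , drop = FALSE]
  g <- ou_tree_geometry(tree)
  if (is.null(alpha_grid)) alpha_grid <- alpha_grid_default(g$T_depth)
  no_cols <- matrix(0, g$n_tip, 0)
  out <- lapply(seq_len(ncol(traits)), function(k) {
    y <- traits[, k]
    if (stats::sd(y) < 1e-12) {
      return(data.frame(organ = colnames(traits)[k], alpha = alpha_grid[1],
                        sigma2 = 1e-12, theta0 = mean(y),
                        gamma = 1e-12 / (2 * alpha_grid[1]),
                        loglik = NA_real_, at_boundary = TRUE))
    }
    f <- fit_organ_ou(g, no_cols, numeric(0), y, alpha_grid, root_mode)
    data.frame(organ = colnames(traits)[k], alpha = f$alpha,
               sigma2 = f$sigma2, theta0 = f$beta[1],
               gamma = f$sigma2 / (2 * f$alpha), loglik = f$loglik,
               at_boundary = f$at_boundary)
  })
  out <- do.call(rbind, out)
  attr(out, "loglik_total") <- sum(out$loglik)
  out
}

#' Collapse near-identical clades of a trait-annotated tree
#'
#' Maximal clades in which the minimum pairwise Pearson correlation of the
#' tips' 6-organ expression vectors exceeds `threshold` are collapsed to a
#' single tip. The new tip keeps the first tip's label, stays at the
#' original depth (the tree remains ultrametric), and carries the clade's
#' Brownian-motion phylogenetic mean (GLS root estimate) per organ.
#' Zero-variance vectors get correlation 1 when equal within 1e-12 and 0
#' otherwise.
#'
#' @param tree Dated ultrametric `phylo` (>= 4 tips) with node labels.
#' @param traits Tips x 6 matrix.
#' @param threshold Minimum pairwise correlation for collapsing.
#' @return List with `tree` (skimmed), `traits` (skimmed tips x 6),
#'   `collapse_map` (new tip -> original clade tips).
#' @export
skim_tree <- function(tree, traits, threshold = 0.99) {
  stopifnot(length(tree$tip.label) >= 4)
  tree <- ensure_node_labels(tree)
  traits <- traits[tree$tip.label, , drop = FALSE]
  n_tip <- length(tree$tip.label)
  C <- robust_row_cor(traits)
  under <- tips_under(tree)
  collapsible <- rep(FALSE, n_tip + tree$Nnode)
  for (v in (n_tip + 1L):(n_tip + tree$Nnode)) {
    tt <- under[[v]]
    collapsible[v] <- min(C[tt, tt]) > threshold
  }
  parent <- parent_of(tree)
  maximal <- which(collapsible &
                     !(parent != 0 & collapsible[pmax(parent, 1)]))
  root <- n_tip + 1L
  if (length(maximal) == 1 && maximal == root) {
    # whole tree collapses to one tip
    mu <- bm_phylo_mean(tree, traits)
    return(list(tree = NULL,
                traits = matrix(mu, 1, ncol(traits),
                                dimnames = list(tree$tip.label[1],
                                                colnames(traits))),
                collapse_map = stats::setNames(list(tree$tip.label),
                                               tree$tip.label[1])))
  }
  collapse_map <- list()
  new_traits <- traits
  drop_tips <- character()
  ages <- node_ages(tree)
  for (v in maximal) {
    tt <- under[[v]]
    rep_tip <- tree$tip.label[tt[1]]
    clade <- ape::extract.clade(tree, v)
    mu <- bm_phylo_mean(clade, traits[clade$tip.label, , drop = FALSE])
    collapse_map[[rep_tip]] <- tree$tip.label[tt]
    new_traits[rep_tip, ] <- mu
    drop_tips <- c(drop_tips, tree$tip.label[tt[-1]])
  }
  if (length(drop_tips)) {
    skimmed <- ape::drop.tip(tree, drop_tips, collapse.singles = TRUE)
  } else {
    skimmed <- tree
  }
  list(tree = skimmed,
       traits = new_traits[skimmed$tip.label, , drop = FALSE],
       collapse_map = collapse_map)
}

# Pairwise Pearson correlation between rows, with the zero-variance
# convention: equal (within 1e-12) constant vectors correlate 1, else 0.
robust_row_cor <- function(traits) {
  n <- nrow(traits)
  sds <- apply(traits, 1, stats::sd)
  C <- matrix(0, n, n)
  ok <- sds > 1e-12
  if (sum(ok) >= 2) {
    C[ok, ok] <- suppressWarnings(stats::cor(t(traits[ok, , drop = FALSE])))
  }
  for (i in which(!ok)) {
    for (j in seq_len(n)) {
      eq <- max(abs(traits[i, ] - traits[j, ])) <= 1e-12
      C[i, j] <- C[j, i] <- if (eq) 1 else 0
    }
  }
  diag(C) <- 1
  C
}

# Brownian-motion GLS root estimate for a clade (per trait column).
bm_phylo_mean <- function(clade, x) {
  if (nrow(x) == 1) return(x[1, ])
  vcvm <- ape::vcv(clade)
  Ci <- solve(vcvm)
  w <- colSums(Ci) / sum(Ci)
  as.numeric(w %*% x[rownames(vcvm), , drop = FALSE])
}
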
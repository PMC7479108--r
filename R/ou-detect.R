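# Regime-shift detection: group-Lasso over candidate branches (grouping the
# six organs' optimum changes so shifts are joint across organs) along a
# geometric lambda path, followed by unpenalized GLS refits with per-organ
# alpha re-optimization, AICc model selection, and a backward elimination
# pass.

#' Configuration for the shift search
#'
#' @param corr_threshold Clade-collapse correlation threshold for skimming.
#' @param n_lambda Length of the lasso path.
#' @param lambda_min_ratio Smallest lambda as a fraction of lambda_max.
#' @param cap_override Optional manual cap on the number of shifts
#'   (otherwise `max[min(N/2, 100), sqrt(N)]`).
#' @param root_mode OU root handling, "fixed" (default) or "stationary".
#' @param max_supports Cap on distinct supports refitted along the path.
#' @param criterion Model-selection score. "fwer_aicc" (default): AICc over
#'   the 6N trait observations plus, per shift, the family-wise critical
#'   value `qchisq(1 - fwer_alpha / p, 6)` of the best-of-p-branches
#'   search, which keeps the per-tree false-shift probability near
#'   `fwer_alpha` at any tree size. "aicc": plain AICc over 6N
#'   observations (markedly more liberal: the per-shift penalty of ~12
#'   sits below the expected best-of-p chi-square(6) maximum).
#' @param fwer_alpha Per-tree false-shift level for "fwer_aicc".
#' @param seed Integer seed (the search itself is deterministic; the seed
#'   only feeds derived bookkeeping).
#' @return A `shift_search_config` list.
#' @export
shift_search_config <- function(corr_threshold = 0.99, n_lambda = 50,
                                lambda_min_ratio = 0.001,
                                cap_override = NULL, root_mode = "fixed",
                                max_supports = 40,
                                criterion = c("fwer_aicc", "aicc"),
                                fwer_alpha = 0.05,
                                seed = 1) {
  structure(list(corr_threshold = corr_threshold, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio,
                 cap_override = cap_override, root_mode = root_mode,
                 max_supports = max_supports,
                 criterion = match.arg(criterion),
                 fwer_alpha = fwer_alpha, seed = as.integer(seed)),
            class = "shift_search_config")
}

# Model-selection score. Base: AICc with 3 parameters per organ (alpha,
# sigma2, theta0) plus 6 per shift over n_obs = 6N trait observations.
# Under "fwer_aicc", each shift's 2k-part of the penalty is replaced by
# the critical value of the best-of-p-branches search (qchisq(1 -
# alpha/p, 6)), so accepting a spurious shift requires beating the null
# maximum at family-wise level alpha.
ou_aicc <- function(loglik, n_shifts, n_organs, n_obs,
                    criterion = "fwer_aicc", n_candidates = 1,
                    fwer_alpha = 0.05) {
  k <- 3 * n_organs + n_organs * n_shifts
  if (n_obs - k - 1 <= 0) return(Inf)
  base <- -2 * loglik + 2 * k + 2 * k * (k + 1) / (n_obs - k - 1)
  if (criterion == "fwer_aicc" && n_shifts > 0) {
    crit <- stats::qchisq(1 - fwer_alpha / max(n_candidates, 1), n_organs)
    base <- base + n_shifts * (crit - 2 * n_organs)
  }
  base
}

# Refit one support: per organ, GLS with intercept + the support's branch
# columns, alpha re-optimized by golden search warm-started at the null
# estimate. Returns total loglik, per-organ parameters and the delta matrix
# (shift x organ).
refit_support <- function(geometry, traits, support, warm_alpha, root_mode,
                          branch_cols) {
  n_organs <- ncol(traits)
  Xsub <- geometry$ind[, support, drop = FALSE]
  sup_start <- geometry$start[support]
  fits <- vector("list", n_organs)
  for (k in seq_len(n_organs)) {
    y <- traits[, k]
    la0 <- log(warm_alpha[k])
    opt <- stats::optimize(function(la)
      ou_eval(geometry, Xsub, sup_start, y, exp(la), root_mode)$loglik,
      la0 + c(-1.5, 1.5), maximum = TRUE, tol = 0.1)
    warm_ll <- ou_eval(geometry, Xsub, sup_start, y, exp(la0), root_mode)
    fits[[k]] <- if (warm_ll$loglik >= opt$objective) warm_ll else
      ou_eval(geometry, Xsub, sup_start, y, exp(opt$maximum), root_mode)
  }
  loglik <- sum(vapply(fits, `[[`, 0, "loglik"))
  deltas <- t(vapply(fits, function(f) {
    b <- f$beta[-1]
    if (length(b) < length(support)) b <- c(b, rep(0, length(support) -
                                                     length(b)))
    b
  }, numeric(length(support))))
  if (length(support) == 0) deltas <- matrix(0, n_organs, 0)
  list(loglik = loglik, fits = fits, deltas = deltas)
}

#' Detect expression regime shifts on a dated gene tree
#'
#' Pipeline: (1) skim the tree (collapse near-identical clades); (2) fit the
#' per-organ no-shift OU model to obtain alpha and sigma2; (3) whiten each
#' organ's data with the Cholesky inverse of its covariance and run a
#' group-Lasso over candidate branch columns (the six organs' optimum
#' changes of a branch form one group); (4) refit every distinct support of
#' size at most the cap by unpenalized GLS with alpha re-optimized per
#' organ, scoring with AICc (3 parameters per organ plus 6 per shift, n =
#' 6N); (5) select the minimum-AICc support (ties: smaller support, then
#' lexicographic branch IDs); (6) backward pass: drop any shift whose
#' removal lowers AICc, to a fixpoint.
#'
#' @param tree Dated ultrametric `phylo` (node-labeled or labeled here).
#' @param traits Tips x 6 trait matrix (log expression), rows = tip labels.
#' @param config A [shift_search_config()].
#' @param skim Collapse near-identical clades first (default TRUE).
#' @return A `regime_model` list: `shift_branches` (ordered branch IDs),
#'   `organ_params` (per-organ alpha/sigma2/theta0/gamma), `deltas`
#'   (shift x organ optimum changes), `loglik`, `aicc`, `n_params`,
#'   `null_aicc`, `tree` (skimmed tree used), `full_tree`, `collapse_map`,
#'   `cap`, and `path_info`.
#' @export
detect_shifts <- function(tree, traits, config = shift_search_config(),
                          skim = TRUE) {
  tree <- ensure_node_labels(tree)
  traits <- as.matrix(traits)[tree$tip.label, , drop = FALSE]
  full_tree <- tree
  collapse_map <- list()
  if (skim && length(tree$tip.label) >= 4) {
    sk <- skim_tree(tree, traits, config$corr_threshold)
    collapse_map <- sk$collapse_map
    tree <- sk$tree
    traits <- sk$traits
  }
  n_organs <- ncol(traits)
  if (is.null(tree) || length(tree$tip.label) < 4 ||
      max(apply(traits, 2, stats::sd)) < 1e-12) {
    return(empty_regime_model(tree, full_tree, collapse_map, traits))
  }
  g <- ou_tree_geometry(tree)
  N <- g$n_tip
  cap <- if (!is.null(config$cap_override)) config$cap_override else
    max_shifts(N)
  grid <- alpha_grid_default(g$T_depth)
  null_fit <- fit_null(tree, traits, root_mode = config$root_mode,
                       alpha_grid = grid)
  # --- whitened, intercept-projected, unit-normalized group design
  branch_cols <- colnames(g$ind)
  Gn <- length(branch_cols)
  Xb <- matrix(0, N, Gn * n_organs)
  ys <- numeric(N * n_organs)
  keep_group <- rep(TRUE, Gn)
  for (k in seq_len(n_organs)) {
    a <- null_fit$alpha[k]
    V <- exp(-a * g$d_mat) / (2 * a)
    if (config$root_mode == "fixed") V <- V * (1 - exp(-2 * a * g$t_mat))
    R <- chol(V)
    s <- sqrt(null_fit$sigma2[k])
    yw <- backsolve(R, traits[, k], transpose = TRUE) / s
    fac <- 1 - exp(-a * (g$T_depth - g$start))
    Xw <- backsolve(R, sweep(g$ind, 2, fac, "*"), transpose = TRUE) / s
    iw <- backsolve(R, rep(1, N), transpose = TRUE) / s
    # project out the (whitened) intercept
    proj <- function(z) z - iw * sum(iw * z) / sum(iw * iw)
    yw <- proj(yw)
    Xw <- apply(Xw, 2, proj)
    ys[(k - 1) * N + seq_len(N)] <- yw
    Xb[, (seq_len(Gn) - 1) * n_organs + k] <- Xw
  }
  # unit-normalize columns; drop groups with a degenerate column
  norms <- sqrt(colSums(Xb^2))
  zero_col <- norms < 1e-10
  # column j of group g sits at (g-1)*n_organs + k
  col_group <- rep(seq_len(Gn), each = n_organs)
  keep_group <- !tapply(zero_col, col_group, any)
  norms[zero_col] <- 1
  Xb <- sweep(Xb, 2, norms, "/")
  # lambda path
  cg <- vapply(seq_len(Gn), function(gi) {
    cols <- (gi - 1) * n_organs + seq_len(n_organs)
    sqrt(sum(vapply(seq_len(n_organs), function(k) {
      sum(Xb[, cols[k]] * ys[(k - 1) * N + seq_len(N)])^2
    }, 0)))
  }, 0)
  cg[!keep_group] <- 0
  lambda_max <- max(cg)
  if (lambda_max <= 0) {
    return(finalize_model(g, tree, full_tree, collapse_map, traits,
                          list(), branch_cols, grid, config, null_fit,
                          cap, list()))
  }
  lambdas <- exp(seq(log(lambda_max * 0.999),
                     log(lambda_max * config$lambda_min_ratio),
                     length.out = config$n_lambda))
  Xb_masked <- Xb
  Xb_masked[, !keep_group[col_group]] <- 0
  betas <- group_lasso_path_cpp(Xb_masked, ys, n_organs, lambdas,
                                max_iter = 200L, tol = 1e-7)
  # distinct supports along the path
  supports <- list()
  seen <- character()
  for (li in seq_len(ncol(betas))) {
    gnorm <- vapply(seq_len(Gn), function(gi) {
      cols <- (gi - 1) * n_organs + seq_len(n_organs)
      sqrt(sum(betas[cols, li]^2))
    }, 0)
    sup <- which(gnorm > 1e-9)
    if (length(sup) > cap) {
      sup <- sup[order(-gnorm[sup])][seq_len(cap)]
      sup <- sort(sup)
    }
    key <- paste(sup, collapse = ",")
    if (!(key %in% seen) && length(sup) > 0) {
      seen <- c(seen, key)
      supports[[length(supports) + 1L]] <- sup
    }
    if (length(supports) >= config$max_supports) break
  }
  finalize_model(g, tree, full_tree, collapse_map, traits, supports,
                 branch_cols, grid, config, null_fit, cap,
                 list(lambda_max = lambda_max, n_supports =
                        length(supports)))
}

# Score the candidate supports, pick min AICc, run the backward pass, and
# assemble the regime model.
finalize_model <- function(g, tree, full_tree, collapse_map, traits,
                           supports, branch_cols, grid, config, null_fit,
                           cap, path_info) {
  n_organs <- ncol(traits)
  n_obs <- n_organs * g$n_tip
  n_cand <- length(branch_cols)
  cache <- new.env(parent = emptyenv())
  warm_alpha <- null_fit$alpha
  score <- function(sup) {
    key <- paste0("s:", paste(sup, collapse = ","))
    if (!is.null(cache[[key]])) return(cache[[key]])
    rf <- refit_support(g, traits, sup, warm_alpha, config$root_mode,
                        branch_cols)
    rf$aicc <- ou_aicc(rf$loglik, length(sup), n_organs, n_obs,
                       criterion = config$criterion %||% "fwer_aicc",
                       n_candidates = n_cand,
                       fwer_alpha = config$fwer_alpha %||% 0.05)
    rf$support <- sup
    cache[[key]] <- rf
    rf
  }
  better <- function(a, b) {
    a$aicc < b$aicc - 1e-9 ||
      (abs(a$aicc - b$aicc) <= 1e-9 &&
         (length(a$support) < length(b$support) ||
            (length(a$support) == length(b$support) &&
               paste(branch_cols[a$support], collapse = ",") <
               paste(branch_cols[b$support], collapse = ","))))
  }
  # backward elimination of one support to its AICc fixpoint; supports
  # larger than 12 shifts are first trimmed to their 12 largest-effect
  # groups (one refit) to bound the search
  prune <- function(sc) {
    if (length(sc$support) > 12) {
      gnorm <- sqrt(colSums(sc$deltas^2))
      keep <- order(-gnorm)[seq_len(12)]
      sc <- score(sort(sc$support[keep]))
    }
    repeat {
      if (length(sc$support) == 0) return(sc)
      improved <- FALSE
      for (drop_i in seq_along(sc$support)) {
        cand <- score(sc$support[-drop_i])
        if (cand$aicc < sc$aicc - 1e-9) {
          sc <- cand
          improved <- TRUE
          break
        }
      }
      if (!improved) return(sc)
    }
  }
  null_sc <- score(integer())
  scored <- lapply(supports, score)
  # prune the most promising candidate supports, then select overall
  ord <- order(vapply(scored, `[[`, 0, "aicc"))
  best <- null_sc
  for (i in utils::head(ord, 4)) {
    sc <- prune(scored[[i]])
    if (better(sc, best)) best <- sc
  }
  best <- prune(best)
  sup <- best$support
  organ_params <- data.frame(
    organ = colnames(traits),
    alpha = vapply(best$fits, `[[`, 0, "alpha"),
    sigma2 = vapply(best$fits, `[[`, 0, "sigma2"),
    theta0 = vapply(best$fits, function(f) f$beta[1], 0))
  organ_params$gamma <- organ_params$sigma2 / (2 * organ_params$alpha)
  deltas <- matrix(0, length(sup), n_organs,
                   dimnames = list(branch_cols[sup], colnames(traits)))
  if (length(sup)) deltas[] <- t(best$deltas)
  structure(list(
    shift_branches = branch_cols[sup],
    organ_params = organ_params,
    deltas = deltas,
    loglik = best$loglik,
    aicc = best$aicc,
    n_params = 3 * n_organs + n_organs * length(sup),
    null_loglik = null_sc$loglik,
    null_aicc = null_sc$aicc,
    tree = tree, full_tree = full_tree, collapse_map = collapse_map,
    traits = traits, cap = cap, root_mode = config$root_mode,
    null_fit = null_fit, path_info = path_info),
    class = "regime_model")
}

empty_regime_model <- function(tree, full_tree, collapse_map, traits) {
  n_organs <- ncol(traits)
  organ_params <- data.frame(
    organ = colnames(traits), alpha = NA_real_, sigma2 = NA_real_,
    theta0 = colMeans(traits))
  organ_params$gamma <- NA_real_
  structure(list(
    shift_branches = character(),
    organ_params = organ_params,
    deltas = matrix(0, 0, n_organs, dimnames = list(NULL,
                                                    colnames(traits))),
    loglik = NA_real_, aicc = NA_real_,
    n_params = 3 * n_organs,
    null_loglik = NA_real_, null_aicc = NA_real_,
    tree = tree, full_tree = full_tree, collapse_map = collapse_map,
    traits = traits, cap = NA_integer_, root_mode = "fixed",
    null_fit = NULL, path_info = list()),
    class = "regime_model")
}

#' Regime optima at every node of a fitted model
#'
#' The optimum of a regime is `theta0` plus the sum of shift deltas on the
#' node's root path.
#'
#' @param model A `regime_model` from [detect_shifts()].
#' @return Nodes x organs matrix (rows named by node/tip label) of optima on
#'   the model's (skimmed) tree.
#' @export
regime_optima <- function(model) {
  tree <- model$tree
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  theta <- matrix(rep(model$organ_params$theta0, each = n_all), n_all,
                  ncol(model$deltas))
  ord <- reorder(tree, "cladewise")
  bid <- node_label(tree, ord$edge[, 2L])
  cum <- matrix(0, n_all, ncol(model$deltas))
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1L]; ch <- ord$edge[k, 2L]
    cum[ch, ] <- cum[p, ]
    if (bid[k] %in% rownames(model$deltas)) {
      cum[ch, ] <- cum[ch, ] + model$deltas[bid[k], ]
    }
  }
  out <- theta + cum
  rownames(out) <- node_label(tree, seq_len(n_all))
  colnames(out) <- colnames(model$deltas)
  out
}

#' Consensus of two regime models
#'
#' Retains the shifts detected with both expression metrics: the
#' intersection of the two models' shift branch sets.
#'
#' @param model_a,model_b `regime_model`s fitted on the same full tree.
#' @return List with `branches` (consistent shift branch IDs), and `venn`
#'   (counts a_only / common / b_only).
#' @export
consensus_shifts <- function(model_a, model_b) {
  ta <- model_a$full_tree; tb <- model_b$full_tree
  if (!setequal(ta$tip.label, tb$tip.label) ||
      ape::dist.topo(ape::unroot(ta), ape::unroot(tb)) != 0) {
    stop("models were fitted on different trees")
  }
  a <- model_a$shift_branches; b <- model_b$shift_branches
  common <- sort(intersect(a, b))
  list(branches = common,
       venn = c(a_only = length(setdiff(a, b)), common = length(common),
                b_only = length(setdiff(b, a))))
}
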
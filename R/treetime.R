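# Reconciliation-assisted rooting and dating of gene trees: species-overlap
# classification of nodes, duplication-loss rooting scores (with midpoint
# and minimal-ancestor-deviation candidates), speciation-derived age
# constraints, and a weighted least-squares dating step with a stepwise
# constraint-relaxation ladder.

#' Rooting configuration
#'
#' @param dup_score Cost of a duplication event.
#' @param loss_score Cost of a loss event.
#' @return A `rooting_config` list.
#' @export
rooting_config <- function(dup_score = 1.5, loss_score = 1.0) {
  stopifnot(dup_score > 0, loss_score > 0)
  structure(list(dup_score = dup_score, loss_score = loss_score),
            class = "rooting_config")
}

#' Classify gene-tree nodes by species overlap
#'
#' A node is a duplication (D) when the species sets of its two child
#' subtrees intersect, otherwise a speciation (S). Every node is also mapped
#' to the species-tree MRCA of its species set.
#'
#' @param tree Rooted binary `phylo` gene tree with node labels.
#' @param tip_species Named character vector, tip label -> species.
#' @param species_tree Dated species `phylo` (needed for the MRCA mapping;
#'   optional).
#' @return List with `events` (named by node label, "S"/"D"),
#'   `species_node` (named by node label, species-tree node label or NA) and
#'   `species_age` (mapped node age in MY, NA without a species tree).
#' @export
classify_species_overlap <- function(tree, tip_species, species_tree = NULL) {
  tree <- ensure_node_labels(tree)
  n_tip <- length(tree$tip.label)
  kids <- children_of(tree)
  if (any(vapply(kids[(n_tip + 1L):(n_tip + tree$Nnode)], length, 0L) != 2)) {
    stop("gene tree must be binary")
  }
  under <- tips_under(tree)
  spsets <- lapply(under, function(i) unique(tip_species[tree$tip.label[i]]))
  events <- character(tree$Nnode)
  for (v in seq_len(tree$Nnode)) {
    ch <- kids[[n_tip + v]]
    a <- spsets[[ch[1]]]; b <- spsets[[ch[2]]]
    events[v] <- if (length(intersect(a, b))) "D" else "S"
  }
  names(events) <- tree$node.label
  sp_node <- rep(NA_character_, tree$Nnode)
  sp_age <- rep(NA_real_, tree$Nnode)
  if (!is.null(species_tree)) {
    species_tree <- ensure_node_labels(species_tree, prefix = "S")
    sp_ages <- node_ages(species_tree)
    for (v in seq_len(tree$Nnode)) {
      sp <- spsets[[n_tip + v]]
      if (!all(sp %in% species_tree$tip.label)) {
        stop("species missing from species tree: ",
             paste(setdiff(sp, species_tree$tip.label), collapse = ", "))
      }
      m <- if (length(sp) == 1) match(sp, species_tree$tip.label) else
        ape::getMRCA(species_tree, sp)
      sp_node[v] <- node_label(species_tree, m)
      sp_age[v] <- sp_ages[m]
    }
  }
  names(sp_node) <- names(sp_age) <- tree$node.label
  list(events = events, species_node = sp_node, species_age = sp_age)
}

# Duplication-loss reconciliation counts for a rooted gene tree against a
# species tree, by LCA mapping (losses from species-tree depth differences).
dl_counts <- function(tree, tip_species, species_tree) {
  n_tip <- length(tree$tip.label)
  sp_ntip <- length(species_tree$tip.label)
  sp_depth_edges <- integer(sp_ntip + species_tree$Nnode)
  sp_parent <- parent_of(species_tree)
  ord <- reorder(species_tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    sp_depth_edges[ord$edge[k, 2L]] <- sp_depth_edges[ord$edge[k, 1L]] + 1L
  }
  under <- tips_under(tree)
  map <- integer(n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) {
    map[i] <- match(tip_species[tree$tip.label[i]], species_tree$tip.label)
  }
  kids <- children_of(tree)
  dups <- 0L; losses <- 0L
  post <- unique(reorder(tree, "postorder")$edge[, 1L])
  sp_mrca <- ape::mrca(species_tree, full = TRUE)
  for (v in post) {
    ch <- kids[[v]]
    m1 <- map[ch[1]]; m2 <- map[ch[2]]
    mv <- sp_mrca[m1, m2]
    map[v] <- mv
    is_dup <- (mv == m1) || (mv == m2)
    if (is_dup) dups <- dups + 1L
    for (c in ch) {
      d <- sp_depth_edges[map[c]] - sp_depth_edges[mv]
      losses <- losses + (if (is_dup) d else max(d - 1L, 0L))
    }
  }
  list(dups = dups, losses = losses)
}

# Root an unrooted tree on edge k, splitting its length rho / (1 - rho)
# (rho = fraction on the side of edge endpoint 1).
root_at_edge <- function(utree, k, rho = 0.5) {
  n_tip <- length(utree$tip.label)
  v <- utree$edge[k, 2L]
  len <- utree$edge.length[k]
  side_tips <- utree$tip.label[tips_under(utree)[[v]]]
  if (length(side_tips) == n_tip) stop("invalid rooting edge")
  rooted <- ape::root(utree, outgroup = side_tips, resolve.root = TRUE)
  rooted <- ensure_node_labels(rooted)
  root <- length(rooted$tip.label) + 1L
  re <- which(rooted$edge[, 1L] == root)
  # identify which root child leads to the outgroup side
  under_r <- tips_under(rooted)
  for (e in re) {
    tl <- rooted$tip.label[under_r[[rooted$edge[e, 2L]]]]
    rooted$edge.length[e] <- if (setequal(tl, side_tips)) {
      len * (1 - rho)
    } else {
      len * rho
    }
  }
  rooted
}

# Canonical bipartition key of edge k in an unrooted tree.
edge_bipartition <- function(utree, k) {
  v <- utree$edge[k, 2L]
  side <- sort(utree$tip.label[tips_under(utree)[[v]]])
  other <- sort(setdiff(utree$tip.label, side))
  if (length(side) < length(other) ||
      (length(side) == length(other) && side[1] < other[1])) {
    paste(side, collapse = "|")
  } else {
    paste(other, collapse = "|")
  }
}

# Minimal ancestor deviation statistics for every edge of an unrooted tree.
# Returns per-edge optimal root position (rho) and the rms deviation score.
mad_scores <- function(utree) {
  n_tip <- length(utree$tip.label)
  dn <- ape::dist.nodes(utree)
  under <- tips_under(utree)
  tipset <- seq_len(n_tip)
  n_edge <- nrow(utree$edge)
  rho <- numeric(n_edge); score <- numeric(n_edge)
  for (k in seq_len(n_edge)) {
    i <- utree$edge[k, 1L]; j <- utree$edge[k, 2L]
    len <- utree$edge.length[k]
    side_j <- under[[j]]
    side_i <- setdiff(tipset, side_j)
    if (length(side_i) == 0 || length(side_j) == 0) {
      rho[k] <- 0.5; score[k] <- Inf; next
    }
    # optimal rho from cross pairs (least squares, clamped)
    dbi <- dn[side_i, i]; dcj <- dn[side_j, j]
    dbc <- outer(dbi, dcj, "+") + len
    A <- 2 / dbc
    Dbi <- matrix(dbi, length(side_i), length(side_j))
    x <- if (len > 0) {
      sum(A * (1 - A * Dbi)) / sum(A^2)
    } else 0
    x <- min(max(x, 0), len)
    rho[k] <- if (len > 0) x / len else 0.5
    # distances of every tip to the root point
    droot <- numeric(n_tip)
    droot[side_i] <- dn[side_i, i] + x
    droot[side_j] <- dn[side_j, j] + (len - x)
    dev2 <- 0; npair <- 0L
    for (b in seq_len(n_tip - 1L)) {
      for (cc in (b + 1L):n_tip) {
        dpair <- dn[b, cc]
        if (dpair <= 0) next
        danc <- (dpair + droot[b] - droot[cc]) / 2
        dev2 <- dev2 + (2 * danc / dpair - 1)^2
        npair <- npair + 1L
      }
    }
    score[k] <- sqrt(dev2 / npair)
  }
  list(rho = rho, score = score)
}

#' Root a gene tree with reconciliation, midpoint, and MAD candidates
#'
#' Scores every branch of the unrooted tree as a rooting candidate by its
#' duplication-loss reconciliation cost (`dup_score * D + loss_score * L`),
#' and also identifies the midpoint and minimal-ancestor-deviation (MAD)
#' candidates. The final root is the MAD branch if it attains the minimal
#' DL score, else the midpoint branch if it does, else the DL-minimal branch
#' topologically nearest the MAD branch (ties: lexicographically smallest
#' bipartition).
#'
#' @param tree `phylo`, rooted or unrooted (it is unrooted first).
#' @param species_tree Species `phylo`.
#' @param tip_species Named tip -> species map.
#' @param config A [rooting_config()].
#' @return List with `tree` (rooted, node-labeled), `candidates` (data.frame
#'   of per-branch scores and flags), and `rule` (which candidate was used).
#' @export
root_tree <- function(tree, species_tree, tip_species,
                      config = rooting_config()) {
  stopifnot(length(tree$tip.label) >= 3)
  utree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  utree$node.label <- NULL
  n_edge <- nrow(utree$edge)
  dl <- matrix(0L, n_edge, 2L)
  for (k in seq_len(n_edge)) {
    rt <- root_at_edge(utree, k)
    cnt <- dl_counts(rt, tip_species, species_tree)
    dl[k, ] <- c(cnt$dups, cnt$losses)
  }
  score <- config$dup_score * dl[, 1] + config$loss_score * dl[, 2]
  bip <- vapply(seq_len(n_edge), function(k) edge_bipartition(utree, k), "")
  # midpoint candidate
  mp <- phangorn::midpoint(utree)
  mp_bip <- root_bipartition(mp)
  # MAD candidate
  mad <- mad_scores(utree)
  mad_k <- which.min(mad$score)
  dl_min <- score <= min(score) + 1e-9
  cand <- data.frame(
    edge = seq_len(n_edge), bipartition = bip,
    dups = dl[, 1], losses = dl[, 2], dl_score = score,
    is_dl_min = dl_min,
    is_midpoint = bip == mp_bip,
    is_mad = seq_len(n_edge) == mad_k,
    mad_score = mad$score, mad_rho = mad$rho)
  if (dl_min[mad_k]) {
    pick <- mad_k; rule <- "mad_in_dlmin"
  } else if (any(dl_min & cand$is_midpoint)) {
    pick <- which(dl_min & cand$is_midpoint)[1]; rule <- "midpoint_in_dlmin"
  } else {
    topo <- edge_topo_dist(utree, mad_k)
    cands <- which(dl_min)
    cands <- cands[order(topo[cands], bip[cands])]
    pick <- cands[1]; rule <- "dlmin_nearest_mad"
  }
  rho <- if (pick == mad_k) mad$rho[pick] else 0.5
  rooted <- root_at_edge(utree, pick, rho = rho)
  list(tree = rooted, candidates = cand, rule = rule,
       root_edge = pick)
}

# Bipartition key of the root edge of a rooted tree.
root_bipartition <- function(rooted) {
  root <- length(rooted$tip.label) + 1L
  ch <- children_of(rooted)[[root]]
  under <- tips_under(rooted)
  side <- sort(rooted$tip.label[under[[ch[1]]]])
  other <- sort(rooted$tip.label[under[[ch[2]]]])
  if (length(side) < length(other) ||
      (length(side) == length(other) && side[1] < other[1])) {
    paste(side, collapse = "|")
  } else {
    paste(other, collapse = "|")
  }
}

# Topological distance (in edges) from each edge to edge k.
edge_topo_dist <- function(utree, k) {
  ut1 <- utree
  ut1$edge.length <- rep(1, nrow(utree$edge))
  dn <- ape::dist.nodes(ut1)
  a <- utree$edge[k, 1L]; b <- utree$edge[k, 2L]
  vapply(seq_len(nrow(utree$edge)), function(e) {
    min(dn[utree$edge[e, 1L], a], dn[utree$edge[e, 1L], b],
        dn[utree$edge[e, 2L], a], dn[utree$edge[e, 2L], b])
  }, 0)
}

#' Build age constraints from a classified gene tree
#'
#' Speciation nodes are fixed to their mapped species-tree ages. Duplication
#' nodes are bounded below by the maximum fixed age among their nearest
#' descendant speciation nodes (0 when none) and above by the fixed age of
#' the nearest ancestral speciation node (`root_upper_default` when none).
#'
#' @param tree Rooted, node-labeled gene `phylo`.
#' @param classification Output of [classify_species_overlap()].
#' @param root_upper_default Upper age bound (MY) used when a duplication
#'   node has no ancestral speciation node (default 1105).
#' @return A `time_constraints` list: `fixed` (named ages), `bounded`
#'   (data.frame node/lower/upper), and `infeasible` (bounds with
#'   lower >= upper, flagged for relaxation).
#' @export
build_constraints <- function(tree, classification,
                              root_upper_default = 1105) {
  tree <- ensure_node_labels(tree)
  n_tip <- length(tree$tip.label)
  ev <- classification$events[tree$node.label]
  fixed <- classification$species_age[tree$node.label][ev == "S"]
  parent <- parent_of(tree)
  kids <- children_of(tree)
  # nearest descendant S ages (max over paths), per internal node
  lower_of <- function(v) {
    ch <- kids[[v]]
    vals <- vapply(ch, function(c) {
      if (c <= n_tip) return(0)
      lab <- node_label(tree, c)
      if (ev[[lab]] == "S") return(classification$species_age[[lab]])
      lower_of(c)
    }, 0)
    max(vals)
  }
  upper_of <- function(v) {
    p <- parent[v]
    while (p != 0) {
      lab <- node_label(tree, p)
      if (ev[[lab]] == "S") return(classification$species_age[[lab]])
      p <- parent[p]
    }
    root_upper_default
  }
  bounded <- data.frame(node = character(), lower = numeric(),
                        upper = numeric())
  for (lab in names(ev)[ev == "D"]) {
    v <- node_index(tree, lab)
    bounded <- rbind(bounded, data.frame(node = lab, lower = lower_of(v),
                                         upper = upper_of(v)))
  }
  infeasible <- bounded[bounded$lower >= bounded$upper, , drop = FALSE]
  sp_ages <- classification$species_age
  species_root_age <- if (any(!is.na(sp_ages))) max(sp_ages, na.rm = TRUE)
    else root_upper_default
  structure(list(fixed = fixed, bounded = bounded, infeasible = infeasible,
                 root_upper_default = root_upper_default,
                 species_root_age = species_root_age),
            class = "time_constraints")
}

#' Date a gene tree under age constraints
#'
#' Estimates node ages by minimizing a weighted least-squares lack-of-clock
#' objective, `sum_b (l_b - r t_b)^2 / max(l_b, eps)`, over free
#' (duplication) node ages and the clock rate(s), with speciation ages
#' pinned and duplication ages kept inside their bounds. With more than one
#' rate category, branches are grouped by their fitted rate and per-category
#' rates are shrunk toward the global rate. Infeasible constraint sets are
#' relaxed stepwise: duplication bounds are widened by 10% of the root's
#' upper bound per step (up to `max_relax` steps), then dropped.
#'
#' @param tree Rooted node-labeled `phylo` with substitution-scale branch
#'   lengths.
#' @param constraints A [build_constraints()] result.
#' @param rate_categories Number of rate categories (1 = strict clock).
#' @param eps Weight floor for short branches.
#' @param max_relax Maximum widening steps before bounds are dropped.
#' @return List with `tree` (branch lengths in MY), `ages` (named by node
#'   label, tips at 0), `rates`, `objective`, and `relaxation` (log of
#'   ladder steps, empty when the original bounds were feasible).
#' @export
date_tree <- function(tree, constraints, rate_categories = 1,
                      eps = 1e-6, max_relax = 5) {
  tree <- ensure_node_labels(tree)
  relax_log <- character()
  widen <- 0.1 * (constraints$species_root_age %||%
                    constraints$root_upper_default)
  bounded <- constraints$bounded
  for (step in 0:(max_relax + 1)) {
    if (step > 0 && step <= max_relax) {
      bounded$lower <- pmax(bounded$lower - widen, 0)
      bounded$upper <- bounded$upper + widen
      relax_log <- c(relax_log, sprintf("step %d: bounds widened by %g MY",
                                        step, widen))
    } else if (step > max_relax) {
      bounded <- bounded[0, , drop = FALSE]
      relax_log <- c(relax_log, "duplication bounds dropped")
    }
    fit <- try(date_tree_fit(tree, constraints$fixed, bounded,
                             constraints$root_upper_default,
                             rate_categories, eps), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      fit$relaxation <- relax_log
      return(fit)
    }
  }
  stop("dating infeasible after full relaxation; conflicting constraints: ",
       paste(utils::capture.output(print(constraints$infeasible)),
             collapse = "\n"))
}

date_tree_fit <- function(tree, fixed, bounded, root_upper,
                          rate_categories, eps) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  parent <- parent_of(tree)
  kids <- children_of(tree)
  age <- numeric(n_all)  # tips at 0
  lo <- rep(0, n_all); hi <- rep(root_upper, n_all)
  is_fixed <- rep(FALSE, n_all)
  for (lab in names(fixed)) {
    v <- node_index(tree, lab)
    age[v] <- fixed[[lab]]; is_fixed[v] <- TRUE
  }
  if (nrow(bounded)) {
    for (r in seq_len(nrow(bounded))) {
      v <- node_index(tree, bounded$node[r])
      lo[v] <- bounded$lower[r]; hi[v] <- bounded$upper[r]
      if (lo[v] > hi[v]) stop("bound infeasible at ", bounded$node[r])
    }
  }
  free <- setdiff((n_tip + 1L):n_all, which(is_fixed))
  post <- unique(reorder(tree, "postorder")$edge[, 1L])
  ell <- tree$edge.length
  w <- pmax(ell, eps)
  child <- tree$edge[, 2L]; par_e <- tree$edge[, 1L]
  # mean substitution depth from each node down to its tips
  sdepth <- numeric(n_all)
  ntips_under <- numeric(n_all)
  ntips_under[seq_len(n_tip)] <- 1
  for (v in post) {
    for (c in kids[[v]]) {
      e <- match(c, child)
      ntips_under[v] <- ntips_under[v] + ntips_under[c]
      sdepth[v] <- sdepth[v] + ntips_under[c] * (sdepth[c] + ell[e])
    }
    sdepth[v] <- sdepth[v] / ntips_under[v]
  }
  # clock anchored at fixed nodes (falls back to a mid-root guess)
  anchors <- which(is_fixed & age > 1e-9)
  r0 <- if (length(anchors)) {
    stats::median(sdepth[anchors] / age[anchors])
  } else {
    max(sdepth) / (0.5 * root_upper)
  }
  r0 <- max(r0, 1e-12)
  init_ages <- function(style) {
    a <- age
    pre <- rev(post)  # parents before children
    for (v in pre) {
      if (is_fixed[v]) next
      p <- parent[v]
      up_v <- min(hi[v], if (p != 0) a[p] else hi[v])
      # children not set yet in preorder; use constraint lower bound
      lo_v <- lo[v]
      a[v] <- if (style == "clock") {
        min(max(sdepth[v] / r0, lo_v), up_v)
      } else {
        (lo_v + up_v) / 2
      }
    }
    # repair child-above-parent violations bottom-up
    for (v in post) {
      cmax <- max(a[kids[[v]]])
      if (!is_fixed[v] && a[v] < cmax) a[v] <- min(cmax, hi[v])
      if (a[v] < cmax - 1e-9) stop("infeasible ages at ",
                                   node_label(tree, v))
    }
    a
  }
  run_from <- function(age) {
  durations <- function() age[par_e] - age[child]
  cat_assign <- rep(1L, length(ell))
  rates <- r0
  obj_val <- Inf
  for (iter in seq_len(400)) {
    t_b <- durations()
    # rate update (per category, shrunk toward the global rate)
    r_glob <- sum(ell * t_b / w) / max(sum(t_b^2 / w), 1e-300)
    r_glob <- max(r_glob, 1e-12)
    if (rate_categories > 1) {
      raw <- ell / pmax(t_b, 1e-9)
      qs <- stats::quantile(raw, probs = seq(0, 1, length.out =
                                               rate_categories + 1))
      cat_assign <- pmin(findInterval(raw, qs, rightmost.closed = TRUE),
                         rate_categories)
      rates <- vapply(seq_len(rate_categories), function(k) {
        sel <- cat_assign == k
        if (!any(sel)) return(r_glob)
        s_num <- sum(ell[sel] * t_b[sel] / w[sel])
        s_den <- sum(t_b[sel]^2 / w[sel])
        m <- mean(t_b^2 / w)
        max((s_num + r_glob * m) / (s_den + m), 1e-12)
      })
    } else {
      rates <- r_glob
    }
    r_b <- rates[cat_assign]
    # coordinate update of free ages (each is a clamped quadratic minimum)
    for (v in free) {
      ch <- kids[[v]]
      e_ch <- match(ch, child)
      e_par <- match(v, child)  # NA at root
      num <- sum(r_b[e_ch] * (ell[e_ch] + r_b[e_ch] * age[ch]) / w[e_ch])
      den <- sum(r_b[e_ch]^2 / w[e_ch])
      upper_v <- hi[v]; lower_v <- max(lo[v], max(age[ch]))
      if (!is.na(e_par)) {
        p <- par_e[e_par]
        num <- num + r_b[e_par] * (r_b[e_par] * age[p] - ell[e_par]) /
          w[e_par]
        den <- den + r_b[e_par]^2 / w[e_par]
        upper_v <- min(upper_v, age[p])
      }
      if (lower_v > upper_v + 1e-9) stop("infeasible interval at ",
                                         node_label(tree, v))
      a_star <- if (den > 0) num / den else (lower_v + upper_v) / 2
      age[v] <- min(max(a_star, lower_v), min(upper_v,
                                              max(lower_v, upper_v)))
    }
    t_b <- durations()
    new_obj <- sum((ell - rates[cat_assign] * t_b)^2 / w)
    if (is.finite(obj_val) && abs(obj_val - new_obj) <
        1e-12 * (1 + abs(obj_val))) {
      obj_val <- new_obj
      break
    }
    obj_val <- new_obj
  }
  list(age = age, rates = rates, categories = cat_assign,
       objective = obj_val)
  }
  fits <- lapply(c("clock", "midpoint"), function(st)
    run_from(init_ages(st)))
  best <- fits[[which.min(vapply(fits, `[[`, 0, "objective"))]]
  age <- best$age
  t_b <- age[par_e] - age[child]
  if (any(t_b < -1e-6)) stop("negative branch duration after dating")
  dated <- tree
  dated$edge.length <- pmax(t_b, 0)
  ages_out <- stats::setNames(age, node_label(tree, seq_len(n_all)))
  list(tree = dated, ages = ages_out, rates = best$rates,
       categories = best$categories, objective = best$objective,
       relaxation = character())
}
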
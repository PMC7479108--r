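# Per-shift expression metrics and the downstream statistics: organ
# specificity (tau), expression complementarity (TEC), primary-expressed
# organ (PEO) transition matrices with margin-preserving permutation nulls,
# global polarity with bootstrap, shift frequencies/rates, stationary
# variance comparisons, and omega (dN/dS) analyses.

#' Organ specificity index tau
#'
#' `tau = sum_i (1 - x_i / max) / (n - 1)`: 0 for uniform expression, 1 for
#' expression confined to a single organ.
#'
#' @param mu Unlogged, nonnegative expression vector (length 6).
#' @return Tau in [0, 1]; NA (with a warning) for an all-zero vector.
#' @export
tau <- function(mu) {
  if (any(mu < 0)) stop("tau expects unlogged, nonnegative values")
  m <- max(mu)
  if (m == 0) {
    warning("tau undefined for an all-zero vector")
    return(NA_real_)
  }
  sum(1 - mu / m) / (length(mu) - 1)
}

#' Expression complementarity TEC
#'
#' With p and q the sum-normalized expression vectors,
#' `TEC = 1 - sum_i min(p_i, q_i)`: 0 for identical patterns, 1 for
#' mutually exclusive organ usage. Symmetric in its arguments.
#'
#' @param mu_a,mu_b Unlogged, nonnegative expression vectors.
#' @return TEC in [0, 1]; NA (with a warning) when either vector sums to 0.
#' @export
tec <- function(mu_a, mu_b) {
  if (any(mu_a < 0) || any(mu_b < 0)) {
    stop("tec expects unlogged, nonnegative values")
  }
  if (sum(mu_a) == 0 || sum(mu_b) == 0) {
    warning("tec undefined for a zero-sum vector")
    return(NA_real_)
  }
  1 - sum(pmin(mu_a / sum(mu_a), mu_b / sum(mu_b)))
}

#' Primary-expressed organ
#'
#' @param mu Unlogged expression vector named by organ (or in [organs()]
#'   order).
#' @return The organ with the highest expression, or NA when the maximum is
#'   tied.
#' @export
peo <- function(mu) {
  nm <- names(mu) %||% organs()
  m <- max(mu)
  hits <- which(mu >= m - 1e-12)
  if (length(hits) != 1) return(NA_character_)
  nm[hits]
}

#' Statistics configuration
#'
#' @param n_perm Permutations for the transition-matrix null (default
#'   10000).
#' @param n_boot Bootstrap resamples for polarity (default 1000).
#' @param seed Integer seed.
#' @param undiff_band Half-width of the omega-ratio "undifferentiated" band
#'   on the raw ratio scale (default 0.05, i.e. within +/-5%).
#' @param alpha_level Nominal significance level.
#' @return A `stats_config` list.
#' @export
stats_config <- function(n_perm = 10000, n_boot = 1000, seed = 1,
                         undiff_band = 0.05, alpha_level = 0.05) {
  stopifnot(n_perm >= 1, n_boot >= 1)
  structure(list(n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
                 seed = as.integer(seed), undiff_band = undiff_band,
                 alpha_level = alpha_level), class = "stats_config")
}

#' Build shift records from fitted regime models
#'
#' For every consistent shift branch: the ancestral regime is the parent
#' branch's optima, the derived regime the shift branch's optima; tau, TEC,
#' and PEO are computed on unlogged optima (2^x - 1, clamped at 0),
#' delta-mu-max on the log scale; TEC compares the shift branch with its
#' sister. Records whose PEO does not switch are kept but flagged. Shifts on
#' a root-child branch with no parent regime are skipped and counted.
#'
#' @param model A `regime_model` (from [detect_shifts()]).
#' @param branches Shift branches to record (default: the model's own; pass
#'   a consensus set to restrict).
#' @param category Named branch -> {"S","D","R"} category vector (optional).
#' @param omega Optional named branch -> omega (dN/dS) vector; the sister's
#'   omega is looked up from the same vector.
#' @param family_id Identifier stored in the records.
#' @param bootstrap Optional named branch -> support vector.
#' @return Data.frame of shift records (one row per shift), with attribute
#'   `skipped_root` counting root shifts.
#' @export
build_shift_records <- function(model, branches = NULL, category = NULL,
                                omega = NULL, family_id = "fam",
                                bootstrap = NULL) {
  if (is.null(branches)) branches <- model$shift_branches
  if (length(branches) == 0) {
    out <- empty_shift_records()
    attr(out, "skipped_root") <- 0L
    return(out)
  }
  tree <- model$tree
  opt <- regime_optima(model)
  parent <- parent_of(tree)
  kids <- children_of(tree)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  rows <- list()
  skipped <- 0L
  for (b in branches) {
    v <- node_index(tree, b)
    p <- parent[v]
    if (p == root && length(kids[[root]]) < 2) { skipped <- skipped + 1L;
      next }
    p_lab <- node_label(tree, p)
    mu_der_log <- opt[b, ]
    mu_anc_log <- opt[p_lab, ]
    sis <- setdiff(kids[[p]], v)
    sis_lab <- if (length(sis) == 1) node_label(tree, sis) else NA
    mu_anc <- unlog_expr(mu_anc_log)
    mu_der <- unlog_expr(mu_der_log)
    tau_anc <- suppressWarnings(tau(mu_anc))
    tau_der <- suppressWarnings(tau(mu_der))
    tec_val <- if (!is.na(sis_lab)) {
      suppressWarnings(tec(mu_der, unlog_expr(opt[sis_lab, ])))
    } else NA_real_
    peo_anc <- peo(mu_anc); peo_der <- peo(mu_der)
    sister_shifted <- !is.na(sis_lab) &&
      sis_lab %in% model$shift_branches
    rows[[length(rows) + 1L]] <- data.frame(
      family_id = family_id, branch = b,
      category = if (!is.null(category)) category[[b]] else NA_character_,
      tau_anc = tau_anc, tau_der = tau_der, d_tau = tau_der - tau_anc,
      mu_max_anc = max(mu_anc_log), mu_max_der = max(mu_der_log),
      d_mu_max = max(mu_der_log) - max(mu_anc_log),
      tec = tec_val,
      peo_anc = ifelse(is.na(peo_anc), NA_character_, peo_anc),
      peo_der = ifelse(is.na(peo_der), NA_character_, peo_der),
      peo_switch = !is.na(peo_anc) && !is.na(peo_der) &&
        peo_anc != peo_der,
      peo_tied = is.na(peo_anc) || is.na(peo_der),
      sister = ifelse(is.na(sis_lab), NA_character_, sis_lab),
      sister_shifted = sister_shifted,
      omega_shift = if (!is.null(omega) && b %in% names(omega))
        omega[[b]] else NA_real_,
      omega_sister = if (!is.null(omega) && !is.na(sis_lab) &&
                         sis_lab %in% names(omega)) omega[[sis_lab]]
      else NA_real_,
      bootstrap_support = if (!is.null(bootstrap) &&
                              b %in% names(bootstrap)) bootstrap[[b]]
      else NA_real_)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_shift_records()
  attr(out, "skipped_root") <- skipped
  out
}

empty_shift_records <- function() {
  data.frame(family_id = character(), branch = character(),
             category = character(), tau_anc = numeric(),
             tau_der = numeric(), d_tau = numeric(),
             mu_max_anc = numeric(), mu_max_der = numeric(),
             d_mu_max = numeric(), tec = numeric(),
             peo_anc = character(), peo_der = character(),
             peo_switch = logical(), peo_tied = logical(),
             sister = character(), sister_shifted = logical(),
             omega_shift = numeric(), omega_sister = numeric(),
             bootstrap_support = numeric())
}

#' Per-category shift frequencies and per-MY rates
#'
#' @param records Shift-record data.frame (with `category`).
#' @param census Data.frame of all classified branches: `category` and
#'   `duration` (MY).
#' @return List with `table` (per category: branches, shifts, frequency,
#'   rate per MY) and `chisq` (shift/non-shift x category test).
#' @export
shift_rates <- function(records, census) {
  cats <- c("S", "D", "R")
  n_branch <- vapply(cats, function(cc) sum(census$category == cc), 0)
  n_shift <- vapply(cats, function(cc) sum(records$category == cc,
                                           na.rm = TRUE), 0)
  t_my <- vapply(cats, function(cc)
    sum(census$duration[census$category == cc]), 0)
  tab <- data.frame(category = cats, branches = n_branch,
                    shifts = n_shift,
                    frequency = ifelse(n_branch > 0, n_shift / n_branch,
                                       NA_real_),
                    rate_per_my = ifelse(t_my > 0, n_shift / t_my,
                                         ifelse(n_branch > 0, 0,
                                                NA_real_)))
  keep <- n_branch > 0
  chisq <- if (sum(keep) >= 2 && sum(n_shift) > 0) {
    m <- rbind(shift = n_shift[keep],
               no_shift = n_branch[keep] - n_shift[keep])
    suppressWarnings(stats::chisq.test(m))
  } else NULL
  list(table = tab, chisq = chisq)
}

#' Two-sided Brunner-Munzel test
#'
#' Rank-based two-sample test of the relative effect
#' `P(X < Y) + 0.5 P(X = Y)`, robust to unequal variances, with
#' Satterthwaite-style degrees of freedom.
#'
#' @param x,y Numeric samples.
#' @return List with `statistic`, `df`, `p_value`, `relative_effect`.
#' @export
brunner_munzel <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  r_all <- rank(c(x, y))
  r1 <- r_all[seq_len(n1)]; r2 <- r_all[n1 + seq_len(n2)]
  m1 <- mean(r1); m2 <- mean(r2)
  v1 <- sum((r1 - rank(x) - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r2 - rank(y) - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  p_hat <- (m2 - (n2 + 1) / 2) / n1
  denom <- sqrt(n1 * v1 + n2 * v2)
  if (denom == 0) {
    stat <- if (m1 == m2) 0 else sign(m2 - m1) * Inf
    return(list(statistic = stat, df = NA_real_,
                p_value = if (m1 == m2) 1 else 0,
                relative_effect = p_hat))
  }
  stat <- (n1 * n2 * (m2 - m1)) / ((n1 + n2) * denom)
  df <- (n1 * v1 + n2 * v2)^2 /
    ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  list(statistic = stat, df = df, p_value = p, relative_effect = p_hat)
}

#' Compare stationary variances of reproductive vs other organs
#'
#' Per tree and organ, gamma = sigma2 / (2 alpha); the pooled reproductive
#' organs (ovary, testis) are compared against the four others with the
#' two-sided Brunner-Munzel test (a permutation fallback is used and
#' flagged below 10 values per side).
#'
#' @param models List of `regime_model`s.
#' @return List with `gamma` (long data.frame: family index, organ, gamma),
#'   `test` (Brunner-Munzel or permutation result), `fallback` flag.
#' @export
stationary_variance_compare <- function(models) {
  stopifnot(length(models) >= 2)
  gam <- do.call(rbind, lapply(seq_along(models), function(i) {
    op <- models[[i]]$organ_params
    data.frame(family = i, organ = op$organ, gamma = op$gamma)
  }))
  gam <- gam[is.finite(gam$gamma), , drop = FALSE]
  repro <- gam$gamma[gam$organ %in% c("ovary", "testis")]
  other <- gam$gamma[!gam$organ %in% c("ovary", "testis")]
  fallback <- length(repro) < 10 || length(other) < 10
  test <- if (!fallback) {
    brunner_munzel(other, repro)
  } else {
    # exact-ish permutation on the difference of means
    obs <- mean(repro) - mean(other)
    pool <- c(repro, other)
    perms <- vapply(seq_len(2000), function(i) {
      idx <- sample(length(pool), length(repro))
      mean(pool[idx]) - mean(pool[-idx])
    }, 0)
    list(statistic = obs, df = NA_real_,
         p_value = (sum(abs(perms) >= abs(obs)) + 1) / (2000 + 1),
         relative_effect = NA_real_)
  }
  list(gamma = gam, test = test, fallback = fallback)
}

#' PEO transition matrix
#'
#' Counts ancestral -> derived PEO switches (diagonal is structurally 0:
#' only switching records enter).
#'
#' @param records Shift-record data.frame.
#' @param category Optional category filter ("S", "D", or "R").
#' @return 6x6 integer matrix (rows = ancestral, cols = derived PEO) with
#'   attribute `category`.
#' @export
transition_matrix <- function(records, category = NULL) {
  if (!is.null(category)) {
    records <- records[!is.na(records$category) &
                         records$category == category, , drop = FALSE]
  }
  records <- records[records$peo_switch %in% TRUE, , drop = FALSE]
  m <- matrix(0L, 6, 6, dimnames = list(organs(), organs()))
  if (nrow(records)) {
    tt <- table(factor(records$peo_anc, organs()),
                factor(records$peo_der, organs()))
    m[] <- as.integer(tt)
  }
  attr(m, "category") <- category %||% "all"
  m
}

#' Expressed-gene correction of a transition matrix
#'
#' Optionally controls PEO-shift counts for organ-wise differences in the
#' number of expressed genes: cell (i, j) is divided by the product of the
#' two organs' expressed-gene counts and rescaled to preserve the total.
#'
#' @param m A [transition_matrix()].
#' @param expressed_counts Named (by organ) counts of genes whose unlogged
#'   fitted expression exceeds a floor.
#' @return Numeric 6x6 matrix with the same total as `m`.
#' @export
normalize_transitions <- function(m, expressed_counts) {
  stopifnot(all(organs() %in% names(expressed_counts)),
            all(expressed_counts > 0))
  w <- outer(expressed_counts[organs()], expressed_counts[organs()])
  out <- unclass(m) / w
  diag(out) <- 0
  tot <- sum(m[row(m) != col(m)])
  if (sum(out) > 0) out <- out * tot / sum(out)
  dimnames(out) <- dimnames(m)
  out
}

#' Expressed-gene counts per organ from fitted regime optima
#'
#' @param models List of `regime_model`s.
#' @param floor Unlogged expression threshold (default 1).
#' @return Named count per organ.
#' @export
expressed_gene_counts <- function(models, floor = 1) {
  counts <- stats::setNames(numeric(6), organs())
  for (m in models) {
    mu <- unlog_expr(as.matrix(m$traits))
    counts <- counts + colSums(mu[, organs(), drop = FALSE] > floor)
  }
  counts
}

#' Compare transition matrices across branch categories
#'
#' @param mats Named list of transition matrices (e.g. S, D, R).
#' @return List with `spearman` (pairwise rank correlations of the
#'   off-diagonal flows) and `chisq` (homogeneity test across categories,
#'   off-diagonal cells).
#' @export
compare_transition_matrices <- function(mats) {
  off <- function(m) m[row(m) != col(m)]
  pairs <- utils::combn(names(mats), 2, simplify = FALSE)
  sp <- lapply(pairs, function(pr) {
    stats::cor.test(off(mats[[pr[1]]]), off(mats[[pr[2]]]),
                    method = "spearman", exact = FALSE)
  })
  names(sp) <- vapply(pairs, paste, "", collapse = "_vs_")
  flat <- do.call(rbind, lapply(mats, off))
  keep <- colSums(flat) > 0
  chisq <- if (nrow(flat) >= 2 && sum(keep) >= 2) {
    suppressWarnings(stats::chisq.test(flat[, keep, drop = FALSE]))
  } else NULL
  list(spearman = sp, chisq = chisq)
}

#' Permutation enrichment of PEO transitions
#'
#' Null: the multiset of derived PEO labels is shuffled against the
#' ancestral labels (preserving both margins of the pairing); identity
#' pairings are excluded from the null matrix, mirroring the observed
#' matrix's structural zero diagonal. Per cell, the two-sided empirical
#' p-value is `2 * min(P(null >= obs), P(null <= obs))` with the (b+1)/(n+1)
#' correction, capped at 1.
#'
#' @param matrix_obs Transition matrix from [transition_matrix()].
#' @param config A [stats_config()].
#' @param bh Apply Benjamini-Hochberg adjustment across the 30 off-diagonal
#'   cells (default FALSE).
#' @return List with `p` (6x6 matrix, NA diagonal), `expected` (null mean),
#'   and `n_perm`.
#' @export
permutation_enrichment <- function(matrix_obs, config = stats_config(),
                                   bh = FALSE) {
  if (config$n_perm < 1) stop("n_perm must be >= 1")
  n_tot <- sum(matrix_obs)
  if (n_tot < 1) stop("empty transition matrix")
  anc <- rep(rep(organs(), 6), times = as.vector(matrix_obs))
  der <- rep(rep(organs(), each = 6), times = as.vector(matrix_obs))
  if (length(unique(anc)) < 2 && length(unique(der)) < 2) {
    warning("degenerate margins; p-values undefined")
    p <- matrix(NA_real_, 6, 6, dimnames = dimnames(matrix_obs))
    return(list(p = p, expected = NULL, n_perm = config$n_perm))
  }
  set.seed(derive_seed(config$seed, "perm_enrich",
                       attr(matrix_obs, "category") %||% "all"))
  anc_f <- factor(anc, organs()); der_f <- factor(der, organs())
  ge <- matrix(0L, 6, 6); le <- matrix(0L, 6, 6)
  esum <- matrix(0, 6, 6)
  obs <- unclass(matrix_obs)
  for (b in seq_len(config$n_perm)) {
    perm <- der_f[sample.int(n_tot)]
    keep <- perm != anc_f
    nm <- table(anc_f[keep], perm[keep])
    nm <- matrix(as.integer(nm), 6, 6)
    ge <- ge + (nm >= obs)
    le <- le + (nm <= obs)
    esum <- esum + nm
  }
  n <- config$n_perm
  p <- pmin(2 * pmin((ge + 1) / (n + 1), (le + 1) / (n + 1)), 1)
  dimnames(p) <- dimnames(obs)
  diag(p) <- NA_real_
  if (bh) {
    off <- row(p) != col(p)
    p[off] <- stats::p.adjust(p[off], method = "BH")
  }
  list(p = p, expected = esum / n, n_perm = n)
}

#' Global polarity of PEO shifts
#'
#' `polarity = sum_{i<j} |N_ij - N_ji| / sum_{i!=j} N_ij`, in [0, 1]: 0 for
#' perfectly symmetric flows, 1 for strictly one-directional flows. The
#' bootstrap resamples individual switching records with replacement.
#'
#' @param records Switching shift records (or a transition matrix when
#'   `n_boot` bootstrapping is not needed).
#' @param config A [stats_config()].
#' @param category Optional category filter.
#' @return List with `polarity`, `bootstrap` (numeric vector of length
#'   n_boot), `n_records`.
#' @export
polarity <- function(records, config = stats_config(), category = NULL) {
  if (is.matrix(records)) {
    return(list(polarity = polarity_of_matrix(records),
                bootstrap = numeric(), n_records = sum(records)))
  }
  if (!is.null(category)) {
    records <- records[!is.na(records$category) &
                         records$category == category, , drop = FALSE]
  }
  records <- records[records$peo_switch %in% TRUE, , drop = FALSE]
  if (nrow(records) == 0) stop("no switching records")
  m <- transition_matrix(records)
  set.seed(derive_seed(config$seed, "polarity", category %||% "all"))
  boot <- vapply(seq_len(config$n_boot), function(b) {
    idx <- sample.int(nrow(records), replace = TRUE)
    polarity_of_matrix(transition_matrix(records[idx, , drop = FALSE]))
  }, 0)
  list(polarity = polarity_of_matrix(m), bootstrap = boot,
       n_records = nrow(records))
}

polarity_of_matrix <- function(m) {
  tot <- sum(m[row(m) != col(m)])
  if (tot == 0) return(NA_real_)
  sum(abs(m - t(m))[upper.tri(m)]) / tot
}

#' Pairwise category comparison of polarity bootstrap distributions
#'
#' @param pol_list Named list of [polarity()] results.
#' @return Data.frame of pairwise two-sided Kolmogorov-Smirnov tests.
#' @export
polarity_ks <- function(pol_list) {
  pairs <- utils::combn(names(pol_list), 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    ks <- suppressWarnings(
      stats::ks.test(pol_list[[pr[1]]]$bootstrap,
                     pol_list[[pr[2]]]$bootstrap))
    data.frame(a = pr[1], b = pr[2], D = unname(ks$statistic),
               p_value = ks$p.value)
  }))
}

#' Omega (dN/dS) analyses of shift vs sister branches
#'
#' Pairs with a missing or nonpositive omega, or with a shifted sister, are
#' excluded (and counted). Reports (1) per-category Brunner-Munzel tests of
#' omega on shift (+) vs sister (-) branches, (2) the
#' higher/undifferentiated/lower classification of the raw omega ratio
#' within the +/- band, and (3) least-squares regressions of
#' log2(omega+/omega-) on d_tau (split by sign), on d_mu_max (split by
#' sign), and on TEC, with two-sided t-tests on the slopes (regressions
#' with fewer than 3 points are flagged and report no p-value).
#'
#' @param records Shift-record data.frame.
#' @param config A [stats_config()].
#' @return List with `tests` (per category), `classification`,
#'   `regressions` (data.frame), `excluded` counts.
#' @export
omega_analysis <- function(records, config = stats_config()) {
  ok <- !is.na(records$omega_shift) & !is.na(records$omega_sister) &
    records$omega_shift > 0 & records$omega_sister > 0 &
    !(records$sister_shifted %in% TRUE)
  excluded <- c(missing_or_nonpositive =
                  sum(!ok & !(records$sister_shifted %in% TRUE)),
                sister_shifted = sum(records$sister_shifted %in% TRUE))
  rec <- records[ok, , drop = FALSE]
  ratio <- rec$omega_shift / rec$omega_sister
  lr <- log2(ratio)
  cls <- ifelse(abs(ratio - 1) <= config$undiff_band, "undifferentiated",
                ifelse(ratio > 1, "higher", "lower"))
  tests <- lapply(c(S = "S", D = "D", R = "R"), function(cc) {
    sel <- rec$category %in% cc
    if (sum(sel) < 2) return(NULL)
    brunner_munzel(rec$omega_sister[sel], rec$omega_shift[sel])
  })
  reg_one <- function(x, y, label) {
    keep <- is.finite(x) & is.finite(y)
    if (sum(keep) < 3 || stats::sd(x[keep]) == 0) {
      return(data.frame(term = label, n = sum(keep), slope = NA_real_,
                        p_value = NA_real_, insufficient = TRUE))
    }
    fit <- stats::lm(y ~ x, data = data.frame(x = x[keep], y = y[keep]))
    sm <- summary(fit)$coefficients
    data.frame(term = label, n = sum(keep), slope = sm["x", "Estimate"],
               p_value = sm["x", "Pr(>|t|)"], insufficient = FALSE)
  }
  regs <- list()
  for (cc in c("S", "D", "R")) {
    sel <- rec$category %in% cc
    r <- rec[sel, , drop = FALSE]; l <- lr[sel]
    regs[[length(regs) + 1L]] <-
      reg_one(r$d_tau[r$d_tau < 0], l[r$d_tau < 0],
              paste0(cc, ":d_tau_neg"))
    regs[[length(regs) + 1L]] <-
      reg_one(r$d_tau[r$d_tau > 0], l[r$d_tau > 0],
              paste0(cc, ":d_tau_pos"))
    regs[[length(regs) + 1L]] <-
      reg_one(r$d_mu_max[r$d_mu_max < 0], l[r$d_mu_max < 0],
              paste0(cc, ":d_mu_max_neg"))
    regs[[length(regs) + 1L]] <-
      reg_one(r$d_mu_max[r$d_mu_max > 0], l[r$d_mu_max > 0],
              paste0(cc, ":d_mu_max_pos"))
    regs[[length(regs) + 1L]] <- reg_one(r$tec, l, paste0(cc, ":tec"))
  }
  list(tests = tests,
       classification = c(table(factor(cls, c("higher",
                                              "undifferentiated",
                                              "lower")))),
       classification_prop = c(prop.table(table(factor(cls,
                                                       c("higher",
                                                         "undifferentiated",
                                                         "lower"))))),
       regressions = do.call(rbind, regs),
       excluded = excluded, n_pairs = nrow(rec))
}

#' Rerun the PEO analyses on high-confidence record subsets
#'
#' @param records Shift-record data.frame.
#' @param config A [stats_config()].
#' @param tau_min Keep records with derived tau above this (NA = no filter).
#' @param bootstrap_min Keep records with bootstrap support above this
#'   (NA = no filter).
#' @return List with the filtered records, per-category transition matrices,
#'   enrichment p-values, polarity, and `concordance` (fraction of cells
#'   significant in the full analysis that stay significant), or a `skipped`
#'   marker when the subset is empty.
#' @export
robustness_subsets <- function(records, config = stats_config(),
                               tau_min = NA, bootstrap_min = NA) {
  sub <- records
  if (!is.na(tau_min)) sub <- sub[!is.na(sub$tau_der) &
                                    sub$tau_der > tau_min, , drop = FALSE]
  if (!is.na(bootstrap_min)) {
    sub <- sub[!is.na(sub$bootstrap_support) &
                 sub$bootstrap_support > bootstrap_min, , drop = FALSE]
  }
  if (nrow(sub[sub$peo_switch %in% TRUE, , drop = FALSE]) == 0) {
    return(list(skipped = TRUE, reason = "empty subset", records = sub))
  }
  run <- function(rr) {
    m <- transition_matrix(rr)
    list(matrix = m,
         enrichment = permutation_enrichment(m, config),
         polarity = polarity(rr, config))
  }
  full <- run(records)
  filt <- run(sub)
  sig_full <- full$enrichment$p < config$alpha_level
  sig_filt <- filt$enrichment$p < config$alpha_level
  conc <- if (any(sig_full, na.rm = TRUE)) {
    sum(sig_full & sig_filt, na.rm = TRUE) / sum(sig_full, na.rm = TRUE)
  } else NA_real_
  list(skipped = FALSE, records = sub, full = full, filtered = filt,
       concordance = conc)
}
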
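# Amalgamation: turn heterogeneous per-sample expression tables into
# per-species organ-wise mean expression. Steps: TMM scaling across samples
# using single-copy orthologs, log2(N+1) transform, iterative removal of
# anomalous projects by a correlation majority rule, surrogate-variable
# correction with the organ design protected, and organ-wise averaging.

#' Construct an expression table
#'
#' A genes x samples numeric matrix carrying a metric tag that every
#' transform updates.
#'
#' @param values Genes x samples matrix with dimnames.
#' @param metric One of "TPM", "FPKM", "TMM-FPKM", "log-TPM",
#'   "log-TMM-FPKM", "SVA-log-TPM", "SVA-log-TMM-FPKM".
#' @return The matrix with a `metric` attribute.
#' @export
expression_table <- function(values, metric) {
  metric <- match.arg(metric, c("TPM", "FPKM", "TMM-FPKM", "log-TPM",
                                "log-TMM-FPKM", "SVA-log-TPM",
                                "SVA-log-TMM-FPKM"))
  values <- as.matrix(values)
  if (anyNA(values)) stop("expression table must not contain missing values")
  if (!grepl("log", metric) && any(values < 0)) {
    stop("unlogged expression values must be nonnegative")
  }
  attr(values, "metric") <- metric
  values
}

#' Metric tag of an expression table
#' @param table An [expression_table()].
#' @return Character scalar.
#' @export
expr_metric <- function(table) {
  m <- attr(table, "metric")
  if (is.null(m)) stop("table has no metric tag")
  m
}

#' TMM scaling factors from single-copy orthologs
#'
#' Computes per-sample scaling factors by the weighted trimmed mean of
#' M-values against a reference sample, using only the single-copy ortholog
#' rows; because amalgamated FPKM columns are compared directly (not via
#' library sizes), the factors absorb both depth and composition
#' differences. Factors are normalized to geometric mean 1.
#'
#' @param fpkm An unlogged FPKM [expression_table()].
#' @param single_copy_ids Gene IDs of single-copy orthologs.
#' @param min_genes Minimum usable single-copy genes (default 20).
#' @return Named numeric vector of factors, one per sample.
#' @export
tmm_factors <- function(fpkm, single_copy_ids, min_genes = 20) {
  stopifnot(ncol(fpkm) >= 2)
  if (!all(single_copy_ids %in% rownames(fpkm))) {
    stop("single_copy_ids must be a subset of the table's genes")
  }
  sub <- fpkm[single_copy_ids, , drop = FALSE]
  usable <- rowSums(sub > 0) == ncol(sub)
  if (sum(usable) < min_genes) {
    stop("fewer than ", min_genes, " usable single-copy genes (",
         sum(usable), ")")
  }
  f <- edgeR::calcNormFactors(sub[usable, , drop = FALSE],
                              lib.size = rep(1, ncol(sub)), method = "TMM")
  stats::setNames(f, colnames(fpkm))
}

#' Apply TMM factors to an FPKM table
#'
#' @param fpkm An unlogged FPKM [expression_table()].
#' @param factors Output of [tmm_factors()].
#' @return A "TMM-FPKM" [expression_table()].
#' @export
apply_tmm <- function(fpkm, factors) {
  stopifnot(expr_metric(fpkm) == "FPKM",
            all(colnames(fpkm) %in% names(factors)))
  expression_table(sweep(fpkm, 2, factors[colnames(fpkm)], "/"), "TMM-FPKM")
}

#' log2(N + 1) transform
#'
#' @param table An unlogged [expression_table()].
#' @return The log2(x + 1) table with its metric tag updated.
#' @export
log_transform <- function(table) {
  metric <- expr_metric(table)
  if (grepl("log", metric)) stop("table is already on the log scale")
  if (any(table < 0)) stop("negative expression values")
  expression_table(log2(table + 1), paste0("log-", metric))
}

# Correlations of one sample against leave-own-project-out organ means.
# Returns the per-organ correlation vector plus a fallback flag.
sample_organ_cors <- function(values, meta, s) {
  organs_here <- unique(meta$organ)
  own_proj <- meta$project_id[s]
  cors <- rep(NA_real_, length(organs_here))
  fallback <- FALSE
  for (j in seq_along(organs_here)) {
    sel <- meta$organ == organs_here[j] & meta$project_id != own_proj
    if (!any(sel)) {
      sel <- meta$organ == organs_here[j] & seq_len(nrow(meta)) != s
      fallback <- TRUE
    }
    if (!any(sel)) next
    m <- rowMeans(values[, sel, drop = FALSE])
    cors[j] <- suppressWarnings(stats::cor(values[, s], m))
  }
  list(cors = stats::setNames(cors, organs_here), fallback = fallback)
}

#' Iterative removal of anomalous projects
#'
#' Every sample is correlated (Pearson) against the mean expression of each
#' organ computed from all samples outside the sample's own project. A
#' sample violates the curation assumption when its same-organ correlation
#' is not strictly greater than every other-organ correlation (ties count
#' as violations). Per iteration, the single project with the most violating
#' samples is removed (ties: higher violating fraction, then lexicographic
#' project ID); iteration continues until no violations remain.
#'
#' @param table A log-scale [expression_table()] for one species.
#' @param meta Sample metadata data.frame with columns `sample_id`,
#'   `project_id`, `species`, `organ`, aligned with `colnames(table)`.
#' @param rule Whether the majority rule ranks projects by violating sample
#'   `count` (default) or `fraction`.
#' @return A `curation_report` list: `iterations` (each with
#'   `removed_project_id` and `violating_samples`), `kept_samples`,
#'   `removed_samples`, `skipped` (with `reason`), `status`, and
#'   `missing_organs` (organs left without samples).
#' @export
iterative_removal <- function(table, meta, rule = c("count", "fraction")) {
  rule <- match.arg(rule)
  stopifnot(identical(colnames(table), meta$sample_id))
  all_samples <- meta$sample_id
  report <- list(iterations = list(), kept_samples = all_samples,
                 removed_samples = character(), skipped = FALSE,
                 reason = NULL, status = "ok",
                 missing_organs = character())
  if (length(unique(meta$project_id)) < 2) {
    report$skipped <- TRUE
    report$reason <- "fewer than 2 projects; curation skipped"
    class(report) <- "curation_report"
    return(report)
  }
  keep <- rep(TRUE, nrow(meta))
  repeat {
    cur_meta <- meta[keep, , drop = FALSE]
    cur_tab <- table[, keep, drop = FALSE]
    if (nrow(cur_meta) == 0) {
      report$status <- "warning: all projects removed"
      break
    }
    violating <- character()
    for (s in seq_len(nrow(cur_meta))) {
      sc <- sample_organ_cors(cur_tab, cur_meta, s)
      same <- sc$cors[[cur_meta$organ[s]]]
      others <- sc$cors[names(sc$cors) != cur_meta$organ[s]]
      others <- others[!is.na(others)]
      if (is.na(same) || (length(others) && same <= max(others))) {
        violating <- c(violating, cur_meta$sample_id[s])
      }
    }
    if (length(violating) == 0) break
    vmeta <- cur_meta[cur_meta$sample_id %in% violating, , drop = FALSE]
    n_viol <- table(vmeta$project_id)
    size <- table(cur_meta$project_id)[names(n_viol)]
    frac <- as.numeric(n_viol) / as.numeric(size)
    ranking <- if (rule == "count") {
      order(-as.numeric(n_viol), -frac, names(n_viol))
    } else {
      order(-frac, -as.numeric(n_viol), names(n_viol))
    }
    worst <- names(n_viol)[ranking[1]]
    report$iterations[[length(report$iterations) + 1L]] <- list(
      removed_project_id = worst,
      violating_samples = violating)
    keep <- keep & meta$project_id != worst
  }
  report$kept_samples <- meta$sample_id[keep]
  report$removed_samples <- setdiff(all_samples, report$kept_samples)
  report$missing_organs <- setdiff(unique(meta$organ),
                                   unique(meta$organ[keep]))
  if (length(report$missing_organs) && report$status == "ok") {
    report$status <- "warning: organ(s) lost during curation"
  }
  class(report) <- "curation_report"
  report
}

# Buja-Eyuboglu permutation parallel analysis: how many leading principal
# directions of the residual matrix carry more variance than row-permuted
# (signal-destroyed) residuals. Permutation p-values use the (b+1)/(B+1)
# estimator and are forced monotone down the eigenvalue sequence.
num_sv_be <- function(res, hat, B = 20, alpha = 0.05) {
  n <- ncol(res); m <- nrow(res)
  ndf <- min(m, n) - as.integer(round(sum(diag(hat))))
  if (ndf < 1) return(0L)
  d <- svd(res, nu = 0, nv = 0)$d[seq_len(ndf)]
  dstat <- d^2 / sum(d^2)
  exceed <- integer(ndf)
  for (b in seq_len(B)) {
    res0 <- t(apply(res, 1, sample))
    res0 <- res0 - res0 %*% hat
    d0 <- svd(res0, nu = 0, nv = 0)$d[seq_len(ndf)]
    d0 <- d0^2 / sum(d0^2)
    exceed <- exceed + (d0 >= dstat)
  }
  p <- (exceed + 1) / (B + 1)
  p <- cummax(p)
  sum(p <= alpha)
}

#' Surrogate-variable correction with the organ design protected
#'
#' The number of surrogate variables is selected by Buja-Eyuboglu
#' permutation parallel analysis on the residuals of the organ-mean model
#' (20 row permutations, alpha = 0.05, monotone p-values with the
#' (b+1)/(B+1) estimator); the surrogate variables are the leading
#' principal directions of those residuals. Their contribution is regressed
#' out while protecting organ effects (`limma::removeBatchEffect` with the
#' organ design).
#'
#' @param table A curated log-scale [expression_table()] for one species.
#' @param meta Metadata aligned with the table's columns.
#' @param seed Integer seed for the permutation selection.
#' @param n_sv Optional override of the number of surrogate variables.
#' @param B,alpha Permutation count and level for the parallel analysis.
#' @return List with `table` (corrected, metric tag prefixed "SVA-") and
#'   `model` (`n_sv`, `sv_matrix`, `protected_design`).
#' @export
sva_correct <- function(table, meta, seed = 1, n_sv = NULL, B = 20,
                        alpha = 0.05) {
  stopifnot(identical(colnames(table), meta$sample_id))
  metric <- expr_metric(table)
  if (!grepl("^log", metric)) stop("sva_correct expects a log-scale table")
  organ <- factor(meta$organ)
  if (nlevels(organ) < 2) stop("organ design is not full rank")
  mod <- stats::model.matrix(~organ)
  rownames(mod) <- meta$sample_id
  dat <- as.matrix(table)
  dat <- dat[apply(dat, 1, stats::sd) > 0, , drop = FALSE]
  resid_rank <- ncol(dat) - qr(mod)$rank
  if (is.null(n_sv)) {
    set.seed(derive_seed(seed, "num_sv"))
    hat <- mod %*% solve(crossprod(mod)) %*% t(mod)
    res0 <- dat - dat %*% hat
    n_sv <- num_sv_be(res0, hat, B = B, alpha = alpha)
  }
  if (n_sv > resid_rank) {
    warning("requested ", n_sv, " surrogate variables; capped at residual ",
            "rank ", resid_rank)
    n_sv <- resid_rank
  }
  if (n_sv <= 0) {
    model <- list(n_sv = 0L,
                  sv_matrix = matrix(0, nrow(meta), 0),
                  protected_design = mod)
    return(list(table = expression_table(as.matrix(table),
                                         paste0("SVA-", metric)),
                model = model))
  }
  fit <- stats::lm.fit(mod, t(dat))
  res <- t(fit$residuals)
  sv <- svd(res, nu = 0, nv = n_sv)$v
  sv <- qr.Q(qr(sv))  # enforce orthonormality
  colnames(sv) <- paste0("SV", seq_len(ncol(sv)))
  rownames(sv) <- meta$sample_id
  cleaned <- limma::removeBatchEffect(as.matrix(table), covariates = sv,
                                      design = mod)
  list(table = expression_table(cleaned, paste0("SVA-", metric)),
       model = list(n_sv = as.integer(n_sv), sv_matrix = sv,
                    protected_design = mod))
}

#' Organ-wise mean expression
#'
#' @param table A corrected log-scale [expression_table()].
#' @param meta Metadata aligned with the table's columns.
#' @return Genes x organs matrix of arithmetic means on the log scale, with
#'   attribute `missing_organs` listing organs (from the fixed vocabulary)
#'   without samples.
#' @export
organ_means <- function(table, meta) {
  stopifnot(identical(colnames(table), meta$sample_id))
  present <- intersect(organs(), unique(meta$organ))
  out <- sapply(present, function(o) {
    rowMeans(table[, meta$organ == o, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(table),
                dimnames = list(rownames(table), present))
  attr(out, "missing_organs") <- setdiff(organs(), present)
  out
}

#' Subsampling convergence of organ means
#'
#' For each project-subset size k, computes the mean expression of one gene
#' in one organ over every (or at most `max_subsets` sampled) k-subset of
#' projects, mirroring a convergence diagnostic for amalgamated expression
#' estimates.
#'
#' @param table Log-scale [expression_table()].
#' @param meta Metadata aligned with the table.
#' @param gene Gene ID.
#' @param organ Organ label.
#' @param k_range Integer vector of subset sizes.
#' @param max_subsets Cap on enumerated subsets per k.
#' @param seed Seed used when subsets are sampled.
#' @return Named list, one numeric vector of subset means per k (k values
#'   exceeding the number of projects are skipped).
#' @export
subsample_convergence <- function(table, meta, gene, organ,
                                  k_range, max_subsets = 200, seed = 1) {
  sel <- meta$organ == organ
  stopifnot(gene %in% rownames(table))
  projects <- sort(unique(meta$project_id[sel]))
  if (length(projects) < 2) stop("need >= 2 projects for the organ")
  set.seed(derive_seed(seed, "subsample", gene, organ))
  out <- list()
  for (k in k_range) {
    if (k > length(projects)) next
    combs <- if (choose(length(projects), k) <= max_subsets) {
      utils::combn(projects, k, simplify = FALSE)
    } else {
      lapply(seq_len(max_subsets),
             function(i) sample(projects, k))
    }
    vals <- vapply(combs, function(ps) {
      cols <- sel & meta$project_id %in% ps
      mean(table[gene, cols])
    }, 0)
    out[[as.character(k)]] <- vals
  }
  out
}

#' Full per-species amalgamation
#'
#' Convenience wrapper: TMM scaling (FPKM), log transform, iterative
#' curation, SVA correction, and organ means, for both metrics.
#'
#' @param samples Output of [simulate_samples()] or a list with `tpm`,
#'   `fpkm`, `meta` in the same layout.
#' @param single_copy_ids Gene IDs used for TMM scaling (default: all).
#' @param seed Integer seed.
#' @return List with per-metric results (`tpm`, `fpkm`), each holding
#'   `curation`, `sva`, `table` (SVA-corrected), and `means` (genes x
#'   organs).
#' @export
amalgamate <- function(samples, single_copy_ids = NULL, seed = 1) {
  if (is.null(single_copy_ids)) single_copy_ids <- rownames(samples$fpkm)
  fac <- tmm_factors(samples$fpkm, single_copy_ids)
  tables <- list(tpm = log_transform(samples$tpm),
                 fpkm = log_transform(apply_tmm(samples$fpkm, fac)))
  out <- list()
  for (m in names(tables)) {
    tab <- tables[[m]]
    rep_m <- iterative_removal(tab, samples$meta)
    keep <- samples$meta$sample_id %in% rep_m$kept_samples
    if (rep_m$skipped) keep <- rep(TRUE, nrow(samples$meta))
    meta_k <- samples$meta[keep, , drop = FALSE]
    tab_k <- expression_table(tab[, keep, drop = FALSE], expr_metric(tab))
    sv <- sva_correct(tab_k, meta_k, seed = derive_seed(seed, m))
    out[[m]] <- list(curation = rep_m, sva = sv$model, table = sv$table,
                     meta = meta_k, means = organ_means(sv$table, meta_k))
  }
  out$tmm_factors <- fac
  out
}
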
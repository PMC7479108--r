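# Per-sample expression simulation: organ truth means plus a rank-one
# project (batch) effect plus i.i.d. noise, on the log2 scale. Anomalous
# projects have their organ labels deranged, planting the metadata
# violations that the curation stage is designed to catch.

#' Parameters for sample-level simulation
#'
#' @param projects_per_organ Number of projects; every project contributes
#'   samples to all six organs.
#' @param samples_per_project Samples per organ per project.
#' @param project_effect_sd SD of the per-project batch score (log2 units);
#'   the batch effect is `loading[gene] * score[project]`.
#' @param noise_sd SD of i.i.d. sample noise (log2 units).
#' @param libsize_lognormal_sd Log-SD of the per-sample library factor
#'   applied to the FPKM variant.
#' @param n_anomalous_projects Number of projects whose organ labels are
#'   deranged.
#' @param seed Integer seed.
#' @return A `sample_sim_params` list.
#' @export
sample_sim_params <- function(projects_per_organ = 4, samples_per_project = 2,
                              project_effect_sd = 0.5, noise_sd = 0.5,
                              libsize_lognormal_sd = 0.3,
                              n_anomalous_projects = 0, seed = 1) {
  stopifnot(projects_per_organ >= 0, samples_per_project >= 0,
            project_effect_sd >= 0, noise_sd >= 0,
            libsize_lognormal_sd >= 0,
            n_anomalous_projects >= 0,
            n_anomalous_projects <= projects_per_organ)
  structure(list(projects_per_organ = as.integer(projects_per_organ),
                 samples_per_project = as.integer(samples_per_project),
                 project_effect_sd = project_effect_sd, noise_sd = noise_sd,
                 libsize_lognormal_sd = libsize_lognormal_sd,
                 n_anomalous_projects = as.integer(n_anomalous_projects),
                 seed = as.integer(seed)),
            class = "sample_sim_params")
}

# Fixed-point-free permutation of 1..n (n >= 2).
derangement <- function(n) {
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Simulate per-sample expression tables for one species
#'
#' @param truth Genes x 6 matrix of log2-scale organ truth means (columns in
#'   [organs()] order; row names are gene IDs).
#' @param params A [sample_sim_params()] list.
#' @param species Species label recorded in the metadata.
#' @return List with `tpm` and `fpkm` (unlogged genes x samples
#'   `expression_table`s), `log_signal` (noiseless log2 organ values per
#'   sample, for reference), `meta` (sample metadata data.frame), and
#'   `truth` (anomalous project IDs, library factors, batch scores).
#' @export
simulate_samples <- function(truth, params = sample_sim_params(),
                             species = "sp01") {
  stopifnot(is.matrix(truth), ncol(truth) == 6)
  colnames(truth) <- organs()
  if (is.null(rownames(truth))) {
    rownames(truth) <- sprintf("g%04d", seq_len(nrow(truth)))
  }
  set.seed(derive_seed(params$seed, "samples", species))
  n_proj <- params$projects_per_organ
  n_per <- params$samples_per_project
  meta <- expand.grid(rep = seq_len(n_per), organ = organs(),
                      project_id = sprintf("PRJ%03d", seq_len(n_proj)),
                      stringsAsFactors = FALSE)
  meta$species <- species
  meta$sample_id <- sprintf("%s_%s_%s_r%d", species, meta$project_id,
                            meta$organ, meta$rep)
  meta <- meta[, c("sample_id", "project_id", "species", "organ")]
  anomalous <- character()
  gen_organ <- meta$organ  # organ actually generating the data
  if (params$n_anomalous_projects > 0) {
    anomalous <- sprintf("PRJ%03d", seq_len(params$n_anomalous_projects))
    swap <- stats::setNames(organs()[derangement(6L)], organs())
    bad <- meta$project_id %in% anomalous
    gen_organ[bad] <- swap[meta$organ[bad]]
  }
  n_s <- nrow(meta)
  loading <- stats::rnorm(nrow(truth))
  score <- stats::setNames(
    stats::rnorm(n_proj, 0, params$project_effect_sd),
    sprintf("PRJ%03d", seq_len(n_proj)))
  logval <- truth[, gen_organ, drop = FALSE] +
    outer(loading, score[meta$project_id]) +
    matrix(stats::rnorm(nrow(truth) * n_s, 0, params$noise_sd),
           nrow(truth), n_s)
  colnames(logval) <- meta$sample_id
  raw <- unlog_expr(logval)
  tpm <- sweep(raw, 2, pmax(colSums(raw), 1e-12), "/") * 1e6
  libfac <- exp(stats::rnorm(n_s, 0, params$libsize_lognormal_sd))
  fpkm <- sweep(raw, 2, libfac, "*")
  list(tpm = expression_table(tpm, "TPM"),
       fpkm = expression_table(fpkm, "FPKM"),
       log_signal = truth[, gen_organ, drop = FALSE],
       meta = meta,
       truth = list(anomalous_projects = anomalous,
                    lib_factors = stats::setNames(libfac, meta$sample_id),
                    project_scores = score))
}
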
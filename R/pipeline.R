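# End-to-end orchestration on synthetic (or pre-simulated) inputs:
# simulate families and samples, amalgamate per species, detect shifts per
# metric, take the cross-metric consensus, annotate branches, and compute
# the propensity statistics. Failures are isolated per family; all
# randomness flows through seeds derived from the global seed, so reruns
# are bit-identical.

#' Pipeline configuration
#'
#' @param n_species,root_age Species-tree shape.
#' @param n_families Gene families to simulate.
#' @param family_params,expr_params,sample_params,omega_params Stage
#'   parameter templates (seeds are re-derived per family from `seed`).
#' @param search Shift-search configuration ([shift_search_config()]).
#' @param stats A [stats_config()].
#' @param use_dating Re-estimate node ages from substitution-scale branch
#'   lengths (rooting + constraints + WLS dating) instead of using the
#'   simulated ages.
#' @param n_scaling_genes Simulated single-copy ortholog genes added to
#'   every species' table; they anchor the TMM scaling (mirroring the
#'   single-copy set used on real data) and are excluded from the family
#'   analyses.
#' @param min_tips Families with fewer tips are skipped.
#' @param seed Global integer seed.
#' @param outdir Optional directory for TSV/JSON outputs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_species = 6, root_age = 400, n_families = 8,
                            family_params = family_sim_params(),
                            expr_params = expr_sim_params(),
                            sample_params = sample_sim_params(),
                            omega_params = omega_sim_params(),
                            search = shift_search_config(),
                            stats = stats_config(n_perm = 1000,
                                                 n_boot = 200),
                            use_dating = FALSE, n_scaling_genes = 60,
                            min_tips = 4, seed = 1, outdir = NULL) {
  structure(list(n_species = n_species, root_age = root_age,
                 n_families = n_families, family_params = family_params,
                 expr_params = expr_params, sample_params = sample_params,
                 omega_params = omega_params, search = search,
                 stats = stats, use_dating = use_dating,
                 n_scaling_genes = as.integer(n_scaling_genes),
                 min_tips = min_tips, seed = as.integer(seed),
                 outdir = outdir), class = "pipeline_config")
}

# Reseed a stage parameter template for one family.
reseed <- function(params, seed, ...) {
  params$seed <- derive_seed(seed, ...)
  params
}

#' Run the full pipeline
#'
#' Stages: simulate families -> simulate expression truth -> per-species
#' sample simulation and amalgamation (both metrics) -> per-family shift
#' detection on each metric -> consensus -> branch annotation (S/D/R via
#' species overlap + intron posteriors) -> shift records and propensity
#' statistics.
#'
#' @param config A [pipeline_config()].
#' @return List with `manifest` (per-family status), `records` (shift
#'   records), `census` (all classified branches with durations), `stats`
#'   (shift rates, transition matrices, enrichment, polarity, omega), and
#'   `families` (per-family detail).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  sp <- species_tree_spec(sim_species_tree(config$n_species,
                                           config$root_age,
                                           seed = config$seed))
  manifest <- list()
  fams <- list()
  # ---- stage 1: families + expression truth
  for (w in seq_len(config$n_families)) {
    fid <- sprintf("fam%03d", w)
    st <- tryCatch({
      fam <- simulate_gene_family(sp, reseed(config$family_params,
                                             config$seed, "family", fid))
      if (fam$extinct || fam$n_tips < config$min_tips) {
        list(status = if (fam$extinct) "skipped:extinct" else
          "skipped:too_small")
      } else {
        expr <- simulate_ou_expression(fam, reseed(config$expr_params,
                                                   config$seed, "expr",
                                                   fid))
        omega <- simulate_omega(fam, expr$shifts$branch,
                                reseed(config$omega_params, config$seed,
                                       "omega", fid))
        fams[[fid]] <- list(family = fam, expr = expr, omega = omega)
        list(status = "ok")
      }
    }, error = function(e) list(status = paste0("error:",
                                                conditionMessage(e))))
    manifest[[fid]] <- st$status
  }
  ok_ids <- names(fams)
  # ---- stage 2: per-species samples + amalgamation
  # conserved single-copy scaling genes, shared across species; they are
  # drawn highly expressed so that, as in a real transcriptome, no single
  # family gene dominates the per-sample total that TPM normalizes by
  set.seed(derive_seed(config$seed, "scaling_genes"))
  n_sc <- max(config$n_scaling_genes, 0L)
  sc_truth <- matrix(stats::rnorm(n_sc, 8, 1.5), n_sc, 6) +
    matrix(stats::rnorm(n_sc * 6, 0, 0.5), n_sc, 6)
  rownames(sc_truth) <- sprintf("sc%04d", seq_len(n_sc))
  colnames(sc_truth) <- organs()
  gene_means <- list(tpm = NULL, fpkm = NULL)
  species_reports <- list()
  for (s in sp$tree$tip.label) {
    rows <- if (n_sc > 0) list(sc_truth) else list()
    for (fid in ok_ids) {
      fam <- fams[[fid]]
      sel <- names(fam$family$tip_species)[fam$family$tip_species == s]
      if (length(sel) == 0) next
      m <- fam$expr$traits[sel, , drop = FALSE]
      rownames(m) <- paste(fid, sel, sep = ".")
      rows[[length(rows) + 1L]] <- m
    }
    if (length(rows) == (n_sc > 0)) next  # no family genes in species
    truth <- do.call(rbind, rows)
    samples <- simulate_samples(truth,
                                reseed(config$sample_params, config$seed,
                                       "samples", s), species = s)
    am <- tryCatch(amalgamate(samples,
                              single_copy_ids = rownames(sc_truth),
                              seed = derive_seed(config$seed,
                                                 "amalgam", s)),
                   error = function(e) NULL)
    if (is.null(am)) next
    species_reports[[s]] <- list(curation_tpm = am$tpm$curation,
                                 curation_fpkm = am$fpkm$curation,
                                 n_sv = c(tpm = am$tpm$sva$n_sv,
                                          fpkm = am$fpkm$sva$n_sv))
    for (m in c("tpm", "fpkm")) {
      gene_means[[m]] <- rbind(gene_means[[m]], am[[m]]$means)
    }
  }
  # ---- stage 3: per-family detection, annotation, records
  all_records <- list()
  census <- list()
  models_tpm <- list()
  for (fid in ok_ids) {
    res <- tryCatch(
      pipeline_family(fid, fams[[fid]], sp, gene_means, config),
      error = function(e) list(error = conditionMessage(e)))
    if (!is.null(res$error)) {
      manifest[[fid]] <- paste0("error:", res$error)
      next
    }
    fams[[fid]]$analysis <- res
    if (nrow(res$records)) all_records[[fid]] <- res$records
    census[[fid]] <- res$census
    models_tpm[[fid]] <- res$model_tpm
  }
  records <- if (length(all_records)) do.call(rbind, all_records) else
    empty_shift_records()
  rownames(records) <- NULL
  census <- if (length(census)) do.call(rbind, census) else
    data.frame(category = character(), duration = numeric())
  rownames(census) <- NULL
  # ---- stage 4: downstream statistics
  stats_out <- list()
  if (nrow(records)) {
    stats_out$rates <- shift_rates(records, census)
    mats <- lapply(c(S = "S", D = "D", R = "R"), function(cc)
      transition_matrix(records, cc))
    stats_out$transition <- mats
    nonempty <- vapply(mats, sum, 0) > 0
    stats_out$enrichment <- lapply(mats[nonempty], function(m)
      tryCatch(permutation_enrichment(m, config$stats),
               error = function(e) NULL))
    stats_out$polarity <- lapply(names(mats)[nonempty], function(cc)
      tryCatch(polarity(records, config$stats, category = cc),
               error = function(e) NULL))
    names(stats_out$polarity) <- names(mats)[nonempty]
    stats_out$omega <- tryCatch(omega_analysis(records, config$stats),
                                error = function(e) NULL)
  }
  manifest_df <- data.frame(family = names(manifest),
                            status = unlist(manifest))
  rownames(manifest_df) <- NULL
  out <- list(manifest = manifest_df, records = records, census = census,
              stats = stats_out, species_tree = sp,
              species_reports = species_reports, families = fams)
  if (!is.null(config$outdir)) write_pipeline_outputs(out, config)
  out
}

# Analyze one family: trait assembly, (optional) dating, detection on both
# metrics, consensus, annotation, records.
pipeline_family <- function(fid, fam, sp, gene_means, config) {
  tree <- fam$family$tree
  gene_ids <- paste(fid, tree$tip.label, sep = ".")
  traits <- list()
  for (m in c("tpm", "fpkm")) {
    gm <- gene_means[[m]]
    if (is.null(gm) || !all(gene_ids %in% rownames(gm))) {
      stop("missing amalgamated means for ", fid)
    }
    tm <- gm[gene_ids, organs(), drop = FALSE]
    rownames(tm) <- tree$tip.label
    traits[[m]] <- tm
  }
  ana_tree <- tree
  if (config$use_dating) {
    rt <- root_tree(fam$family$subst_tree, sp$tree, fam$family$tip_species)
    cls <- classify_species_overlap(rt$tree, fam$family$tip_species,
                                    sp$tree)
    cons <- build_constraints(rt$tree, cls)
    ana_tree <- date_tree(rt$tree, cons)$tree
  }
  search <- config$search
  search$seed <- derive_seed(config$seed, "search", fid)
  model_tpm <- detect_shifts(ana_tree, traits$tpm, search)
  model_fpkm <- detect_shifts(ana_tree, traits$fpkm, search)
  cons_sh <- consensus_shifts(model_tpm, model_fpkm)
  # annotation on the analysis tree
  ev_cls <- classify_species_overlap(ana_tree, fam$family$tip_species,
                                     sp$tree)
  intron_states <- ifelse(fam$family$tip_introns[ana_tree$tip.label] > 0,
                          "containing", "intronless")
  intron_post <- ancestral_binary(ana_tree, intron_states,
                                  discrete_char_model("intron"))
  chrom_post <- ancestral_binary(ana_tree,
                                 fam$family$tip_chromosome[
                                   ana_tree$tip.label],
                                 discrete_char_model("chromosome"))
  branches <- classify_branches(ana_tree, ev_cls$events, intron_post,
                                chrom_post)
  cat_map <- stats::setNames(branches$category, branches$branch)
  durations <- stats::setNames(ana_tree$edge.length, branch_ids(ana_tree))
  census <- data.frame(family = fid, branch = branches$branch,
                       category = branches$category,
                       duration = as.numeric(durations[branches$branch]))
  # records only for consensus branches that survive in the skimmed tree
  usable <- intersect(cons_sh$branches, branch_ids(model_fpkm$tree))
  records <- build_shift_records(model_fpkm, branches = usable,
                                 category = cat_map, omega = fam$omega,
                                 family_id = fid)
  list(model_tpm = model_tpm, model_fpkm = model_fpkm,
       consensus = cons_sh, branches = branches, census = census,
       records = records, tree = ana_tree)
}

write_pipeline_outputs <- function(out, config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(out$records, file.path(config$outdir,
                                            "shift_records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(out$manifest, file.path(config$outdir,
                                             "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(out$census, file.path(config$outdir, "census.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(out$stats$rates)) {
    write_json_report(list(rates = out$stats$rates$table),
                      file.path(config$outdir, "stats.json"))
  }
  invisible(NULL)
}

#' Validate pipeline input files
#'
#' Report-only schema checks for externally supplied inputs.
#'
#' @param species_tree_path Newick species tree.
#' @param gene_tree_paths Character vector of newick gene trees.
#' @param expression_paths Character vector of expression TSVs.
#' @param meta_path Sample metadata TSV.
#' @param species_map Named tip -> species vector (optional).
#' @return List with `issues` (character vector; empty when everything
#'   checks out) and `checked` counts.
#' @export
validate_inputs <- function(species_tree_path = NULL,
                            gene_tree_paths = character(),
                            expression_paths = character(),
                            meta_path = NULL, species_map = NULL) {
  issues <- character()
  n_checked <- 0L
  sp_tree <- NULL
  if (!is.null(species_tree_path)) {
    n_checked <- n_checked + 1L
    if (!file.exists(species_tree_path)) {
      issues <- c(issues, paste0("missing file: ", species_tree_path))
    } else {
      sp_tree <- tryCatch(ape::read.tree(species_tree_path),
                          error = function(e) NULL)
      if (is.null(sp_tree)) {
        issues <- c(issues, "species tree: unparseable newick")
      } else if (!is_ultrametric_tol(sp_tree, 1e-6)) {
        issues <- c(issues, "species tree: not ultrametric")
      }
    }
  }
  for (p in gene_tree_paths) {
    n_checked <- n_checked + 1L
    gt <- tryCatch(ape::read.tree(p), error = function(e) NULL)
    if (is.null(gt)) {
      issues <- c(issues, paste0("gene tree ", p, ": unparseable newick"))
      next
    }
    if (!is.null(species_map)) {
      unmapped <- setdiff(gt$tip.label, names(species_map))
      if (length(unmapped)) {
        issues <- c(issues, paste0("gene tree ", p, ": tips without a ",
                                   "species map: ",
                                   paste(unmapped, collapse = ", ")))
      } else if (!is.null(sp_tree)) {
        missing_sp <- setdiff(species_map[gt$tip.label],
                              sp_tree$tip.label)
        if (length(missing_sp)) {
          issues <- c(issues, paste0("gene tree ", p, ": species absent ",
                                     "from species tree: ",
                                     paste(missing_sp, collapse = ", ")))
        }
      }
    }
  }
  for (p in expression_paths) {
    n_checked <- n_checked + 1L
    tab <- tryCatch(read_expression_tsv(p), error = function(e) NULL)
    if (is.null(tab)) issues <- c(issues, paste0("expression table ", p,
                                                 ": unreadable"))
  }
  if (!is.null(meta_path)) {
    n_checked <- n_checked + 1L
    meta <- tryCatch(read_meta_tsv(meta_path), error = function(e) NULL)
    if (is.null(meta)) {
      issues <- c(issues, "metadata: unreadable or missing columns")
    } else if (!all(meta$organ %in% organs())) {
      issues <- c(issues, "metadata: organ labels outside the fixed ",
                  "vocabulary")
    }
  }
  list(issues = issues, checked = n_checked)
}
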
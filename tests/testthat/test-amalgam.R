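# Amalgamation: TMM scaling, log transform, curation, SVA, organ means.

# Brute-force weighted trimmed-mean-of-M-values oracle for one sample
# against a reference column (canonical trims: 30% on M, 5% on A;
# inverse-asymptotic-variance weights), on raw column ratios.
oracle_tmm_factor <- function(obs, ref) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  n_o <- sum(obs); n_r <- sum(ref)
  M <- log2(obs / ref)
  A <- (log2(obs) + log2(ref)) / 2
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; o <- obs[fin]; r <- ref[fin]
  loM <- stats::quantile(M, 0.3, type = 7)
  hiM <- stats::quantile(M, 0.7, type = 7)
  loA <- stats::quantile(A, 0.05, type = 7)
  hiA <- stats::quantile(A, 0.95, type = 7)
  # edgeR trims by rank, keeping the central mass
  rkM <- rank(M); rkA <- rank(A); n <- length(M)
  keep2 <- rkM >= floor(n * 0.3) + 1 & rkM <= n - floor(n * 0.3) &
    rkA >= floor(n * 0.05) + 1 & rkA <= n - floor(n * 0.05)
  w <- 1 / ((1 - o / n_o) / o + (1 - r / n_r) / r)
  2^(sum(w[keep2] * M[keep2]) / sum(w[keep2]))
}

make_fpkm <- function(mat) {
  expression_table(mat, "FPKM")
}

test_that("TMM factors: identical columns give 1, pure depth is restored,
          planted inflation matches the brute-force oracle within 5%", {
  set.seed(11)
  g <- 200
  base <- exp(stats::rnorm(g, 2, 1))
  ids <- sprintf("sc%03d", seq_len(g))
  m <- cbind(a = base, b = base)
  rownames(m) <- ids
  f <- tmm_factors(make_fpkm(m), ids)
  expect_equal(unname(f), c(1, 1), tolerance = 1e-12)
  # pure 3x depth
  m2 <- cbind(a = base, b = 3 * base, c = base)
  rownames(m2) <- ids
  f2 <- tmm_factors(make_fpkm(m2), ids)
  expect_equal(unname(f2[["b"]] / f2[["a"]]), 3, tolerance = 1e-6)
  corrected <- sweep(m2, 2, f2, "/")
  M_after <- log2(corrected[, "b"] / corrected[, "a"])
  expect_equal(mean(M_after, trim = 0.3), 0, tolerance = 1e-6)
  # planted 2-fold inflation of a 10% subset in one of three samples
  m3 <- cbind(a = base, b = base, c = base)
  infl <- seq_len(g %/% 10)
  m3[infl, "c"] <- 2 * m3[infl, "c"]
  rownames(m3) <- ids
  f3 <- tmm_factors(make_fpkm(m3), ids)
  # reference will be a clean column; oracle vs column "c"
  ora <- oracle_tmm_factor(m3[, "c"], m3[, "a"])
  got_ratio <- f3[["c"]] / f3[["a"]]
  expect_equal(unname(got_ratio), ora, tolerance = 0.05)
})

test_that("TMM factors are invariant to gene and sample order", {
  set.seed(12)
  g <- 150
  m <- matrix(exp(stats::rnorm(g * 4, 2, 1)), g, 4,
              dimnames = list(sprintf("g%03d", 1:g), paste0("s", 1:4)))
  ids <- rownames(m)
  f <- tmm_factors(make_fpkm(m), ids)
  pg <- sample(g); ps <- sample(4)
  f_perm <- tmm_factors(make_fpkm(m[pg, ps]), ids)
  expect_equal(f_perm[names(f)], f, tolerance = 1e-12)
})

test_that("tmm_factors errors with too few usable single-copy genes", {
  m <- matrix(1, 10, 2, dimnames = list(paste0("g", 1:10), c("a", "b")))
  expect_error(tmm_factors(make_fpkm(m), paste0("g", 1:10),
                           min_genes = 20), "fewer than 20")
})

test_that("log transform is log2(x+1) and guards its domain", {
  m <- matrix(c(0, 1, 15, 3), 2, 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  lt <- log_transform(expression_table(m, "TPM"))
  expect_equal(unname(lt[1, 1]), 0)
  expect_equal(unname(lt[2, 1]), 1)
  expect_equal(unname(lt[1, 2]), 4)
  expect_equal(expr_metric(lt), "log-TPM")
  expect_error(log_transform(lt), "log scale")
  expect_error(expression_table(matrix(-1), "TPM"), "nonnegative")
})

test_that("curation keeps clean data, removes exactly the planted project,
          flags lost organs, and is idempotent", {
  truth <- fixture_truth(seed = 21)
  clean <- simulate_samples(truth, sample_sim_params(
    projects_per_organ = 5, samples_per_project = 2,
    project_effect_sd = 0.1, noise_sd = 0.2, seed = 31))
  tab <- log_transform(clean$tpm)
  rep_clean <- iterative_removal(tab, clean$meta)
  expect_length(rep_clean$iterations, 0)
  expect_equal(rep_clean$kept_samples, clean$meta$sample_id)
  # planted organ-shuffled project among 5 projects
  bad <- simulate_samples(truth, sample_sim_params(
    projects_per_organ = 5, samples_per_project = 2,
    project_effect_sd = 0.1, noise_sd = 0.2,
    n_anomalous_projects = 1, seed = 32))
  tab_b <- log_transform(bad$tpm)
  rep_bad <- iterative_removal(tab_b, bad$meta)
  removed <- vapply(rep_bad$iterations, `[[`, "", "removed_project_id")
  expect_equal(removed, bad$truth$anomalous_projects)
  # idempotence
  keep <- bad$meta$sample_id %in% rep_bad$kept_samples
  rep2 <- iterative_removal(
    expression_table(tab_b[, keep, drop = FALSE], "log-TPM"),
    bad$meta[keep, , drop = FALSE])
  expect_length(rep2$iterations, 0)
  # fewer than 2 projects -> skipped
  one <- bad$meta$project_id == bad$meta$project_id[1]
  rep_one <- iterative_removal(
    expression_table(tab_b[, one, drop = FALSE], "log-TPM"),
    bad$meta[one, , drop = FALSE])
  expect_true(rep_one$skipped)
})

test_that("SVA correction: no batch -> usually 0 SVs; planted batch is
          detected and within-organ cross-project correlation improves
          while organ F-statistics are preserved", {
  truth <- fixture_truth(n_genes = 120, seed = 22)
  # null calibration (a scaled-down replicate set) on clean log-scale
  # tables: organ means plus i.i.d. noise and no batch structure. (The
  # unlog/relog round trip through nonnegative expression clamps
  # low-expressed genes at zero, which is real shared structure, not a
  # selection false positive.)
  meta0 <- simulate_samples(truth, sample_sim_params(
    projects_per_organ = 4, samples_per_project = 2, seed = 99))$meta
  n_sv_null <- vapply(1:20, function(i) {
    set.seed(4200 + i)
    vals <- truth[, meta0$organ] +
      matrix(stats::rnorm(nrow(truth) * nrow(meta0), 0, 0.4),
             nrow(truth), nrow(meta0))
    colnames(vals) <- meta0$sample_id
    tab <- expression_table(vals, "log-TPM")
    sva_correct(tab, meta0, seed = i)$model$n_sv
  }, 0L)
  expect_gte(mean(n_sv_null == 0), 0.9)
  # strong planted batch
  s <- simulate_samples(truth, sample_sim_params(
    projects_per_organ = 4, samples_per_project = 2,
    project_effect_sd = 2, noise_sd = 0.4, seed = 200))
  tab <- log_transform(s$tpm)
  sv <- sva_correct(tab, s$meta, seed = 3)
  expect_gte(sv$model$n_sv, 1)
  cross_proj_cor <- function(x) {
    vals <- c()
    for (o in organs()) {
      cols <- which(s$meta$organ == o)
      for (i in cols) for (j in cols) {
        if (i < j && s$meta$project_id[i] != s$meta$project_id[j]) {
          vals <- c(vals, stats::cor(x[, i], x[, j]))
        }
      }
    }
    stats::median(vals)
  }
  expect_gt(cross_proj_cor(sv$table), cross_proj_cor(tab))
  # organ effects protected: per-gene fitted organ means nearly unchanged
  # (the correction removes residual variance, so raw F statistics rise;
  # the protected quantity is the organ-mean profile)
  organ_profile <- function(x) {
    t(vapply(seq_len(nrow(x)), function(g)
      tapply(x[g, ], s$meta$organ, mean), numeric(6)))
  }
  prof_before <- organ_profile(tab); prof_after <- organ_profile(sv$table)
  dev <- abs(prof_after - prof_before)
  spread <- apply(prof_before, 1, function(z) diff(range(z)))
  expect_lt(stats::median(apply(dev, 1, max) / spread), 0.05)
  # and F statistics do not deflate (organ signal is not removed)
  organ_f <- function(x) {
    vapply(seq_len(nrow(x)), function(g) {
      fit <- stats::aov(x[g, ] ~ factor(s$meta$organ))
      summary(fit)[[1]]$`F value`[1]
    }, 0)
  }
  expect_gt(stats::median(organ_f(sv$table) / organ_f(tab)), 0.95)
  # SV orthogonality
  if (sv$model$n_sv > 1) {
    g_mat <- crossprod(sv$model$sv_matrix)
    expect_lt(max(abs(g_mat[row(g_mat) != col(g_mat)])), 1e-8)
  }
})

test_that("organ means average correctly and flag missing organs", {
  m <- matrix(c(1, 2, 3, 5, 4, 6), 1, 6)
  rownames(m) <- "g1"
  colnames(m) <- paste0("s", 1:6)
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     project_id = "p1", species = "sp01",
                     organ = c("brain", "brain", "heart", "heart",
                               "kidney", "kidney"))
  om <- organ_means(expression_table(m, "log-TPM"), meta)
  expect_equal(unname(om[1, "brain"]), 1.5)
  expect_equal(unname(om[1, "heart"]), 4)
  expect_equal(sort(attr(om, "missing_organs")),
               c("liver", "ovary", "testis"))
  # single sample -> mean equals it
  expect_equal(unname(om[1, "kidney"]), 5)
})

test_that("subsampling means converge: k = #projects gives the full mean,
          k = 1 gives one value per project, variance non-increasing", {
  truth <- fixture_truth(seed = 23)
  s <- simulate_samples(truth, sample_sim_params(
    projects_per_organ = 5, samples_per_project = 2,
    project_effect_sd = 0.5, noise_sd = 0.5, seed = 41))
  tab <- log_transform(s$tpm)
  sc <- subsample_convergence(tab, s$meta, "g001", "brain", k_range = 1:5)
  expect_length(sc[["5"]], 1)
  full_mean <- mean(tab["g001", s$meta$organ == "brain"])
  expect_equal(sc[["5"]], full_mean)
  expect_length(sc[["1"]], 5)
  # law of large numbers: subset-mean variance non-increasing over seeds
  vars <- sapply(1:10, function(i) {
    ss <- simulate_samples(truth, sample_sim_params(
      projects_per_organ = 6, samples_per_project = 2,
      project_effect_sd = 0.5, noise_sd = 0.5, seed = 500 + i))
    tt <- log_transform(ss$tpm)
    con <- subsample_convergence(tt, ss$meta, "g001", "brain", c(1, 3, 5))
    vapply(con, stats::var, 0)
  })
  avg <- rowMeans(vars)
  expect_true(all(diff(avg) <= 0))
  # k beyond the project count is skipped
  expect_null(subsample_convergence(tab, s$meta, "g001", "brain",
                                    k_range = 9)[["9"]])
})

test_that("full amalgamation recovers truth organ means increasingly well
          with more samples, and TMM equalizes library factors", {
  truth <- fixture_truth(n_genes = 60, seed = 24)
  rmse <- vapply(c(2, 8, 32), function(nspp) {
    s <- simulate_samples(truth, sample_sim_params(
      projects_per_organ = 2, samples_per_project = nspp / 2,
      project_effect_sd = 0.3, noise_sd = 0.6,
      libsize_lognormal_sd = 0.4, seed = 600 + nspp))
    am <- amalgamate(s, seed = 5)
    est <- am$fpkm$means[rownames(truth), organs()]
    sqrt(mean((est - truth)^2))
  }, 0)
  expect_true(all(diff(rmse) < 0))
  # raw FPKM column sums differ; TMM-corrected single-copy profiles align
  s <- simulate_samples(truth, sample_sim_params(
    projects_per_organ = 3, samples_per_project = 2,
    project_effect_sd = 0, noise_sd = 0, libsize_lognormal_sd = 0.5,
    seed = 700))
  expect_gt(stats::sd(colSums(s$fpkm)) / mean(colSums(s$fpkm)), 0.05)
  f <- tmm_factors(s$fpkm, rownames(truth))
  corrected <- apply_tmm(s$fpkm, f)
  same_organ <- which(s$meta$organ == "brain")
  pos <- corrected[, same_organ[1]] > 0 & corrected[, same_organ[2]] > 0
  ratio <- corrected[pos, same_organ[1]] / corrected[pos, same_organ[2]]
  expect_equal(unname(stats::median(ratio)), 1, tolerance = 0.02)
})
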
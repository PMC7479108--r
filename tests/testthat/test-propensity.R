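# Expression metrics and downstream statistics.

test_that("tau hits its analytic endpoints and scales correctly", {
  expect_equal(tau(c(5, 5, 5, 5, 5, 5)), 0)
  expect_equal(tau(c(8, 0, 0, 0, 0, 0)), 1)
  expect_equal(tau(c(4, 2, 0, 0, 0, 0)), 0.9)
  # scale invariance
  set.seed(1)
  for (i in 1:20) {
    v <- stats::runif(6, 0, 50)
    expect_equal(tau(v), tau(v * stats::runif(1, 0.1, 10)))
    expect_gte(tau(v), 0); expect_lte(tau(v), 1)
  }
  expect_warning(expect_true(is.na(tau(rep(0, 6)))), "undefined")
})

test_that("tec hits its endpoints, is symmetric, and stays in [0,1]", {
  expect_equal(tec(c(1, 1, 0, 0, 0, 0), c(1, 1, 0, 0, 0, 0)), 0)
  expect_equal(tec(c(1, 0, 0, 0, 0, 0), c(0, 1, 0, 0, 0, 0)), 1)
  expect_equal(tec(c(.5, .5, 0, 0, 0, 0), c(.5, 0, .5, 0, 0, 0)), 0.5)
  set.seed(2)
  for (i in 1:20) {
    a <- stats::runif(6); b <- stats::runif(6)
    expect_equal(tec(a, b), tec(b, a))
    expect_gte(tec(a, b), 0); expect_lte(tec(a, b), 1)
  }
  expect_warning(expect_true(is.na(tec(rep(0, 6), c(1, rep(0, 5))))),
                 "undefined")
})

test_that("peo picks the top organ and refuses ties", {
  expect_equal(peo(c(brain = 3, heart = 1, kidney = 0, liver = 0,
                     ovary = 0, testis = 2)), "brain")
  expect_true(is.na(peo(c(2, 2, 0, 0, 0, 0))))
})

test_that("brunner_munzel matches the independent placement oracle", {
  set.seed(3)
  x <- stats::rnorm(10); y <- stats::rnorm(10, 0.8)
  got <- brunner_munzel(x, y)
  ora <- oracle_brunner_munzel(x, y)
  expect_equal(got$statistic, ora$statistic, tolerance = 1e-10)
  expect_equal(got$df, ora$df, tolerance = 1e-10)
  expect_equal(got$p_value, ora$p_value, tolerance = 1e-10)
  expect_equal(got$relative_effect, ora$relative_effect,
               tolerance = 1e-10)
  # with ties
  xt <- c(1, 1, 2, 3, 3, 4, 5, 5, 6, 7)
  yt <- c(2, 2, 3, 4, 4, 5, 6, 6, 7, 8)
  got_t <- brunner_munzel(xt, yt)
  ora_t <- oracle_brunner_munzel(xt, yt)
  expect_equal(got_t$statistic, ora_t$statistic, tolerance = 1e-10)
  # identical distributions -> relative effect 0.5
  expect_equal(brunner_munzel(1:50, 1:50)$relative_effect, 0.5)
  # complete separation at n = 50/50
  sep <- brunner_munzel(stats::rnorm(50), stats::rnorm(50) + 100)
  expect_equal(sep$relative_effect, 1)
  expect_lt(sep$p_value, 0.001)
})

test_that("transition_matrix counts switches with a zero diagonal", {
  rec <- data.frame(category = c("S", "S", "S", "S", "S"),
                    peo_anc = c("brain", "brain", "brain", "testis",
                                "heart"),
                    peo_der = c("testis", "testis", "testis", "brain",
                                "heart"),
                    peo_switch = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  m <- transition_matrix(rec, "S")
  expect_equal(m["brain", "testis"], 3L)
  expect_equal(m["testis", "brain"], 1L)
  expect_equal(sum(m), 4L)
  expect_true(all(diag(m) == 0))
  empty <- transition_matrix(rec[0, , drop = FALSE])
  expect_equal(sum(empty), 0L)
  # identical matrices -> Spearman rho = 1
  cmp <- compare_transition_matrices(list(S = m, D = m))
  expect_equal(unname(cmp$spearman[[1]]$estimate), 1)
})

test_that("polarity endpoints and the direct 3-vs-1 example hold", {
  m <- matrix(0L, 6, 6, dimnames = list(organs(), organs()))
  m["brain", "testis"] <- 3L; m["testis", "brain"] <- 3L
  expect_equal(polarity(m)$polarity, 0)
  m2 <- matrix(0L, 6, 6, dimnames = list(organs(), organs()))
  m2["brain", "testis"] <- 5L; m2["kidney", "liver"] <- 2L
  expect_equal(polarity(m2)$polarity, 1)
  m3 <- matrix(0L, 6, 6, dimnames = list(organs(), organs()))
  m3["brain", "heart"] <- 3L; m3["heart", "brain"] <- 1L
  expect_equal(polarity(m3)$polarity, 0.5)
})

test_that("polarity is invariant under organ relabeling", {
  set.seed(4)
  m <- matrix(rpois(36, 3), 6, 6, dimnames = list(organs(), organs()))
  diag(m) <- 0L
  for (i in 1:5) {
    p <- sample(6)
    expect_equal(polarity(m)$polarity, polarity(m[p, p])$polarity)
  }
})

test_that("permutation nulls preserve margins and flag extremes", {
  rec <- data.frame(category = "S",
                    peo_anc = rep(c("brain", "testis", "kidney"),
                                  c(20, 15, 10)),
                    peo_der = rep(c("testis", "brain", "liver"),
                                  c(20, 15, 10)),
                    peo_switch = TRUE)
  m <- transition_matrix(rec, "S")
  cfg <- stats_config(n_perm = 200, seed = 5)
  en <- permutation_enrichment(m, cfg)
  expect_true(all(is.na(diag(en$p))))
  off <- en$p[row(en$p) != col(en$p)]
  expect_true(all(off >= 0 & off <= 1, na.rm = TRUE))
  # one-directional concentration with balanced margins -> minimal p
  m1 <- matrix(0L, 6, 6, dimnames = list(organs(), organs()))
  m1["brain", "testis"] <- 30L; m1["testis", "brain"] <- 30L
  m1["kidney", "liver"] <- 30L; m1["liver", "kidney"] <- 30L
  attr(m1, "category") <- "S"
  en1 <- permutation_enrichment(m1, stats_config(n_perm = 400, seed = 6))
  expect_lte(en1$p["brain", "testis"], 2 / 401)
  cfg0 <- stats_config(n_perm = 5)
  cfg0$n_perm <- 0L
  expect_error(permutation_enrichment(m, cfg0), "n_perm")
  # margins preserved by the permutation pairing itself
  anc <- rep(rep(organs(), 6), times = as.vector(m))
  der <- rep(rep(organs(), each = 6), times = as.vector(m))
  set.seed(7)
  for (i in 1:10) {
    perm <- der[sample.int(length(der))]
    expect_equal(table(factor(perm, organs())),
                 table(factor(der, organs())))
    expect_equal(table(factor(anc, organs())),
                 table(factor(anc, organs())))
  }
})

test_that("omega_analysis recovers a planted TEC slope and handles the
          degenerate equal-omega case", {
  set.seed(8)
  n <- 500
  tec_v <- stats::runif(n)
  lr <- 0.8 * tec_v + stats::rnorm(n, 0, 0.4)  # planted positive slope
  om_minus <- exp(stats::rnorm(n, -2, 0.3))
  rec <- data.frame(family_id = "f", branch = paste0("b", 1:n),
                    category = "S",
                    tau_anc = 0.5, tau_der = 0.6, d_tau = 0.1,
                    mu_max_anc = 4, mu_max_der = 5, d_mu_max = 1,
                    tec = tec_v, peo_anc = "brain", peo_der = "testis",
                    peo_switch = TRUE, peo_tied = FALSE,
                    sister = "s", sister_shifted = FALSE,
                    omega_shift = om_minus * 2^lr,
                    omega_sister = om_minus,
                    bootstrap_support = NA_real_)
  oa <- omega_analysis(rec)
  tec_row <- oa$regressions[oa$regressions$term == "S:tec", ]
  expect_gt(tec_row$slope, 0)
  expect_lt(tec_row$p_value, 0.05)
  # omega+ == omega- -> everything undifferentiated, slopes ~ 0
  rec2 <- rec
  rec2$omega_shift <- rec2$omega_sister
  oa2 <- omega_analysis(rec2)
  expect_equal(unname(oa2$classification["undifferentiated"]), n)
  tec2 <- oa2$regressions[oa2$regressions$term == "S:tec", ]
  expect_equal(tec2$slope, 0, tolerance = 1e-10)
  # a regression with < 3 points is flagged, no p reported
  rec3 <- rec[1:2, ]
  oa3 <- omega_analysis(rec3)
  expect_true(all(oa3$regressions$insufficient[
    oa3$regressions$term == "S:tec"]))
})

test_that("stationary-variance comparison pools reproductive organs and
          applies the Brunner-Munzel test (permutation fallback flagged
          at small n)", {
  mock_model <- function(gamma6) {
    list(organ_params = data.frame(organ = organs(), gamma = gamma6))
  }
  set.seed(42)
  # 20 trees: reproductive gammas systematically higher
  models <- lapply(1:20, function(i) {
    g <- c(stats::rlnorm(4, 0, 0.2), stats::rlnorm(2, 1, 0.2))
    mock_model(g)
  })
  sv <- stationary_variance_compare(models)
  expect_false(sv$fallback)
  expect_lt(sv$test$p_value, 0.01)
  expect_gt(sv$test$relative_effect, 0.5)  # P(other < repro) high
  expect_equal(nrow(sv$gamma), 120)
  # small n triggers the flagged permutation fallback
  sv2 <- stationary_variance_compare(models[1:2])
  expect_true(sv2$fallback)
  expect_true(is.numeric(sv2$test$p_value))
  # KS comparison of polarity bootstrap distributions
  mkpol <- function(center) list(polarity = center,
                                 bootstrap = stats::rnorm(200, center,
                                                          0.02),
                                 n_records = 100)
  ks <- polarity_ks(list(S = mkpol(0.2), D = mkpol(0.2),
                         R = mkpol(0.6)))
  expect_equal(nrow(ks), 3)
  expect_lt(ks$p_value[ks$a == "S" & ks$b == "R"], 0.001)
})

test_that("expressed-gene normalization preserves totals and undoes a
          pure pool-size bias", {
  m <- matrix(0L, 6, 6, dimnames = list(organs(), organs()))
  m["brain", "testis"] <- 40L; m["kidney", "liver"] <- 10L
  counts <- stats::setNames(c(2, 1, 1, 1, 1, 2), organs())
  nm <- normalize_transitions(m, counts)
  expect_equal(sum(nm), sum(m))
  # the brain-testis cell was inflated 4x by pool sizes; after
  # normalization the two flows are equal
  expect_equal(unname(nm["brain", "testis"]), unname(nm["kidney",
                                                        "liver"]))
  # equal pools leave the matrix unchanged
  nm2 <- normalize_transitions(m, stats::setNames(rep(3, 6), organs()))
  expect_equal(unname(nm2), unname(unclass(m) * 1))
})

test_that("shift_rates computes frequencies, per-MY rates and the chi2
          test", {
  census <- data.frame(category = rep(c("S", "D", "R"), c(100, 20, 5)),
                       duration = c(rep(10, 100), rep(10, 20), rep(10, 5)))
  rec <- data.frame(category = rep(c("S", "D"), c(10, 4)))
  sr <- shift_rates(rec, census)
  s_row <- sr$table[sr$table$category == "S", ]
  expect_equal(s_row$frequency, 0.1)
  expect_equal(s_row$rate_per_my, 10 / 1000)
  r_row <- sr$table[sr$table$category == "R", ]
  expect_equal(r_row$frequency, 0)
  expect_equal(r_row$rate_per_my, 0)
  expect_s3_class(sr$chisq, "htest")
})

test_that("robustness_subsets with zero thresholds reproduces the full
          analysis and empty subsets are skipped", {
  set.seed(9)
  n <- 80
  rec <- data.frame(family_id = "f", branch = paste0("b", 1:n),
                    category = "S",
                    tau_anc = 0.4, tau_der = stats::runif(n),
                    d_tau = 0, mu_max_anc = 4, mu_max_der = 4,
                    d_mu_max = 0, tec = 0.5,
                    peo_anc = sample(organs(), n, TRUE),
                    peo_der = sample(organs(), n, TRUE),
                    peo_switch = NA, peo_tied = FALSE, sister = "s",
                    sister_shifted = FALSE, omega_shift = 0.1,
                    omega_sister = 0.1, bootstrap_support = 1)
  rec$peo_switch <- rec$peo_anc != rec$peo_der
  cfg <- stats_config(n_perm = 100, n_boot = 50, seed = 10)
  rs0 <- robustness_subsets(rec, cfg, tau_min = 0, bootstrap_min = 0)
  expect_false(rs0$skipped)
  expect_equal(rs0$filtered$matrix, rs0$full$matrix)
  rs_empty <- robustness_subsets(rec, cfg, tau_min = 2)
  expect_true(rs_empty$skipped)
})
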
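test_that("intra_inter recovers diagonal and row means, globally and within folds", {
  expect_equal(intra_inter(diag(3))$r_intra, rep(1, 3))
  expect_equal(intra_inter(diag(3))$r_inter, rep(0, 3))

  const <- matrix(0.7, 4, 4)
  tab <- intra_inter(const)
  expect_equal(tab$r_intra, rep(0.7, 4))
  expect_equal(tab$r_inter, rep(0.7, 4))

  S <- withr::with_seed(31, matrix(runif(100), 10, 10))
  folds <- fold_partition(rep(1:2, each = 5))
  tab <- intra_inter(S, folds, scope = "within_fold")
  for (i in 1:10) {
    k <- folds$assignment[i]
    members <- setdiff(which(folds$assignment == k), i)
    expect_equal(tab$r_inter[i], mean(S[i, members]), tolerance = 1e-12)
    expect_equal(tab$r_intra[i], S[i, i])
  }
  g <- intra_inter(S)
  for (i in 1:10) expect_equal(g$r_inter[i], mean(S[i, -i]), tolerance = 1e-12)
  expect_error(intra_inter(S, fold_partition(c(rep(1, 9), 2)), "within_fold"),
               class = "fcbench_error_degenerate_fold")
})

test_that("naive test matches the hand-computed one-sample t and its conventions", {
  d <- c(0.1, 0.2, 0.3, 0.2)
  res <- naive_identifiability_test(d, rep(0, 4))
  t_hand <- mean(d) / (stats::sd(d) / sqrt(4))
  expect_equal(res$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$p_value, stats::pt(t_hand, 3, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_identical(res$df, 3L)
  expect_equal(res$cohen_d, mean(d) / stats::sd(d), tolerance = 1e-12)

  # all differences zero -> t = 0, one-tailed p = 0.5, flagged degenerate
  res0 <- naive_identifiability_test(rep(0.4, 5), rep(0.4, 5))
  expect_identical(res0$t_statistic, 0)
  expect_identical(res0$p_value, 0.5)
  expect_true(res0$degenerate)

  # df convention: N subjects -> df = N - 1
  big <- naive_identifiability_test(seq_len(1000) / 1000, rep(0, 1000))
  expect_identical(big$df, 999L)

  # distance direction flips the differences: perfect predictions still reject
  resd <- naive_identifiability_test(rep(0, 4) + c(0, .01, -.01, 0), d,
                                     direction = "lower_is_more_similar")
  expect_gt(resd$t_statistic, 0)
  expect_lt(resd$p_value, 0.05)

  expect_error(naive_identifiability_test(c(1, 2), c(0, 0)),
               class = "fcbench_error_dimension")
})

test_that("tidy/glance expose the identifiability result as tibbles", {
  co <- make_cohort(N = 6, p = 5, K = 2, seed = 32)
  sim <- build_similarity(co$pfc, co$efc, "pearson")
  res <- naive_identifiability_test(intra_inter(sim, co$folds))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 6L)
  expect_equal(td$difference, td$r_intra - td$r_inter)
  gl <- glance(res)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$method, "naive_t")
})

test_that("fold-constrained permutation p matches exhaustive enumeration and is deterministic", {
  co <- make_cohort(N = 6, p = 6, K = 2, seed = 33)
  S <- build_similarity(co$pfc, co$efc, "pearson")$values
  folds <- fold_partition(c(1, 1, 1, 2, 2, 2))
  N <- 6
  rs <- rowSums(S)
  t_of <- function(colperm) {
    dg <- S[cbind(1:N, colperm)]
    d <- dg - (rs - dg) / (N - 1)
    mean(d) / (stats::sd(d) / sqrt(N))
  }
  t_obs <- t_of(1:6)
  tp <- numeric(0)
  for (qa in all_perms(3)) for (qb in all_perms(3)) {
    tp <- c(tp, t_of(c(qa, qb + 3L)))
  }
  p_exact <- mean(tp >= t_obs - 1e-12)

  res <- fold_constrained_permutation_test(S, folds, n_perm = 4000, seed = 2)
  expect_lt(abs(res$p_value - p_exact), 0.02)
  expect_equal(res$t_observed, t_obs, tolerance = 1e-12)
  expect_true(res$p_ci_95[1] <= res$p_value && res$p_value <= res$p_ci_95[2])

  # determinism and degenerate constant-block null
  res2 <- fold_constrained_permutation_test(S, folds, n_perm = 500, seed = 9)
  expect_identical(res2$p_value,
                   fold_constrained_permutation_test(S, folds, 500, seed = 9)$p_value)
  Sc <- matrix(0.2, 6, 6)
  Sc[1:3, 1:3] <- 0.5
  expect_identical(
    fold_constrained_permutation_test(Sc, folds, n_perm = 200, seed = 1)$p_value, 1)
  expect_error(fold_constrained_permutation_test(S, folds, n_perm = 10),
               class = "fcbench_error_nperm")
})

test_that("naive and permutation p-values track each other across cohorts", {
  # the two tests estimate the same tail but from different null models; they
  # need not agree pointwise in the body, but must rank cohorts identically
  pn <- pp <- numeric(10)
  for (r in 1:10) {
    spec <- synthetic_spec(n_subjects = 40, n_nodes = 15, t_samples = 60,
                           alpha = 0.1, beta = (r %% 2) * 0.3, K = 2,
                           seed = 300 + r)
    gen <- generate_cohort(spec)
    sim <- build_similarity(gen$cohort$pfc, gen$cohort$efc, "pearson")
    pn[r] <- naive_identifiability_test(intra_inter(sim, gen$cohort$folds))$p_value
    pp[r] <- fold_constrained_permutation_test(sim, gen$cohort$folds,
                                               n_perm = 400, seed = r)$p_value
  }
  expect_gt(stats::cor(pn, pp, method = "spearman"), 0.9)
})

test_that("corrected resampled t matches the hand formula, df and antisymmetry", {
  mk <- function(vals) {
    tibble::tibble(
      fold = rep(seq_along(vals), each = 3),
      subject_id = as.character(seq_len(3 * length(vals))),
      delta = rep(vals, each = 3)
    )
  }
  zero <- mk(c(0, 0, 0))
  model <- mk(c(0.1, 0.2, 0.3))
  res <- corrected_resampled_t(model, zero, n_test = 10, n_train = 90)
  t_hand <- 0.2 / sqrt((1 / 3 + 10 / 90) * stats::var(c(0.1, 0.2, 0.3)))
  expect_equal(res$t_statistic, t_hand, tolerance = 1e-12)
  expect_identical(res$df, 2L)
  expect_equal(res$p_value, stats::pt(t_hand, 2, lower.tail = FALSE),
               tolerance = 1e-12)

  # identical deltas -> t = 0, p = 0.5
  same <- corrected_resampled_t(model, model, 10, 90)
  expect_identical(same$t_statistic, 0)
  expect_identical(same$p_value, 0.5)
  expect_true(same$degenerate)

  # antisymmetry: swapping model and benchmark negates t
  swapped <- corrected_resampled_t(zero, model, 10, 90)
  expect_equal(swapped$t_statistic, -res$t_statistic, tolerance = 1e-12)

  # K = 10 folds -> df = 9
  ten <- corrected_resampled_t(mk(seq(0.01, 0.1, by = 0.01)), mk(rep(0, 10)),
                               100, 900)
  expect_identical(ten$df, 9L)

  # median vs mean summaries differ when fold distributions are skewed
  skew <- tibble::tibble(fold = rep(1:3, each = 3),
                         subject_id = as.character(1:9),
                         delta = c(0, 0, 9, 0, 0, 9, 0, 0, 9))
  base <- tibble::tibble(fold = rep(1:3, each = 3),
                         subject_id = as.character(1:9), delta = rep(0, 9))
  med <- corrected_resampled_t(skew, base, 3, 6, f = "median")
  mea <- corrected_resampled_t(skew, base, 3, 6, f = "mean")
  expect_identical(med$fold_summaries$s, rep(0, 3))
  expect_equal(mea$fold_summaries$s, rep(3, 3))
})

test_that("fold deltas come from the within-fold submatrix with direction applied", {
  co <- make_cohort(N = 6, p = 5, K = 2, seed = 35)
  sim <- build_similarity(co$pfc, co$efc, "pearson", subject_ids = co$subject_ids)
  fd <- fold_deltas(sim, co$folds)
  wf <- intra_inter(sim, co$folds, scope = "within_fold")
  expect_equal(fd$delta, wf$r_intra - wf$r_inter, tolerance = 1e-12)

  siml <- build_similarity(co$pfc, co$efc, "lerm", subject_ids = co$subject_ids)
  fdl <- fold_deltas(siml, co$folds)
  wfl <- intra_inter(siml, co$folds, scope = "within_fold")
  expect_equal(fdl$delta, wfl$r_inter - wfl$r_intra, tolerance = 1e-12)
})

test_that("per-fold bootstrap bounds behave on constant, signed and random differences", {
  mk2 <- function(d1, d2) {
    tibble::tibble(fold = rep(1:2, each = length(d1)),
                   subject_id = as.character(seq_len(2 * length(d1))),
                   delta = c(d1, d2))
  }
  base <- mk2(rep(0, 6), rep(0, 6))
  # constant +0.5 differences: lower bound exactly 0.5, significant
  res <- fold_bootstrap_comparison(mk2(rep(0.5, 6), rep(-0.2, 6)), base,
                                   n_boot = 1000, seed = 3)
  expect_equal(res$lower_bound[1], 0.5)
  expect_true(res$significant[1])
  expect_false(res$significant[2])
  expect_identical(attr(res, "n_significant"), 1L)

  # determinism
  d <- withr::with_seed(4, mk2(rnorm(8, 0.2), rnorm(8)))
  r1 <- fold_bootstrap_comparison(d, mk2(rep(0, 8), rep(0, 8)),
                                  n_boot = 1500, seed = 11)
  r2 <- fold_bootstrap_comparison(d, mk2(rep(0, 8), rep(0, 8)),
                                  n_boot = 1500, seed = 11)
  expect_identical(r1$lower_bound, r2$lower_bound)

  # differences symmetric around zero should not be flagged
  sym <- mk2(c(-3, -2, -1, 1, 2, 3) / 10, c(-3, -1, 0, 0, 1, 3) / 10)
  rs <- fold_bootstrap_comparison(sym, base, n_boot = 1000, seed = 5)
  expect_false(any(rs$significant))

  expect_error(
    fold_bootstrap_comparison(mk2(rep(1, 6), rep(1, 6)), base, n_boot = 10),
    class = "fcbench_error_nboot"
  )
})

test_that("percent improvement and differential identifiability arithmetic", {
  expect_equal(percent_improvement(0.5, 0.5), 0)
  expect_equal(percent_improvement(0.5, 0.25), 50)
  expect_equal(percent_improvement(0.547, 0.477), (0.547 - 0.477) / 0.547 * 100)
  expect_error(percent_improvement(0, 0.2), class = "fcbench_error_zero_model")

  S <- matrix(0.2, 4, 4); diag(S) <- 0.6
  expect_equal(differential_identifiability(S), 0.4, tolerance = 1e-12)
})
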
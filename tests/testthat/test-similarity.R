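test_that("vectorize_offdiag extracts the strict upper triangle in row-major order", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- 10; m[1, 3] <- 20; m[2, 3] <- 30
  m <- m + t(m)
  expect_identical(vectorize_offdiag(m), c(10, 20, 30))
  expect_length(vectorize_offdiag(diag(68)), 2278L)  # p = 68 feature count
  s <- rand_corr_fixture(6, seed = 3)
  expect_identical(vectorize_offdiag(s), vectorize_offdiag(t(s)))
  expect_error(vectorize_offdiag(matrix(1, 2, 3)), class = "fcbench_error_dimension")
})

test_that("pearson_similarity matches the textbook formula and its edge cases", {
  a <- rand_corr_fixture(4, seed = 1)
  b <- rand_corr_fixture(4, seed = 2)
  # independent oracle: explicit Pearson formula on the 6 off-diagonal values
  x <- vectorize_offdiag(a); y <- vectorize_offdiag(b)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_similarity(a, b), r_hand, tolerance = 1e-12)

  expect_equal(pearson_similarity(a, a), 1)
  flip <- matrix(0, 3, 3)
  flip[upper.tri(flip)] <- c(1, 2, 3)
  flip <- flip + t(flip)
  anti <- -flip
  expect_equal(pearson_similarity(flip, anti), -1)
  expect_error(pearson_similarity(diag(3), a[1:3, 1:3]),
               class = "fcbench_error_zero_variance")
})

test_that("pearson_similarity is invariant to positive affine rescaling (property)", {
  for (s in 1:10) {
    a <- rand_corr_fixture(5, seed = s)
    b <- rand_corr_fixture(5, seed = s + 100)
    a2 <- 2.5 * a + 0.3
    expect_equal(pearson_similarity(a2, b), pearson_similarity(a, b),
                 tolerance = 1e-10)
    r <- pearson_similarity(a, b)
    expect_true(r >= -1 && r <= 1)
  }
})

test_that("masked_pearson restricts to the mask and reduces to the unmasked case", {
  a <- rand_corr_fixture(4, seed = 4)
  b <- rand_corr_fixture(4, seed = 5)
  all_true <- matrix(TRUE, 4, 4)
  expect_equal(masked_pearson(a, b, all_true), pearson_similarity(a, b))

  mask <- matrix(FALSE, 4, 4)
  mask[1, 2] <- mask[1, 4] <- mask[3, 4] <- TRUE
  mask <- mask | t(mask)
  x <- c(a[1, 2], a[1, 4], a[3, 4]); y <- c(b[1, 2], b[1, 4], b[3, 4])
  expect_equal(masked_pearson(a, b, mask), stats::cor(x, y), tolerance = 1e-12)

  mask2 <- matrix(FALSE, 4, 4)
  mask2[1, 2] <- mask2[3, 4] <- TRUE
  expect_error(masked_pearson(a, b, mask2 | t(mask2)),
               class = "fcbench_error_mask")
})

test_that("spd_project clips the spectrum and is idempotent on well-conditioned SPD input", {
  spd <- rand_spd(5, seed = 1)
  expect_lt(max(abs(spd_project(spd) - spd)), 1e-10)

  clipped <- spd_project(diag(c(2, -1)), floor = 1e-6)
  expect_equal(sort(eigen(clipped, symmetric = TRUE)$values),
               c(2e-6, 2), tolerance = 1e-12)

  for (s in 1:5) {
    ind <- withr::with_seed(s, {
      A <- matrix(rnorm(25), 5, 5); (A + t(A)) / 2
    })
    out <- spd_project(ind, floor = 1e-6)
    ev <- eigen(out, symmetric = TRUE)$values
    expect_gte(min(ev), 1e-6 * max(ev) - 1e-12)  # up to reconstruction roundoff
    expect_lt(max(abs(out - t(out))), 1e-12)
  }
  expect_error(spd_project(matrix(1:4, 2, 2)), class = "fcbench_error_symmetry")
})

test_that("lerm_distance matches closed forms and the eigendecomposition oracle", {
  A <- rand_spd(4, seed = 2)
  expect_equal(lerm_distance(A, A), 0)
  # Log(I) = 0 and Log(e I) = I, so the distance is sqrt(p)
  expect_equal(lerm_distance(diag(3), exp(1) * diag(3)), sqrt(3),
               tolerance = 1e-12)
  for (s in 1:10) {
    A <- rand_spd(5, seed = s)
    B <- rand_spd(5, seed = s + 50)
    expect_equal(lerm_distance(A, B), lerm_oracle(A, B), tolerance = 1e-10)
  }
  expect_error(lerm_distance(diag(c(1, -1, 1)), diag(3)),
               class = "fcbench_error_not_spd")
})

test_that("build_similarity agrees with the naive double loop for both measures", {
  co <- make_cohort(N = 3, p = 5, K = 2, seed = 9)
  sim <- build_similarity(co$pfc, co$efc, "pearson",
                          subject_ids = co$subject_ids)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(sim$values[i, j],
                 pearson_similarity(co$pfc[, , i], co$efc[, , j]),
                 tolerance = 1e-12)
  }
  expect_identical(sim$direction, "higher_is_more_similar")

  self <- build_similarity(co$efc, co$efc, "pearson")
  expect_equal(unname(diag(self$values)), rep(1, 3))

  siml <- build_similarity(co$pfc, co$efc, "lerm")
  expect_identical(siml$direction, "lower_is_more_similar")
  for (i in 1:3) for (j in 1:3) {
    expect_equal(siml$values[i, j],
                 lerm_distance(spd_project(co$pfc[, , i]),
                               spd_project(co$efc[, , j])),
                 tolerance = 1e-8)
  }
  expect_true(all(siml$values >= 0))
})

test_that("per-prediction nonzero masking applies each row's own SC pattern", {
  co <- make_cohort(N = 3, p = 6, K = 2, seed = 10, with_sc = TRUE)
  sim <- build_similarity(co$sc, co$efc, "pearson",
                          mask_policy = "per_prediction_nonzero")
  for (i in 1:3) {
    mask <- co$sc[, , i] != 0
    for (j in 1:3) {
      expect_equal(sim$values[i, j],
                   masked_pearson(co$sc[, , i], co$efc[, , j], mask),
                   tolerance = 1e-12)
    }
  }
  expect_error(
    build_similarity(co$sc, co$efc, "lerm",
                     mask_policy = "per_prediction_nonzero"),
    class = "fcbench_error_mask"
  )
})

test_that("similarity matrices round-trip through the text + sidecar format", {
  co <- make_cohort(N = 4, p = 5, K = 2, seed = 12)
  sim <- build_similarity(co$pfc, co$efc, "lerm", subject_ids = co$subject_ids)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_similarity(sim, path)
  back <- read_similarity(path)
  expect_equal(unname(back$values), unname(sim$values), tolerance = 1e-12)
  expect_identical(back$measure, "lerm")
  expect_identical(back$direction, "lower_is_more_similar")
  expect_identical(back$subject_ids, co$subject_ids)
})
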
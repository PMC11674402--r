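#' Intra- and inter-individual similarity
#'
#' From the cross-subject similarity matrix, `r_intra(i)` is the diagonal
#' entry (prediction `i` against subject `i`'s own empirical matrix) and
#' `r_inter(i)` the mean of row `i` over the remaining subjects. With
#' `scope = "within_fold"` the average is restricted to the other members of
#' subject `i`'s cross-validation fold, using only the fold's sub-similarity
#' matrix.
#'
#' @param similarity An `fc_similarity` (or plain square matrix).
#' @param folds Fold partition; required for `scope = "within_fold"`.
#' @param scope `"global"` or `"within_fold"`.
#'
#' @return A tibble with columns `subject_id`, `fold`, `r_intra`, `r_inter`.
#' @export
intra_inter <- function(similarity, folds = NULL,
                        scope = c("global", "within_fold")) {
  scope <- match.arg(scope)
  S <- similarity_values(similarity)
  N <- nrow(S)
  ids <- similarity_ids(similarity, N)
  r_intra <- diag(S)
  if (scope == "global") {
    r_inter <- (rowSums(S) - r_intra) / (N - 1)
    fold <- if (is.null(folds)) rep(NA_integer_, N) else folds$assignment
  } else {
    if (is.null(folds)) {
      abort_fcbench("within_fold scope requires a fold partition",
                    class = "fcbench_error_folds")
    }
    if (any(fold_sizes(folds) < 2L)) {
      abort_fcbench("within_fold scope requires every fold size >= 2",
                    class = "fcbench_error_degenerate_fold")
    }
    fold <- folds$assignment
    r_inter <- numeric(N)
    for (k in seq_len(folds$K)) {
      idx <- which(fold == k)
      sub <- S[idx, idx, drop = FALSE]
      r_inter[idx] <- (rowSums(sub) - diag(sub)) / (length(idx) - 1)
    }
  }
  tibble::tibble(subject_id = ids, fold = fold,
                 r_intra = r_intra, r_inter = r_inter)
}

similarity_values <- function(similarity) {
  S <- if (inherits(similarity, "fc_similarity")) similarity$values else similarity
  if (!is.matrix(S) || nrow(S) != ncol(S)) {
    abort_fcbench("similarity must be a square matrix",
                  class = "fcbench_error_dimension")
  }
  S
}

similarity_ids <- function(similarity, N) {
  if (inherits(similarity, "fc_similarity")) similarity$subject_ids
  else as.character(seq_len(N))
}

similarity_direction <- function(similarity, default = "higher_is_more_similar") {
  if (inherits(similarity, "fc_similarity")) similarity$direction else default
}

# signed per-subject differences: positive = prediction favours its own subject
signed_diff <- function(r_intra, r_inter, direction) {
  sign <- if (direction == "lower_is_more_similar") -1 else 1
  sign * (r_intra - r_inter)
}

#' Naive one-sample identifiability test
#'
#' One-tailed one-sample t test of the null hypothesis that the mean of
#' `r_intra(i) - r_inter(i)` is zero, against the alternative that predictions
#' are more similar to their own subject's empirical matrix than to others'.
#' For distance measures (`direction = "lower_is_more_similar"`) the
#' differences are sign-flipped so the alternative is always "better than
#' exchangeable". "Naive" because the test assumes the per-subject
#' differences are independent, which cross-validation can violate; see
#' [fold_constrained_permutation_test()] and [corrected_resampled_t()].
#'
#' @param r_intra,r_inter Aligned numeric vectors (e.g. from [intra_inter()]),
#'   or a single tibble with `r_intra`/`r_inter` columns passed as `r_intra`.
#' @param direction `"higher_is_more_similar"` (correlations) or
#'   `"lower_is_more_similar"` (distances).
#' @param alternative `"one.sided"` (default, the headline convention) or
#'   `"two.sided"`.
#'
#' @return An `fc_identifiability` object; see [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods.
#' @export
naive_identifiability_test <- function(r_intra, r_inter = NULL,
                                       direction = "higher_is_more_similar",
                                       alternative = c("one.sided", "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.data.frame(r_intra)) {
    tab <- r_intra
    r_intra <- tab$r_intra
    r_inter <- tab$r_inter
  }
  N <- length(r_intra)
  if (N < 3L || length(r_inter) != N) {
    abort_fcbench("need aligned r_intra/r_inter vectors with N >= 3",
                  class = "fcbench_error_dimension")
  }
  d <- signed_diff(r_intra, r_inter, direction)
  df <- N - 1L
  sd_d <- stats::sd(d)
  degenerate <- sd_d == 0
  if (degenerate) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 0.5 else if (mean(d) > 0) 0 else 1
    if (alternative == "two.sided" && mean(d) != 0) p <- 0
    if (alternative == "two.sided" && mean(d) == 0) p <- 1
    cohen_d <- NaN
  } else {
    t_stat <- mean(d) / (sd_d / sqrt(N))
    p <- if (alternative == "one.sided") {
      stats::pt(t_stat, df, lower.tail = FALSE)
    } else {
      2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
    }
    cohen_d <- mean(d) / sd_d
  }
  structure(
    list(
      r_intra = r_intra, r_inter = r_inter, scope = "global",
      direction = direction,
      mean_intra = mean(r_intra), mean_inter = mean(r_inter),
      t_statistic = t_stat, p_value = p, df = df,
      cohen_d = cohen_d, method = "naive_t",
      alternative = alternative, degenerate = degenerate
    ),
    class = "fc_identifiability"
  )
}

#' @export
print.fc_identifiability <- function(x, ...) {
  cat("<fc_identifiability>", x$method, "\n")
  cat(sprintf("  mean intra = %.4g, mean inter = %.4g\n", x$mean_intra, x$mean_inter))
  cat(sprintf("  t = %.4g, df = %s, p (%s) = %.4g, d = %.3g\n",
              x$t_statistic, format(x$df), x$alternative, x$p_value, x$cohen_d))
  invisible(x)
}

#' Fold-constrained permutation identifiability test
#'
#' Permutation analogue of [naive_identifiability_test()] that preserves
#' dependencies induced by cross-validation: for each permutation, columns of
#' the similarity matrix are shuffled independently *within* each fold and
#' never across folds, and the one-tailed t statistic is recomputed as a
#' pivotal quantity. The p value uses the add-one estimator
#' `(1 + #(t_perm >= t_obs)) / (1 + n_perm)`, reported alongside a
#' normal-approximation binomial 95% interval.
#'
#' @param similarity An `fc_similarity` (or square matrix).
#' @param folds Fold partition; every fold must have at least 2 members.
#' @param n_perm Number of permutations (at least 100; default 10000).
#' @param seed Integer seed.
#'
#' @return An `fc_permutation` object: list with `p_value`, `p_ci_95`,
#'   `t_observed`, `n_perm`, `seed`.
#' @export
fold_constrained_permutation_test <- function(similarity, folds,
                                              n_perm = 10000, seed = 1L) {
  if (n_perm < 100) {
    abort_fcbench("n_perm must be at least 100", class = "fcbench_error_nperm")
  }
  if (any(fold_sizes(folds) < 2L)) {
    abort_fcbench("every fold must have at least 2 subjects",
                  class = "fcbench_error_degenerate_fold")
  }
  S <- similarity_values(similarity)
  direction <- similarity_direction(similarity)
  N <- nrow(S)
  rs <- rowSums(S)
  fold_idx <- split(seq_len(N), folds$assignment)

  t_from_diag <- function(diag_vals) {
    d <- signed_diff(diag_vals, (rs - diag_vals) / (N - 1), direction)
    sd_d <- stats::sd(d)
    if (sd_d == 0) return(if (mean(d) == 0) 0 else sign(mean(d)) * Inf)
    mean(d) / (sd_d / sqrt(N))
  }

  t_obs <- t_from_diag(diag(S))
  exceed <- 0L
  withr::with_seed(seed, {
    colperm <- integer(N)
    for (b in seq_len(n_perm)) {
      for (idx in fold_idx) colperm[idx] <- idx[sample.int(length(idx))]
      t_b <- t_from_diag(S[cbind(seq_len(N), colperm)])
      if (t_b >= t_obs) exceed <- exceed + 1L
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  half <- 1.959964 * sqrt(p * (1 - p) / n_perm)
  structure(
    list(p_value = p, p_ci_95 = c(max(0, p - half), min(1, p + half)),
         t_observed = t_obs, n_perm = n_perm, seed = seed,
         method = "permutation"),
    class = "fc_permutation"
  )
}

#' @export
print.fc_permutation <- function(x, ...) {
  cat(sprintf("<fc_permutation> p = %.4g [%.4g, %.4g], t_obs = %.4g, n_perm = %d\n",
              x$p_value, x$p_ci_95[1], x$p_ci_95[2], x$t_observed, x$n_perm))
  invisible(x)
}

#' Per-fold prediction-performance differences
#'
#' For each cross-validation fold `k`, computes the vector
#' `delta(k) = r_intra(k) - r_inter(k)` over the fold's subjects using only
#' the fold's own sub-similarity matrix (sign-flipped for distance measures).
#' These per-fold vectors feed the corrected resampled t test and the
#' per-fold bootstrap comparison.
#'
#' @param similarity An `fc_similarity` (or square matrix).
#' @param folds Fold partition.
#'
#' @return A tibble with columns `fold`, `subject_id`, `delta`.
#' @export
fold_deltas <- function(similarity, folds) {
  tab <- intra_inter(similarity, folds, scope = "within_fold")
  direction <- similarity_direction(similarity)
  tibble::tibble(
    fold = tab$fold, subject_id = tab$subject_id,
    delta = signed_diff(tab$r_intra, tab$r_inter, direction)
  )
}

#' Corrected resampled t test between two predictors
#'
#' Compares per-fold prediction performance of a model against a benchmark
#' while accounting for the dependence that cross-validation induces between
#' folds. Per fold `k`, the summary `s_k = f(delta_model(k) -
#' delta_benchmark(k))` is computed over the fold's paired per-subject
#' differences; the statistic is
#' `t = mean(s) / sqrt((1/K + n_test/n_train) * var(s))` with `K - 1` degrees
#' of freedom: the usual standard error is inflated by the train/test overlap
#' factor `n_test/n_train`. The default central-tendency summary is the
#' median (robust to the skewness of the per-subject differences).
#'
#' @param delta_model,delta_benchmark Tibbles from [fold_deltas()] with
#'   aligned `fold` and `subject_id`.
#' @param n_test,n_train Per-fold test and training sample sizes.
#' @param f `"median"` (default) or `"mean"`.
#' @param alternative `"one.sided"` (model better than benchmark) or
#'   `"two.sided"`.
#'
#' @return A list with `t_statistic`, `p_value`, `df`, `fold_summaries`,
#'   `f`, `degenerate`.
#' @export
corrected_resampled_t <- function(delta_model, delta_benchmark,
                                  n_test, n_train, f = c("median", "mean"),
                                  alternative = c("one.sided", "two.sided")) {
  f <- match.arg(f)
  alternative <- match.arg(alternative)
  fstat <- if (f == "median") stats::median else mean
  merged <- dplyr::inner_join(
    delta_model, delta_benchmark,
    by = c("fold", "subject_id"), suffix = c("_model", "_benchmark")
  )
  if (nrow(merged) != nrow(delta_model) || nrow(merged) != nrow(delta_benchmark)) {
    abort_fcbench("delta tables do not align on fold and subject_id",
                  class = "fcbench_error_alignment")
  }
  s <- merged |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(s = fstat(.data$delta_model - .data$delta_benchmark),
                     .groups = "drop")
  K <- nrow(s)
  if (K < 2L) {
    abort_fcbench("need at least 2 folds", class = "fcbench_error_degenerate_fold")
  }
  sigma2 <- stats::var(s$s)
  degenerate <- sigma2 == 0
  if (degenerate) {
    t_stat <- if (mean(s$s) == 0) 0 else sign(mean(s$s)) * Inf
    p <- if (mean(s$s) == 0) {
      if (alternative == "one.sided") 0.5 else 1
    } else if (mean(s$s) > 0) 0 else if (alternative == "one.sided") 1 else 0
  } else {
    t_stat <- mean(s$s) / sqrt((1 / K + n_test / n_train) * sigma2)
    p <- if (alternative == "one.sided") {
      stats::pt(t_stat, K - 1, lower.tail = FALSE)
    } else {
      2 * stats::pt(abs(t_stat), K - 1, lower.tail = FALSE)
    }
  }
  list(t_statistic = t_stat, p_value = p, df = K - 1L,
       fold_summaries = s, f = f, method = "corrected_resampled_t",
       alternative = alternative, degenerate = degenerate)
}

#' Per-fold bootstrap comparison of two predictors
#'
#' For each fold, bootstrap resamples (with replacement) of the fold's paired
#' per-subject differences `delta_model - delta_benchmark` are summarized with
#' `f`; the one-sided 95% lower percentile bound is reported, and a fold is
#' flagged significant when that bound exceeds zero.
#'
#' @param delta_model,delta_benchmark Tibbles from [fold_deltas()].
#' @param n_boot Bootstrap resamples per fold (at least 1000).
#' @param seed Integer seed.
#' @param f `"median"` (default) or `"mean"`.
#'
#' @return A tibble with columns `fold`, `n`, `estimate`, `lower_bound`,
#'   `significant`; the count of significant folds is in attribute
#'   `n_significant`.
#' @export
fold_bootstrap_comparison <- function(delta_model, delta_benchmark,
                                      n_boot = 2000, seed = 1L,
                                      f = c("median", "mean")) {
  f <- match.arg(f)
  if (n_boot < 1000) {
    abort_fcbench("n_boot must be at least 1000", class = "fcbench_error_nboot")
  }
  fstat <- if (f == "median") stats::median else mean
  merged <- dplyr::inner_join(
    delta_model, delta_benchmark,
    by = c("fold", "subject_id"), suffix = c("_model", "_benchmark")
  )
  folds <- sort(unique(merged$fold))
  rows <- vector("list", length(folds))
  withr::with_seed(seed, {
    for (j in seq_along(folds)) {
      d <- with(merged[merged$fold == folds[j], ],
                delta_model - delta_benchmark)
      n <- length(d)
      if (n < 3L) {
        abort_fcbench(sprintf("fold %d has fewer than 3 subjects", folds[j]),
                      class = "fcbench_error_degenerate_fold")
      }
      boots <- vapply(seq_len(n_boot),
                      function(b) fstat(d[sample.int(n, n, replace = TRUE)]),
                      numeric(1))
      lb <- unname(stats::quantile(boots, 0.05, type = 7))
      rows[[j]] <- tibble::tibble(fold = folds[j], n = n,
                                  estimate = fstat(d),
                                  lower_bound = lb,
                                  significant = lb > 0)
    }
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_significant") <- sum(out$significant)
  attr(out, "f") <- f
  attr(out, "seed") <- seed
  out
}

#' Percent improvement of a model over a reference
#'
#' `(r_model - r_reference) / r_model * 100`, the headline effect-size
#' summary for how much of the model's intra-individual similarity is not
#' explained by the reference (e.g. the noisy group-mean benchmark).
#'
#' @param r_model,r_reference Scalar similarities; `r_model` must be nonzero.
#'
#' @return Percentage (can be negative if the reference outperforms).
#' @export
percent_improvement <- function(r_model, r_reference) {
  if (r_model == 0) {
    abort_fcbench("r_model must be nonzero", class = "fcbench_error_zero_model")
  }
  (r_model - r_reference) / r_model * 100
}

#' Differential identifiability
#'
#' Convenience descriptive statistic: the mean of the diagonal (intra)
#' similarities minus the mean of all off-diagonal (inter) similarities of
#' the similarity matrix. No significance test is attached: its two-sample
#' framing assumes independence across all pairs, which cross-validated
#' predictions violate; use the within-subject tests instead.
#'
#' @param similarity An `fc_similarity` (or square matrix).
#'
#' @return A single number (sign-flipped for distance measures so that
#'   positive means identifiable).
#' @export
differential_identifiability <- function(similarity) {
  S <- similarity_values(similarity)
  direction <- similarity_direction(similarity)
  N <- nrow(S)
  intra <- mean(diag(S))
  inter <- (sum(S) - sum(diag(S))) / (N * (N - 1))
  signed_diff(intra, inter, direction)
}
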
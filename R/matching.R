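#' Optimal one-to-one prediction-to-reference assignment
#'
#' Solves the linear assignment problem on the similarity matrix with the
#' Hungarian method: for correlation-like measures the total similarity is
#' maximized (equivalently, the negated matrix is minimized); for distance
#' measures the total distance is minimized directly. The number of fixed
#' points of the resulting permutation — the trace of the binary assignment
#' matrix — is the number of correctly matched subjects.
#'
#' @param similarity An `fc_similarity` or a square numeric matrix (a bare
#'   matrix is treated as higher-is-more-similar).
#'
#' @return A list with `assignment` (integer permutation: row `i` is matched
#'   to column `assignment[i]`), `n_correct`, and `total` (summed similarity
#'   or distance along the assignment).
#' @export
optimal_assignment <- function(similarity) {
  S <- similarity_values(similarity)
  if (any(!is.finite(S))) {
    abort_fcbench("similarity matrix has non-finite entries",
                  class = "fcbench_error_nonfinite")
  }
  maximize <- similarity_direction(similarity) == "higher_is_more_similar"
  # solve_LSAP requires nonnegative entries; a constant shift leaves the
  # optimal permutation unchanged
  shifted <- S - min(S)
  a <- as.integer(clue::solve_LSAP(shifted, maximum = maximize))
  list(assignment = a,
       n_correct = sum(a == seq_len(nrow(S))),
       total = sum(S[cbind(seq_len(nrow(S)), a)]))
}

#' Chance-level assignment via column permutation
#'
#' Columns of the similarity matrix are permuted uniformly at random before
#' solving the assignment, which destroys the subject correspondence and
#' yields the chance null for matching accuracy (a uniformly random
#' permutation has one fixed point in expectation, so chance accuracy is
#' `100/n` percent).
#'
#' @param similarity An `fc_similarity` or square numeric matrix.
#' @param seed Integer seed.
#'
#' @return Integer count of correctly matched subjects under the chance
#'   condition.
#' @export
chance_assignment <- function(similarity, seed) {
  S <- similarity_values(similarity)
  n <- nrow(S)
  q <- withr::with_seed(seed, sample.int(n))
  chance_assignment_perm(similarity, q)
}

# chance assignment given an explicit column permutation (internal fast path);
# scored against the diagonal of the permuted matrix, so the solver recovering
# the true correspondence lands on the fixed points of a random permutation
chance_assignment_perm <- function(similarity, q) {
  S <- similarity_values(similarity)
  Sq <- S[, q, drop = FALSE]
  if (inherits(similarity, "fc_similarity")) {
    sim_q <- new_fc_similarity(Sq, similarity$measure, similarity$subject_ids)
  } else {
    sim_q <- Sq
  }
  optimal_assignment(sim_q)$n_correct
}

#' Matching-accuracy curve over subset sizes
#'
#' For each subset size `n = 2, ..., n_max`, draws `M` random subsets of `n`
#' subjects — each subset sampled without replacement from within a single
#' cross-validation fold chosen uniformly at random, so no between-fold
#' dependence enters a subset — and records the percentage of subjects
#' correctly matched by [optimal_assignment()] (model condition) and by
#' [chance_assignment()] (null condition) on the subset's sub-similarity
#' matrix. Per size, a one-tailed two-sample equal-variance t test
#' (`df = 2M - 2`) compares the per-subset accuracies between conditions, and
#' Benjamini-Hochberg adjustment controls the false discovery rate across the
#' `n_max - 1` sizes.
#'
#' @param similarity An `fc_similarity` (or square matrix).
#' @param folds Fold partition; `n_max` must not exceed the smallest fold.
#' @param n_max Largest subset size (default 20).
#' @param M Subsets per size (default 2500).
#' @param seed Integer seed.
#' @param fdr_level FDR level for the significance flags (default 0.05).
#'
#' @return An `fc_matching_curve`: a tibble with one row per subset size and
#'   columns `n`, `accuracy_model`, `accuracy_null`, `t`, `p`, `q`,
#'   `significant`, `improvement`, with sampling settings in attributes.
#' @export
matching_curve <- function(similarity, folds, n_max = 20, M = 2500,
                           seed = 1L, fdr_level = 0.05) {
  S <- similarity_values(similarity)
  if (n_max > min(fold_sizes(folds))) {
    abort_fcbench("n_max exceeds the smallest fold size",
                  class = "fcbench_error_subset_size")
  }
  if (M < 1 || n_max < 2) {
    abort_fcbench("need M >= 1 and n_max >= 2", class = "fcbench_error_subset_size")
  }
  fold_idx <- split(seq_len(nrow(S)), folds$assignment)
  sizes <- 2:n_max
  acc_model <- matrix(NA_real_, M, length(sizes))
  acc_null <- matrix(NA_real_, M, length(sizes))

  subset_sim <- function(idx) {
    sub <- S[idx, idx, drop = FALSE]
    if (inherits(similarity, "fc_similarity")) {
      new_fc_similarity(sub, similarity$measure,
                        similarity_ids(similarity, nrow(S))[idx])
    } else {
      sub
    }
  }

  withr::with_seed(seed, {
    for (j in seq_along(sizes)) {
      n <- sizes[j]
      for (m in seq_len(M)) {
        fold <- fold_idx[[sample.int(length(fold_idx), 1L)]]
        idx <- fold[sample.int(length(fold), n)]
        sub <- subset_sim(idx)
        acc_model[m, j] <- optimal_assignment(sub)$n_correct / n * 100
        acc_null[m, j] <- chance_assignment_perm(sub, sample.int(n)) / n * 100
      }
    }
  })

  tt <- vapply(seq_along(sizes), function(j) {
    x <- acc_model[, j]; y <- acc_null[, j]
    sp <- sqrt(((M - 1) * stats::var(x) + (M - 1) * stats::var(y)) / (2 * M - 2))
    se <- sp * sqrt(2 / M)
    if (se == 0) {
      if (mean(x) == mean(y)) c(0, 0.5) else c(sign(mean(x) - mean(y)) * Inf,
                                               if (mean(x) > mean(y)) 0 else 1)
    } else {
      t <- (mean(x) - mean(y)) / se
      c(t, stats::pt(t, 2 * M - 2, lower.tail = FALSE))
    }
  }, numeric(2))

  out <- tibble::tibble(
    n = sizes,
    accuracy_model = colMeans(acc_model),
    accuracy_null = colMeans(acc_null),
    t = tt[1, ],
    p = tt[2, ],
    q = stats::p.adjust(tt[2, ], method = "BH"),
    improvement = colMeans(acc_model) - colMeans(acc_null)
  )
  out$significant <- out$q < fdr_level
  out <- out[, c("n", "accuracy_model", "accuracy_null", "t", "p", "q",
                 "significant", "improvement")]
  class(out) <- c("fc_matching_curve", class(out))
  attr(out, "M") <- M
  attr(out, "seed") <- seed
  attr(out, "fdr_level") <- fdr_level
  out
}

#' Improvement of matching accuracy over chance
#'
#' Per-size improvement in percentage points (`accuracy_model -
#' accuracy_null`) and the pooled mean and standard deviation across subset
#' sizes.
#'
#' @param curve An `fc_matching_curve` from [matching_curve()].
#'
#' @return A list with `per_n` (tibble `n`, `improvement`, `significant`),
#'   `pooled_mean`, `pooled_sd`.
#' @export
improvement_vs_chance <- function(curve) {
  stopifnot(inherits(curve, "fc_matching_curve"))
  list(
    per_n = tibble::tibble(n = curve$n, improvement = curve$improvement,
                           significant = curve$significant),
    pooled_mean = mean(curve$improvement),
    pooled_sd = stats::sd(curve$improvement)
  )
}

#' Write a matching curve as TSV
#'
#' @param curve An `fc_matching_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matching_curve <- function(curve, path) {
  readr::write_tsv(as.data.frame(curve), path)
  invisible(path)
}
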
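# Fold-respecting benchmark predictions and standardization.
#
# All three operations draw moments exclusively from each subject's training
# complement (subjects outside the subject's own fold), so no information
# leaks from a test fold into the benchmark or the z-scoring applied to it.

# per-fold elementwise mean and sd (n-1 denominator) over training subjects
fold_moments <- function(stack, folds) {
  K <- folds$K
  out <- vector("list", K)
  for (k in seq_len(K)) {
    train <- which(folds$assignment != k)
    if (length(train) < 2L) {
      abort_fcbench(sprintf("training complement of fold %d has < 2 subjects", k),
                    class = "fcbench_error_degenerate_fold")
    }
    sub <- stack[, , train, drop = FALSE]
    mu <- apply(sub, c(1L, 2L), mean)
    sdv <- apply(sub, c(1L, 2L), stats::sd)
    out[[k]] <- list(fold = k, mean = mu, sd = sdv, n_train = length(train))
  }
  out
}

#' Group-mean benchmark prediction
#'
#' For each subject, the elementwise mean empirical FC over the subjects in
#' that subject's training complement (all folds except their own), with the
#' diagonal set to 1. This is the "predict the group average for everyone"
#' benchmark: it carries no individual information, yet correlates highly with
#' every subject's eFC because group structure dominates.
#'
#' @param cohort An `fc_cohort`.
#'
#' @return A `p x p x N` array usable in place of the pFC stack.
#' @export
fold_mean_prediction <- function(cohort) {
  stopifnot(inherits(cohort, "fc_cohort"))
  moments <- fold_moments(cohort$efc, cohort$folds)
  out <- array(NA_real_, dim = dim(cohort$efc))
  for (i in seq_len(n_subjects(cohort))) {
    m <- moments[[cohort$folds$assignment[i]]]$mean
    diag(m) <- 1
    out[, , i] <- m
  }
  out
}

#' Group-mean-plus-matched-noise benchmark prediction
#'
#' [fold_mean_prediction()] with independent zero-mean Gaussian noise added to
#' each off-diagonal element, the noise standard deviation matched to the
#' elementwise standard deviation observed across the training-set eFC
#' matrices. Noise is drawn once per upper-triangle element and mirrored, so
#' the output stays symmetric; values are deliberately not clipped to
#' `[-1, 1]`, which would distort the matched-variance property. This
#' benchmark mimics inter-individual variability in distribution without
#' containing any subject-specific signal.
#'
#' @param cohort An `fc_cohort`.
#' @param seed Integer seed; the draw is reproducible for a fixed seed.
#'
#' @return A `p x p x N` array.
#' @export
noisy_mean_prediction <- function(cohort, seed) {
  stopifnot(inherits(cohort, "fc_cohort"))
  moments <- fold_moments(cohort$efc, cohort$folds)
  p <- n_nodes(cohort)
  ut <- upper.tri(matrix(0, p, p))
  out <- array(NA_real_, dim = dim(cohort$efc))
  withr::with_seed(seed, {
    for (i in seq_len(n_subjects(cohort))) {
      mom <- moments[[cohort$folds$assignment[i]]]
      m <- mom$mean
      noise <- matrix(0, p, p)
      noise[ut] <- stats::rnorm(sum(ut), mean = 0, sd = mom$sd[ut])
      m <- m + noise + t(noise)
      diag(m) <- 1
      out[, , i] <- m
    }
  })
  out
}

#' Fold-respecting z-scoring of a matrix stack
#'
#' Standardizes each off-diagonal element across participants: element `e` of
#' subject `i` becomes `(e - mean) / sd`, with the mean and standard deviation
#' computed over the training complement of subject `i`'s fold in
#' `moments_source`. Elements whose training standard deviation is below
#' `1e-12` are set to 0, as is the diagonal. Standardization removes the
#' dominant group-average component so that individual deviations carry the
#' similarity signal; computing moments within training folds avoids data
#' leakage.
#'
#' @param stack `p x p x N` array to standardize.
#' @param cohort_folds An `fc_folds` partition aligned with the stack.
#' @param moments_source `p x p x N` array from which training moments are
#'   computed (defaults to `stack` itself: own-stack moments).
#'
#' @return The standardized `p x p x N` array.
#' @export
fold_zscore <- function(stack, cohort_folds, moments_source = stack) {
  if (!identical(dim(stack), dim(moments_source))) {
    abort_fcbench("stack and moments_source are not aligned",
                  class = "fcbench_error_dimension")
  }
  moments <- fold_moments(moments_source, cohort_folds)
  out <- array(NA_real_, dim = dim(stack))
  for (i in seq_len(dim(stack)[3L])) {
    mom <- moments[[cohort_folds$assignment[i]]]
    z <- (stack[, , i] - mom$mean) / mom$sd
    z[mom$sd < 1e-12] <- 0
    diag(z) <- 0
    out[, , i] <- z
  }
  out
}
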
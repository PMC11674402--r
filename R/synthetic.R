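#' Specification for a synthetic connectome cohort
#'
#' Describes a cohort in which every subject's latent covariance is a mixture
#' of a shared group component and a subject-specific individual component,
#' `(1 - alpha) * Sigma_G + alpha * Sigma_i`. Empirical FC is the sample
#' correlation matrix of `t_samples` latent draws; predicted FC is built from
#' an independent set of draws whose individual component is a
#' `beta`-weighted blend of the true `Sigma_i` and a fresh nuisance
#' covariance, so `beta` tunes prediction fidelity (`beta = 0` is the null
#' condition: predictions carry no individual information). Sparse
#' nonnegative structural connectomes are coupled to the same individual
#' component.
#'
#' @param n_subjects Number of subjects (>= 4; default 100, desk scale).
#' @param n_nodes Number of nodes `p` (>= 5; default 68, the cortical
#'   parcellation size typical of this literature).
#' @param t_samples Latent observations per subject (> `n_nodes`, default
#'   300), guaranteeing full-rank sample correlation matrices.
#' @param alpha Share of each subject's latent covariance contributed by the
#'   individual component, in `[0, 1]` (default 0.1: group structure
#'   dominates and individual effects are small but stable, matching the
#'   subtle fingerprinting effects seen in real cohorts).
#' @param beta Prediction fidelity to the individual component, in `[0, 1]`
#'   (default 1).
#' @param sc_density Fraction of nonzero SC edges in `(0, 1]` (default 0.5).
#' @param sc_noise Standard deviation of Gaussian noise added to the SC
#'   coupling before thresholding (default 0.1).
#' @param sc_coupling Strength of the SC link to the individual component
#'   (default 1).
#' @param K Fold count (default 10).
#' @param factor_rank Rank of the random factor matrices behind each latent
#'   covariance (default `round(n_nodes / 4)`, giving realistic eigenvalue
#'   decay).
#' @param seed Integer seed; generation is fully deterministic given the spec.
#'
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_subjects = 100, n_nodes = 68, t_samples = 300,
                           alpha = 0.1, beta = 1, sc_density = 0.5,
                           sc_noise = 0.1, sc_coupling = 1, K = 10,
                           factor_rank = NULL, seed = 1L) {
  if (is.null(factor_rank)) factor_rank <- max(1L, round(n_nodes / 4))
  spec <- list(n_subjects = as.integer(n_subjects), n_nodes = as.integer(n_nodes),
               t_samples = as.integer(t_samples), alpha = alpha, beta = beta,
               sc_density = sc_density, sc_noise = sc_noise,
               sc_coupling = sc_coupling, K = as.integer(K),
               factor_rank = as.integer(factor_rank), seed = as.integer(seed))
  with(spec, {
    if (n_subjects < 4L) abort_fcbench("n_subjects must be >= 4",
                                       class = "fcbench_error_spec")
    if (n_nodes < 5L) abort_fcbench("n_nodes must be >= 5",
                                    class = "fcbench_error_spec")
    if (t_samples <= n_nodes) abort_fcbench("t_samples must exceed n_nodes",
                                            class = "fcbench_error_spec")
    if (alpha < 0 || alpha > 1) abort_fcbench("alpha must lie in [0, 1]",
                                              class = "fcbench_error_spec")
    if (beta < 0 || beta > 1) abort_fcbench("beta must lie in [0, 1]",
                                            class = "fcbench_error_spec")
    if (sc_density <= 0 || sc_density > 1) abort_fcbench(
      "sc_density must lie in (0, 1]", class = "fcbench_error_spec")
    if (sc_noise < 0) abort_fcbench("sc_noise must be nonnegative",
                                    class = "fcbench_error_spec")
    if (K < 2L || K > n_subjects %/% 2L) abort_fcbench(
      "K must be >= 2 with at least 2 subjects per fold",
      class = "fcbench_error_spec")
  })
  structure(spec, class = "synthetic_spec")
}

# random low-rank-plus-identity latent covariance A A' + I
random_factor_cov <- function(p, rank) {
  A <- matrix(stats::rnorm(p * rank), p, rank)
  tcrossprod(A) + diag(p)
}

# sample correlation matrix of t draws from N(0, C)
sample_correlation <- function(C, t_samples) {
  X <- matrix(stats::rnorm(t_samples * nrow(C)), t_samples, nrow(C)) %*% chol(C)
  stats::cor(X)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Deterministic under the spec's seed. Per subject: empirical FC is the
#' sample correlation of latent draws from the mixed covariance; predicted FC
#' uses an independent set of draws whose individual component is diluted by
#' `1 - beta` of a fresh nuisance covariance; SC couples the individual
#' component off-diagonals with additive noise, keeps the strongest
#' `sc_density` fraction of edges and maps the surviving weights through a
#' rank transform onto a positive normal scale (log-streamline-count
#' flavour). Folds are assigned in contiguous blocks. Because eFC and pFC are
#' realized as sample correlation matrices, they are symmetric, unit-diagonal
#' and positive semidefinite by construction.
#'
#' @param spec A [synthetic_spec()].
#'
#' @return A list with `cohort` (an [fc_cohort()]) and `truth` (a
#'   `ground_truth` list: realized `alpha`, `beta`, the group covariance, the
#'   per-subject individual covariances, and the fold partition).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  N <- spec$n_subjects; p <- spec$n_nodes
  efc <- array(NA_real_, c(p, p, N))
  pfc <- array(NA_real_, c(p, p, N))
  sc <- array(NA_real_, c(p, p, N))
  sigma_i <- vector("list", N)
  sigma_g <- NULL
  withr::with_seed(spec$seed, {
    sigma_g <- random_factor_cov(p, spec$factor_rank)
    for (i in seq_len(N)) {
      sigma_i[[i]] <- random_factor_cov(p, spec$factor_rank)
      nuisance <- random_factor_cov(p, spec$factor_rank)
      c_e <- (1 - spec$alpha) * sigma_g + spec$alpha * sigma_i[[i]]
      c_p <- (1 - spec$alpha) * sigma_g +
        spec$alpha * (spec$beta * sigma_i[[i]] + (1 - spec$beta) * nuisance)
      efc[, , i] <- sample_correlation(c_e, spec$t_samples)
      pfc[, , i] <- sample_correlation(c_p, spec$t_samples)
      sc[, , i] <- synthetic_sc(sigma_i[[i]], spec)
    }
  })
  folds <- fold_partition(sort(rep_len(seq_len(spec$K), N)))
  cohort <- fc_cohort(
    subject_ids = sprintf("sub%03d", seq_len(N)),
    efc = efc, pfc = pfc, sc = sc, folds = folds
  )
  truth <- structure(
    list(alpha = spec$alpha, beta = spec$beta, spec = spec,
         group_cov = sigma_g, individual_covs = sigma_i, folds = folds),
    class = "ground_truth"
  )
  list(cohort = cohort, truth = truth)
}

# sparse nonnegative SC coupled to the individual latent covariance:
# threshold to the top sc_density fraction of edges, rank-transform surviving
# weights to Normal(5, 1) quantiles (floored at a tiny positive value so
# nonnegativity is structural), mirror symmetric, zero diagonal
synthetic_sc <- function(sigma_ind, spec) {
  p <- spec$n_nodes
  ut <- which(upper.tri(matrix(0, p, p)))
  w <- spec$sc_coupling * sigma_ind[ut] +
    stats::rnorm(length(ut), sd = spec$sc_noise)
  n_keep <- max(3L, ceiling(spec$sc_density * length(w)))
  keep <- rank(-w, ties.method = "first") <= n_keep
  m <- matrix(0, p, p)
  vals <- numeric(sum(keep))
  r <- rank(w[keep], ties.method = "first")
  vals <- pmax(stats::qnorm(r / (sum(keep) + 1), mean = 5, sd = 1), 1e-6)
  m[ut[keep]] <- vals
  m + t(m)
}

#' Generate a null synthetic cohort
#'
#' [generate_cohort()] with `beta` forced to 0: predictions are statistically
#' exchangeable across subjects given the group component, so identifiability
#' tests should reject only at the nominal rate and matching accuracy should
#' sit at the `100/n` percent chance level.
#'
#' @param spec A [synthetic_spec()]; its `beta` is overridden with 0.
#'
#' @return As [generate_cohort()].
#' @export
null_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  spec$beta <- 0
  generate_cohort(spec)
}
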
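# deterministic in-code fixtures and independent oracles

# random symmetric matrix with unit diagonal (valid eFC-like fixture)
rand_corr_fixture <- function(p, t_samples = 4 * p, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(t_samples * p), t_samples, p)
    stats::cor(X)
  })
}

# random SPD matrix via A'A + eps I
rand_spd <- function(p, seed, jitter = 0.5) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(p * p), p, p)
    crossprod(A) / p + jitter * diag(p)
  })
}

# small valid cohort built from sample correlation matrices
make_cohort <- function(N = 6, p = 5, K = 2, t_samples = 40, seed = 1,
                        with_sc = FALSE) {
  withr::with_seed(seed, {
    efc <- array(NA_real_, c(p, p, N))
    pfc <- array(NA_real_, c(p, p, N))
    sc <- if (with_sc) array(NA_real_, c(p, p, N)) else NULL
    for (i in seq_len(N)) {
      efc[, , i] <- stats::cor(matrix(rnorm(t_samples * p), t_samples, p))
      pfc[, , i] <- stats::cor(matrix(rnorm(t_samples * p), t_samples, p))
      if (with_sc) {
        m <- matrix(0, p, p)
        ut <- upper.tri(m)
        w <- runif(sum(ut))
        w[w < 0.3] <- 0
        m[ut] <- w
        sc[, , i] <- m + t(m)
      }
    }
    fc_cohort(
      subject_ids = sprintf("s%02d", seq_len(N)),
      efc = efc, pfc = pfc, sc = sc,
      folds = fold_partition(sort(rep_len(seq_len(K), N)))
    )
  })
}

# all permutations of 1..n (independent of any solver)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}

# brute-force best assignment total by enumeration
brute_force_best_total <- function(S, maximize = TRUE) {
  n <- nrow(S)
  totals <- vapply(all_perms(n),
                   function(q) sum(S[cbind(seq_len(n), q)]), numeric(1))
  if (maximize) max(totals) else min(totals)
}

# matrix logarithm oracle: explicit eigendecomposition and Frobenius sum,
# written independently of the package internals
lerm_oracle <- function(A, B) {
  logm <- function(M) {
    e <- eigen(M, symmetric = TRUE)
    U <- e$vectors
    L <- matrix(0, nrow(M), nrow(M))
    for (k in seq_len(nrow(M))) {
      L <- L + log(e$values[k]) * (U[, k] %o% U[, k])
    }
    L
  }
  D <- logm(A) - logm(B)
  s <- 0
  for (i in seq_len(nrow(D))) for (j in seq_len(ncol(D))) s <- s + D[i, j]^2
  sqrt(s)
}
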
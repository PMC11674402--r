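#' Vectorize the strict upper triangle of a square matrix
#'
#' Connectivity matrices are symmetric with an uninformative diagonal (unit
#' self-correlation), so similarity between two matrices is computed on the
#' `p(p-1)/2` strict upper-triangle entries, taken in row-major order.
#'
#' @param matrix A square numeric matrix, `p >= 3`.
#'
#' @return Numeric vector of length `p(p-1)/2`.
#' @export
#' @examples
#' vectorize_offdiag(matrix(1:9, 3, 3))  # upper triangle, by row
vectorize_offdiag <- function(matrix) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix)) {
    abort_fcbench("input must be a square matrix", class = "fcbench_error_dimension")
  }
  tm <- t(matrix)
  tm[lower.tri(tm)]
}

#' Pearson similarity between two connectivity matrices
#'
#' The standard Pearson correlation between the vectorized strict upper
#' triangles of the two matrices.
#'
#' @param a,b Square numeric matrices of the same dimension.
#'
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_similarity <- function(a, b) {
  va <- vectorize_offdiag(a)
  vb <- vectorize_offdiag(b)
  if (length(va) != length(vb)) {
    abort_fcbench("matrices differ in dimension", class = "fcbench_error_dimension")
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    abort_fcbench("off-diagonal vector has zero variance; correlation undefined",
                  class = "fcbench_error_zero_variance")
  }
  stats::cor(va, vb)
}

#' Masked Pearson similarity
#'
#' Pearson correlation restricted to off-diagonal positions where `mask` is
#' `TRUE`. Used to constrain SC-to-eFC correlations to the nonzero edges of a
#' sparse structural connectome.
#'
#' @param a,b Square numeric matrices of the same dimension.
#' @param mask Square logical (or 0/1) matrix; only its strict upper triangle
#'   is consulted. At least 3 selected positions are required.
#'
#' @return Correlation over the selected positions.
#' @export
masked_pearson <- function(a, b, mask) {
  keep <- as.logical(vectorize_offdiag(mask * 1))
  va <- vectorize_offdiag(a)[keep]
  vb <- vectorize_offdiag(b)[keep]
  if (length(va) < 3L) {
    abort_fcbench("mask selects fewer than 3 off-diagonal positions",
                  class = "fcbench_error_mask")
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    abort_fcbench("masked vector is constant; correlation undefined",
                  class = "fcbench_error_zero_variance")
  }
  stats::cor(va, vb)
}

#' Project a symmetric matrix onto the SPD cone
#'
#' Eigenvalues below `floor * max(lambda_max, 1)` are raised to that
#' threshold and the matrix reconstructed. Needed because predicted
#' connectivity matrices (and near-singular sample correlation matrices) may
#' not be positive definite, while the log-Euclidean metric requires SPD
#' inputs. Idempotent on matrices whose spectrum already clears the floor.
#'
#' @param matrix Symmetric numeric matrix.
#' @param floor Relative eigenvalue floor (default `1e-6`).
#'
#' @return A symmetric positive definite matrix.
#' @export
spd_project <- function(matrix, floor = 1e-6) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix) ||
      max(abs(matrix - t(matrix))) > 1e-8 * max(abs(matrix), 1)) {
    abort_fcbench("spd_project requires a symmetric matrix",
                  class = "fcbench_error_symmetry")
  }
  e <- eigen((matrix + t(matrix)) / 2, symmetric = TRUE)
  thresh <- floor * max(max(e$values), 1)
  vals <- pmax(e$values, thresh)
  out <- e$vectors %*% (vals * t(e$vectors))
  (out + t(out)) / 2
}

#' Log-Euclidean Riemannian distance between SPD matrices
#'
#' The Frobenius norm of the difference of matrix logarithms,
#' `||Log(A) - Log(B)||_F`. Correlation matrices live on the SPD manifold, and
#' this metric respects that geometry by mapping through the matrix logarithm
#' before taking a Euclidean distance. Lower values mean more similar
#' matrices. Callers should pass inputs through [spd_project()] first when
#' positive definiteness is not guaranteed.
#'
#' @param a,b Symmetric positive definite matrices of the same dimension.
#'
#' @return Nonnegative distance.
#' @export
lerm_distance <- function(a, b) {
  sqrt(sum((spd_logm(a) - spd_logm(b))^2))
}

# matrix logarithm of an SPD matrix via symmetric eigendecomposition
spd_logm <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (min(e$values) <= 0) {
    abort_fcbench("matrix is not positive definite; apply spd_project first",
                  class = "fcbench_error_not_spd")
  }
  e$vectors %*% (log(e$values) * t(e$vectors))
}

new_fc_similarity <- function(values, measure, subject_ids) {
  structure(
    list(
      values = values,
      measure = measure,
      direction = if (measure == "lerm") "lower_is_more_similar" else "higher_is_more_similar",
      subject_ids = subject_ids
    ),
    class = "fc_similarity"
  )
}

#' @export
print.fc_similarity <- function(x, ...) {
  cat("<fc_similarity>", nrow(x$values), "x", ncol(x$values),
      "| measure:", x$measure, "|", x$direction, "\n")
  invisible(x)
}

#' Build the cross-subject similarity matrix
#'
#' Entry `(i, j)` compares the prediction for subject `i` against the
#' empirical reference of subject `j`, so the diagonal holds intra-individual
#' similarities and off-diagonal entries inter-individual ones.
#'
#' With `measure = "pearson"`, similarities are correlations of vectorized
#' upper triangles (higher = more similar). `mask_policy =
#' "per_prediction_nonzero"` restricts row `i` to the nonzero off-diagonal
#' pattern of prediction `i` (the SC-to-eFC convention for sparse structural
#' connectomes). With `measure = "lerm"`, both stacks are passed through
#' [spd_project()] and entries are log-Euclidean distances (lower = more
#' similar); raw, unstandardized matrices must be supplied.
#'
#' @param predictions,references `p x p x N` arrays (aligned stacks), or an
#'   `fc_cohort` for `predictions` together with `source`.
#' @param measure `"pearson"` or `"lerm"`.
#' @param mask_policy `"none"` or `"per_prediction_nonzero"` (Pearson only).
#' @param spd_floor Relative eigenvalue floor for the LERM projection.
#' @param subject_ids Optional subject labels.
#'
#' @return An `fc_similarity` object.
#' @export
build_similarity <- function(predictions, references,
                             measure = c("pearson", "lerm"),
                             mask_policy = c("none", "per_prediction_nonzero"),
                             spd_floor = 1e-6, subject_ids = NULL) {
  measure <- match.arg(measure)
  mask_policy <- match.arg(mask_policy)
  if (!identical(dim(predictions), dim(references))) {
    abort_fcbench("prediction and reference stacks are not aligned",
                  class = "fcbench_error_dimension")
  }
  if (mask_policy == "per_prediction_nonzero" && measure != "pearson") {
    abort_fcbench("mask_policy per_prediction_nonzero requires measure = 'pearson'",
                  class = "fcbench_error_mask")
  }
  N <- dim(predictions)[3L]
  if (is.null(subject_ids)) subject_ids <- as.character(seq_len(N))

  if (measure == "pearson") {
    vp <- apply(predictions, 3L, vectorize_offdiag)  # L x N
    vr <- apply(references, 3L, vectorize_offdiag)
    if (any(apply(vp, 2L, stats::sd) == 0) || any(apply(vr, 2L, stats::sd) == 0)) {
      abort_fcbench("a matrix has constant off-diagonal entries; correlation undefined",
                    class = "fcbench_error_zero_variance")
    }
    if (mask_policy == "none") {
      values <- stats::cor(vp, vr)
    } else {
      values <- matrix(NA_real_, N, N)
      for (i in seq_len(N)) {
        keep <- vp[, i] != 0
        if (sum(keep) < 3L) {
          abort_fcbench(sprintf("prediction %d has fewer than 3 nonzero edges", i),
                        class = "fcbench_error_mask")
        }
        values[i, ] <- stats::cor(vp[keep, i], vr[keep, , drop = FALSE])
      }
    }
  } else {
    p <- dim(predictions)[1L]
    logs_p <- matrix(NA_real_, N, p * p)
    logs_r <- matrix(NA_real_, N, p * p)
    for (i in seq_len(N)) {
      logs_p[i, ] <- as.vector(spd_logm(spd_project(predictions[, , i], spd_floor)))
      logs_r[i, ] <- as.vector(spd_logm(spd_project(references[, , i], spd_floor)))
    }
    sq <- outer(rowSums(logs_p^2), rowSums(logs_r^2), "+") -
      2 * tcrossprod(logs_p, logs_r)
    values <- sqrt(pmax(sq, 0))
  }
  dimnames(values) <- list(subject_ids, subject_ids)
  new_fc_similarity(values, measure, subject_ids)
}

#' Write / read a similarity matrix with its metadata sidecar
#'
#' The matrix is written as headerless tab-delimited text; a one-line JSON
#' sidecar (`<path>.json`) records the measure, direction and subject order.
#'
#' @param similarity An `fc_similarity`.
#' @param path Output path for the matrix file.
#' @return `write_similarity` returns `path` invisibly; `read_similarity`
#'   returns an `fc_similarity`.
#' @export
write_similarity <- function(similarity, path) {
  write_matrix_file(similarity$values, path)
  jsonlite::write_json(
    list(measure = similarity$measure, direction = similarity$direction,
         subject_ids = similarity$subject_ids),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  values <- read_matrix_file(path)
  dimnames(values) <- list(meta$subject_ids, meta$subject_ids)
  new_fc_similarity(values, meta$measure, meta$subject_ids)
}
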
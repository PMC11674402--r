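#' Fold partition over cohort subjects
#'
#' A cross-validation fold partition: every subject carries a fold index in
#' `1..K` and every fold is non-empty. Benchmarks, standardization and the
#' fold-constrained permutation test all respect this partition, so when a
#' cohort holds externally predicted matrices the partition must be the one
#' used during model training.
#'
#' @param assignment Integer vector of fold indices, one per subject.
#' @param K Number of folds. Defaults to `max(assignment)`.
#'
#' @return An object of class `fc_folds`: a list with elements `K` and
#'   `assignment`.
#' @export
#' @examples
#' fold_partition(c(1, 1, 2, 2))
fold_partition <- function(assignment, K = NULL) {
  assignment <- as.integer(assignment)
  if (length(assignment) < 2L || anyNA(assignment)) {
    abort_fcbench("fold assignment must be a length >= 2 integer vector without NA",
                  class = "fcbench_error_folds")
  }
  if (is.null(K)) K <- max(assignment)
  K <- as.integer(K)
  if (K < 1L || any(assignment < 1L) || any(assignment > K)) {
    abort_fcbench("fold labels must lie in 1..K", class = "fcbench_error_folds")
  }
  if (!setequal(unique(assignment), seq_len(K))) {
    abort_fcbench("fold labels must form a 1..K partition with every fold non-empty",
                  class = "fcbench_error_folds")
  }
  structure(list(K = K, assignment = assignment), class = "fc_folds")
}

#' @export
print.fc_folds <- function(x, ...) {
  sizes <- tabulate(x$assignment, nbins = x$K)
  cat("<fc_folds> K =", x$K, "| fold sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

fold_sizes <- function(folds) tabulate(folds$assignment, nbins = folds$K)

#' Assemble a connectome cohort
#'
#' Bundles aligned per-subject connectivity matrices: empirical functional
#' connectivity (eFC, Pearson correlation matrices with unit diagonal),
#' predicted functional connectivity (pFC), and optionally structural
#' connectomes (SC, nonnegative weights with zeros for absent edges), together
#' with a cross-validation fold partition. Matrices with asymmetry at or below
#' `1e-8` (relative to the largest magnitude entry) are silently symmetrized
#' as `(M + t(M))/2`; larger asymmetry is an error.
#'
#' @param subject_ids Character vector of unique subject labels.
#' @param efc,pfc `p x p x N` arrays (or lists of `p x p` matrices) of
#'   empirical and predicted functional connectivity.
#' @param sc Optional `p x p x N` array of structural connectomes.
#' @param folds An [fold_partition()] object, or an integer vector of fold
#'   labels.
#'
#' @return An object of class `fc_cohort`: list with `subject_ids`, `efc`,
#'   `pfc`, `sc` (or `NULL`) and `folds`.
#' @export
fc_cohort <- function(subject_ids, efc, pfc, sc = NULL, folds) {
  subject_ids <- as.character(subject_ids)
  efc <- as_stack(efc, "efc")
  pfc <- as_stack(pfc, "pfc")
  if (!is.null(sc)) sc <- as_stack(sc, "sc")
  if (!inherits(folds, "fc_folds")) folds <- fold_partition(folds)

  cohort <- structure(
    list(subject_ids = subject_ids, efc = efc, pfc = pfc, sc = sc, folds = folds),
    class = "fc_cohort"
  )
  findings <- validate_cohort(cohort)
  if (nrow(findings) > 0L) {
    abort_fcbench(
      paste0("invalid cohort:\n", paste0("  [", findings$code, "] ",
                                         findings$message, collapse = "\n")),
      class = paste0("fcbench_error_", findings$code[1L])
    )
  }
  # symmetrize sub-tolerance numerical asymmetry once, after validation
  cohort$efc <- symmetrize_stack(cohort$efc)
  cohort$pfc <- symmetrize_stack(cohort$pfc)
  if (!is.null(cohort$sc)) cohort$sc <- symmetrize_stack(cohort$sc)
  cohort
}

as_stack <- function(x, what) {
  if (is.list(x)) {
    p <- unique(vapply(x, nrow, integer(1)))
    if (length(p) != 1L) {
      abort_fcbench(sprintf("%s matrices differ in dimension", what),
                    class = "fcbench_error_dimension")
    }
    x <- array(unlist(x, use.names = FALSE), dim = c(p, p, length(x)))
  }
  if (!is.array(x) || length(dim(x)) != 3L) {
    abort_fcbench(sprintf("%s must be a p x p x N array or list of matrices", what),
                  class = "fcbench_error_dimension")
  }
  storage.mode(x) <- "double"
  x
}

symmetrize_stack <- function(stack) {
  for (i in seq_len(dim(stack)[3L])) {
    stack[, , i] <- (stack[, , i] + t(stack[, , i])) / 2
  }
  stack
}

#' @export
print.fc_cohort <- function(x, ...) {
  d <- dim(x$efc)
  cat("<fc_cohort> N =", d[3L], "subjects, p =", d[1L], "nodes,",
      "K =", x$folds$K, "folds;",
      if (is.null(x$sc)) "no SC" else "with SC", "\n")
  invisible(x)
}

n_subjects <- function(cohort) dim(cohort$efc)[3L]
n_nodes <- function(cohort) dim(cohort$efc)[1L]

#' Validate a cohort against its structural invariants
#'
#' Checks, without raising: stack alignment (shared `N >= 2`, `p >= 3`),
#' uniqueness of subject ids, finiteness, symmetry within `1e-8`, eFC unit
#' diagonal and off-diagonal range, SC nonnegativity, and fold partition
#' consistency. Intended both as the constructor gate and as a standalone
#' diagnostic for externally assembled cohorts.
#'
#' @param cohort An `fc_cohort`, or a bare list with the same fields.
#'
#' @return A tibble of findings with columns `code`, `subject_id`, `message`;
#'   zero rows iff all invariants hold.
#' @export
validate_cohort <- function(cohort) {
  findings <- list()
  add <- function(code, subject_id, message) {
    findings[[length(findings) + 1L]] <<-
      tibble::tibble(code = code, subject_id = subject_id, message = message)
  }

  ids <- cohort$subject_ids
  if (anyDuplicated(ids)) {
    add("duplicate_subject", ids[duplicated(ids)][1L], "duplicate subject_id")
  }
  dims <- lapply(Filter(Negate(is.null),
                        cohort[c("efc", "pfc", "sc")]), dim)
  if (length(unique(dims)) != 1L) {
    add("dimension", NA_character_, "efc/pfc/sc stacks differ in dimensions")
    return(dplyr::bind_rows(findings))
  }
  d <- dims[[1L]]
  if (d[1L] != d[2L]) add("dimension", NA_character_, "matrices are not square")
  if (d[1L] < 3L) add("dimension", NA_character_, "need p >= 3 nodes")
  if (d[3L] < 2L) add("dimension", NA_character_, "need N >= 2 subjects")
  if (length(ids) != d[3L]) {
    add("dimension", NA_character_, "subject_ids length does not match stacks")
  }
  if (length(cohort$folds$assignment) != d[3L]) {
    add("folds", NA_character_, "fold assignment length does not match N")
  }

  check_stack <- function(stack, name) {
    for (i in seq_len(dim(stack)[3L])) {
      m <- stack[, , i]
      id <- if (i <= length(ids)) ids[i] else NA_character_
      if (any(!is.finite(m))) {
        add("nonfinite", id, sprintf("%s for subject %s has NaN/Inf entries", name, id))
        next
      }
      scale <- max(abs(m), 1)
      if (max(abs(m - t(m))) > 1e-8 * scale) {
        add("asymmetry", id,
            sprintf("%s for subject %s asymmetric beyond 1e-8", name, id))
      }
      if (name == "efc") {
        if (max(abs(diag(m) - 1)) > 1e-8) {
          add("efc_diagonal", id,
              sprintf("efc diagonal for subject %s deviates from 1", id))
        }
        off <- m[upper.tri(m)]
        if (any(off < -1 - 1e-8) || any(off > 1 + 1e-8)) {
          add("efc_range", id,
              sprintf("efc off-diagonal for subject %s outside [-1, 1]", id))
        }
      }
      if (name == "sc" && any(m < 0)) {
        add("sc_negative", id, sprintf("sc for subject %s has negative weights", id))
      }
    }
  }
  check_stack(cohort$efc, "efc")
  check_stack(cohort$pfc, "pfc")
  if (!is.null(cohort$sc)) check_stack(cohort$sc, "sc")

  if (length(findings) == 0L) {
    tibble::tibble(code = character(), subject_id = character(), message = character())
  } else {
    dplyr::bind_rows(findings)
  }
}

abort_fcbench <- function(message, class) {
  rlang::abort(message, class = c(class, "fcbench_error"))
}
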
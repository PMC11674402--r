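#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an identifiability test into per-subject rows
#'
#' @param x An `fc_identifiability`.
#' @param ... Unused.
#' @return A tibble with columns `subject`, `r_intra`, `r_inter`,
#'   `difference` (signed so positive favours the subject's own prediction).
#' @export
tidy.fc_identifiability <- function(x, ...) {
  tibble::tibble(
    subject = seq_along(x$r_intra),
    r_intra = x$r_intra,
    r_inter = x$r_inter,
    difference = signed_diff(x$r_intra, x$r_inter, x$direction)
  )
}

#' One-row summary of an identifiability test
#'
#' @param x An `fc_identifiability`.
#' @param ... Unused.
#' @return A one-row tibble: `mean_intra`, `mean_inter`, `t_statistic`, `df`,
#'   `p_value`, `cohen_d`, `method`, `direction`, `alternative`.
#' @export
glance.fc_identifiability <- function(x, ...) {
  tibble::tibble(
    mean_intra = x$mean_intra, mean_inter = x$mean_inter,
    t_statistic = x$t_statistic, df = x$df, p_value = x$p_value,
    cohen_d = x$cohen_d, method = x$method, direction = x$direction,
    alternative = x$alternative
  )
}

#' @export
glance.fc_permutation <- function(x, ...) {
  tibble::tibble(
    p_value = x$p_value, p_ci_lower = x$p_ci_95[1], p_ci_upper = x$p_ci_95[2],
    t_observed = x$t_observed, n_perm = x$n_perm, method = x$method
  )
}

#' @export
tidy.fc_matching_curve <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.fc_matching_curve <- function(x, ...) {
  tibble::tibble(
    pooled_improvement = mean(x$improvement),
    pooled_improvement_sd = stats::sd(x$improvement),
    n_significant = sum(x$significant),
    n_sizes = nrow(x),
    M = attr(x, "M")
  )
}

#' @export
tidy.fc_report <- function(x, ...) {
  summary_table(x)
}
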
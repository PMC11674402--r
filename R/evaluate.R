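#' Evaluate prediction sources against identifiability benchmarks
#'
#' Runs the full evaluation grid on a cohort: for each prediction source
#' (`pfc`, the group-mean benchmark, the noisy group-mean benchmark, and the
#' structural connectome when present, plus its nonzero-masked variant), each
#' requested measure, and optionally fold-respecting z-scored variants, the
#' intra/inter similarity table, the naive one-sample t test and the
#' fold-constrained permutation test are computed. The predicted source is
#' then compared against both benchmarks with the corrected resampled t test
#' and the per-fold bootstrap, and percent improvements over both benchmarks
#' are reported.
#'
#' @param cohort An [fc_cohort()].
#' @param measures Character subset of `c("pearson", "lerm")`. LERM conditions
#'   always use raw (unstandardized) matrices.
#' @param standardize Also evaluate fold-z-scored Pearson conditions
#'   (default `TRUE`).
#' @param n_perm Permutations for the permutation test (default 1000).
#' @param n_boot Bootstrap resamples per fold (default 2000).
#' @param f Central tendency for fold summaries: `"median"` or `"mean"`.
#' @param spd_floor Eigenvalue floor for LERM projection.
#' @param seed Integer seed controlling the noisy benchmark, permutations and
#'   bootstraps.
#'
#' @return An `fc_report` object: list with `config`, `conditions` (one entry
#'   per source x measure x standardization, each holding the intra/inter
#'   table and test results), and `comparisons` (corrected t and bootstrap
#'   versus each benchmark, plus percent improvements).
#' @export
evaluate_cohort <- function(cohort, measures = c("pearson"),
                            standardize = TRUE, n_perm = 1000, n_boot = 2000,
                            f = c("median", "mean"), spd_floor = 1e-6,
                            seed = 1L) {
  stopifnot(inherits(cohort, "fc_cohort"))
  f <- match.arg(f)
  measures <- match.arg(measures, c("pearson", "lerm"), several.ok = TRUE)
  folds <- cohort$folds
  seeds <- derive_seeds(seed, 4L)

  sources <- list(pfc = cohort$pfc,
                  mean_benchmark = fold_mean_prediction(cohort),
                  noisy_benchmark = noisy_mean_prediction(cohort, seeds[1]))
  if (!is.null(cohort$sc)) sources$sc <- cohort$sc

  conditions <- list()
  # a condition can be undefined (e.g. a z-scored group-mean benchmark whose
  # training predictions are all identical has zero off-diagonal variance);
  # record it as skipped rather than failing the whole grid
  add_condition <- function(name, sim_expr) {
    result <- tryCatch({
      sim <- force(sim_expr)
      tab <- intra_inter(sim, folds, scope = "global")
      naive <- naive_identifiability_test(tab, direction = sim$direction)
      perm <- fold_constrained_permutation_test(sim, folds, n_perm = n_perm,
                                                seed = seeds[2])
      list(similarity = sim, intra_inter = tab, naive = naive,
           permutation = perm, deltas = fold_deltas(sim, folds))
    }, fcbench_error_zero_variance = function(e) {
      list(skipped = TRUE, reason = conditionMessage(e))
    })
    conditions[[name]] <<- result
  }

  for (measure in measures) {
    variants <- if (measure == "pearson" && standardize) c(FALSE, TRUE) else FALSE
    for (z in variants) {
      refs <- if (z) fold_zscore(cohort$efc, folds) else cohort$efc
      for (src in names(sources)) {
        if (measure == "lerm" && src == "sc") next  # LERM defined for FC scale
        preds <- if (z) fold_zscore(sources[[src]], folds) else sources[[src]]
        label <- paste0(src, "_", measure, if (z) "_z" else "_raw")
        add_condition(label, build_similarity(
          preds, refs, measure = measure, spd_floor = spd_floor,
          subject_ids = cohort$subject_ids
        ))
      }
      if (!z && measure == "pearson" && !is.null(cohort$sc)) {
        add_condition("sc_masked_pearson_raw", build_similarity(
          cohort$sc, cohort$efc, measure = "pearson",
          mask_policy = "per_prediction_nonzero",
          subject_ids = cohort$subject_ids
        ))
      }
    }
  }

  sizes <- fold_sizes(folds)
  n_test <- mean(sizes)
  n_train <- n_subjects(cohort) - n_test
  comparisons <- list()
  for (measure in measures) {
    variants <- if (measure == "pearson" && standardize) c("_raw", "_z") else "_raw"
    for (v in variants) {
      model_names <- intersect(paste0(c("pfc", "sc"), "_", measure, v),
                               names(conditions))
      for (model in model_names) {
        for (bench in paste0(c("mean_benchmark", "noisy_benchmark"),
                             "_", measure, v)) {
          if (!bench %in% names(conditions)) next
          if (isTRUE(conditions[[model]]$skipped) ||
              isTRUE(conditions[[bench]]$skipped)) next
          key <- paste0(model, "_vs_", bench)
          dm <- conditions[[model]]$deltas
          db <- conditions[[bench]]$deltas
          comparisons[[key]] <- list(
            corrected_t = corrected_resampled_t(dm, db, n_test, n_train, f = f),
            bootstrap = fold_bootstrap_comparison(dm, db, n_boot = n_boot,
                                                  seed = seeds[3], f = f),
            percent_improvement = tryCatch(
              percent_improvement(conditions[[model]]$naive$mean_intra,
                                  conditions[[bench]]$naive$mean_intra),
              fcbench_error = function(e) NA_real_
            )
          )
        }
      }
    }
  }

  structure(
    list(
      config = list(measures = measures, standardize = standardize,
                    n_perm = n_perm, n_boot = n_boot, f = f,
                    spd_floor = spd_floor, seed = seed,
                    n_subjects = n_subjects(cohort), n_nodes = n_nodes(cohort),
                    K = folds$K,
                    version = as.character(utils::packageVersion("fcbench"))),
      conditions = conditions,
      comparisons = comparisons
    ),
    class = "fc_report"
  )
}

derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' @export
print.fc_report <- function(x, ...) {
  cat("<fc_report>", length(x$conditions), "conditions,",
      length(x$comparisons), "comparisons\n")
  print(summary_table(x))
  invisible(x)
}

summary_table <- function(report) {
  purrr::imap_dfr(report$conditions, function(cond, name) {
    if (isTRUE(cond$skipped)) {
      return(tibble::tibble(condition = name, mean_intra = NA_real_,
                            mean_inter = NA_real_, t = NA_real_, df = NA_real_,
                            p_naive = NA_real_, p_perm = NA_real_,
                            cohen_d = NA_real_))
    }
    tibble::tibble(
      condition = name,
      mean_intra = cond$naive$mean_intra,
      mean_inter = cond$naive$mean_inter,
      t = cond$naive$t_statistic,
      df = cond$naive$df,
      p_naive = cond$naive$p_value,
      p_perm = cond$permutation$p_value,
      cohen_d = cond$naive$cohen_d
    )
  })
}

#' Write an evaluation report as JSON
#'
#' Serializes the condition summaries, comparison statistics and the run
#' configuration (seeds included, for provenance) to a JSON file; the heavy
#' similarity matrices themselves are omitted.
#'
#' @param report An `fc_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  conditions <- purrr::map(report$conditions, function(cond) {
    if (isTRUE(cond$skipped)) {
      return(list(skipped = TRUE, reason = cond$reason))
    }
    list(
      measure = cond$similarity$measure,
      direction = cond$similarity$direction,
      mean_intra = cond$naive$mean_intra,
      mean_inter = cond$naive$mean_inter,
      naive = cond$naive[c("t_statistic", "df", "p_value", "cohen_d")],
      permutation = list(p_value = cond$permutation$p_value,
                         p_ci_95 = cond$permutation$p_ci_95,
                         n_perm = cond$permutation$n_perm)
    )
  })
  comparisons <- purrr::map(report$comparisons, function(cmp) {
    list(
      corrected_t = cmp$corrected_t[c("t_statistic", "p_value", "df", "f")],
      bootstrap = list(
        n_significant = attr(cmp$bootstrap, "n_significant"),
        folds = as.data.frame(cmp$bootstrap)
      ),
      percent_improvement = cmp$percent_improvement
    )
  })
  jsonlite::write_json(
    list(config = report$config, conditions = conditions,
         comparisons = comparisons),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(path)
}
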
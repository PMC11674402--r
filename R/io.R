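#' Load a cohort from a manifest file
#'
#' The manifest is a UTF-8 tab-separated table with a header row and columns
#' `subject_id`, `fold`, `efc_path`, `pfc_path` and (optionally) `sc_path`.
#' Each referenced file is a headerless delimited square numeric matrix
#' (comma- or tab-delimited, auto-detected). Relative paths are resolved
#' against the manifest's directory. Subject order follows manifest row order;
#' fold labels must form a `1..K` partition.
#'
#' @param manifest_path Path to the manifest file.
#'
#' @return A validated [fc_cohort()].
#' @export
#' @seealso [write_cohort()]
load_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    abort_fcbench(sprintf("manifest not found: %s", manifest_path),
                  class = "fcbench_error_missing_file")
  }
  manifest <- utils::read.delim(manifest_path, sep = "\t",
                                stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("subject_id", "fold", "efc_path", "pfc_path")
  if (!all(required %in% names(manifest))) {
    abort_fcbench(
      sprintf("manifest must have columns %s", paste(required, collapse = ", ")),
      class = "fcbench_error_manifest"
    )
  }
  base <- dirname(manifest_path)
  has_sc <- "sc_path" %in% names(manifest) &&
    !all(is.na(manifest$sc_path) | manifest$sc_path == "")

  read_stack <- function(paths, what) {
    mats <- vector("list", length(paths))
    for (i in seq_along(paths)) {
      path <- paths[i]
      if (!file.exists(path)) path <- file.path(base, paths[i])
      if (!file.exists(path)) {
        abort_fcbench(
          sprintf("%s file for subject %s not found: %s",
                  what, manifest$subject_id[i], paths[i]),
          class = "fcbench_error_missing_file"
        )
      }
      m <- read_matrix_file(path)
      if (nrow(m) != ncol(m)) {
        abort_fcbench(
          sprintf("%s matrix for subject %s is not square (%d x %d)",
                  what, manifest$subject_id[i], nrow(m), ncol(m)),
          class = "fcbench_error_dimension"
        )
      }
      mats[[i]] <- m
    }
    p <- unique(vapply(mats, nrow, integer(1)))
    if (length(p) != 1L) {
      bad <- manifest$subject_id[which(vapply(mats, nrow, integer(1)) != p[1L])[1L]]
      abort_fcbench(
        sprintf("%s matrix dimension mismatch across subjects (first offender: %s)",
                what, bad),
        class = "fcbench_error_dimension"
      )
    }
    array(unlist(mats, use.names = FALSE), dim = c(p, p, length(mats)))
  }

  efc <- read_stack(manifest$efc_path, "efc")
  pfc <- read_stack(manifest$pfc_path, "pfc")
  sc <- if (has_sc) read_stack(manifest$sc_path, "sc") else NULL

  fc_cohort(
    subject_ids = manifest$subject_id,
    efc = efc, pfc = pfc, sc = sc,
    folds = fold_partition(manifest$fold)
  )
}

# headerless square numeric matrix, comma- or tab-delimited (auto-detected)
read_matrix_file <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

write_matrix_file <- function(m, path) {
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

#' Write a cohort to a directory
#'
#' Serializes one matrix file per subject per modality (tab-delimited, named
#' deterministically from `subject_id`) plus a tab-separated manifest, the
#' inverse of [load_cohort()]: a write/load round trip reproduces all matrix
#' entries to better than `1e-12`.
#'
#' @param cohort An `fc_cohort`.
#' @param directory Output directory (created if absent).
#'
#' @return The manifest path, invisibly usable with [load_cohort()].
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "fc_cohort"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    abort_fcbench(sprintf("cannot create directory %s", directory),
                  class = "fcbench_error_unwritable")
  }
  safe <- gsub("[^A-Za-z0-9_.-]", "_", cohort$subject_ids)
  rows <- vector("list", length(cohort$subject_ids))
  for (i in seq_along(cohort$subject_ids)) {
    efc_file <- paste0(safe[i], "_efc.tsv")
    pfc_file <- paste0(safe[i], "_pfc.tsv")
    write_matrix_file(cohort$efc[, , i], file.path(directory, efc_file))
    write_matrix_file(cohort$pfc[, , i], file.path(directory, pfc_file))
    sc_file <- ""
    if (!is.null(cohort$sc)) {
      sc_file <- paste0(safe[i], "_sc.tsv")
      write_matrix_file(cohort$sc[, , i], file.path(directory, sc_file))
    }
    rows[[i]] <- data.frame(
      subject_id = cohort$subject_ids[i],
      fold = cohort$folds$assignment[i],
      efc_path = efc_file, pfc_path = pfc_file, sc_path = sc_file,
      stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(directory, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest_path)
}
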
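# On-disk conventions: every matrix is TSV with one header row of 0-based
# vertex indices (v0, v1, ...) and a leading subject_id column. Doubles are
# written with 17 significant digits and parsed with base strtod, which is
# correctly rounded, so write -> read is bit-exact.

fmt_cell <- function(x) {
  if (is.double(x)) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NA"
    out
  } else {
    as.character(x)
  }
}

# exact TSV writer for cohort artifacts (round-trip fidelity matters there)
write_tsv_exact <- function(df, path) {
  cols <- lapply(df, fmt_cell)
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(cols, sep = "\t")))
  writeLines(lines, path)
}

read_tsv_exact <- function(path) {
  tb <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  tibble::as_tibble(tb)
}

matrix_to_df <- function(X, subject_ids) {
  df <- as.data.frame(X)
  names(df) <- paste0("v", seq_len(ncol(X)) - 1L)
  cbind(data.frame(subject_id = subject_ids, stringsAsFactors = FALSE), df)
}

read_metric_matrix <- function(path, metric_name) {
  tb <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (!"subject_id" %in% names(tb)) {
    rlang::abort(paste0("Metric file '", path, "' lacks a subject_id column."))
  }
  ids <- tb$subject_id
  raw <- as.matrix(tb[, setdiff(names(tb), "subject_id"), drop = FALSE])
  X <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  if (any(is.na(X))) {
    bad <- which(is.na(X), arr.ind = TRUE)[1, ]
    rlang::abort(paste0("Non-numeric or missing cell in metric '", metric_name,
                        "' (", path, ") at row ", bad[1], ", column ",
                        bad[2], "."))
  }
  rownames(X) <- ids
  X
}

#' Read a cohort from a manifest
#'
#' The manifest is a YAML file listing the cohort name, the subject order,
#' one matrix file per metric, and optional qc/demographics tables. Paths are
#' resolved relative to the manifest. The manifest's subject list is the
#' authoritative order: every matrix and table must list exactly those
#' subjects in that order — mismatches are hard errors naming the offending
#' file, never silently reordered.
#'
#' @param manifest_path Path to the manifest YAML.
#' @return A [cohort_bundle()].
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(manifest_path) {
  man <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  for (field in c("cohort", "subjects", "metrics")) {
    if (is.null(man[[field]])) {
      rlang::abort(paste0("Manifest lacks required field '", field, "'."))
    }
  }
  subject_ids <- as.character(man$subjects)
  metrics <- list()
  for (m in names(man$metrics)) {
    path <- file.path(base, man$metrics[[m]])
    X <- read_metric_matrix(path, m)
    if (nrow(X) != length(subject_ids) ||
        !identical(rownames(X), subject_ids)) {
      rlang::abort(paste0("Metric '", m, "' (", path, ") does not match the ",
                          "manifest subject list (", nrow(X), " vs ",
                          length(subject_ids), " subjects, or wrong order)."))
    }
    metrics[[m]] <- X
  }
  read_table_checked <- function(field) {
    if (is.null(man[[field]])) return(NULL)
    path <- file.path(base, man[[field]])
    tb <- read_tsv_exact(path)
    tb$subject_id <- as.character(tb$subject_id)
    if (!identical(tb$subject_id, subject_ids)) {
      rlang::abort(paste0("Table '", path,
                          "' does not match the manifest subject list."))
    }
    tb
  }
  cohort_bundle(man$cohort, subject_ids, metrics,
                qc = read_table_checked("qc"),
                demographics = read_table_checked("demographics"))
}

#' Write a cohort and its manifest
#'
#' Inverse of [read_cohort()]: writes one TSV per metric, optional qc and
#' demographics tables, and a `manifest.yaml` tying them together.
#'
#' @param bundle A [cohort_bundle()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) rlang::abort(paste0("Cannot create directory ", dir))
  man <- list(cohort = bundle$name, subjects = as.list(bundle$subject_ids),
              metrics = list())
  for (m in names(bundle$metrics)) {
    f <- paste0(bundle$name, "_", m, ".tsv")
    write_tsv_exact(matrix_to_df(bundle$metrics[[m]], bundle$subject_ids),
                    file.path(dir, f))
    man$metrics[[m]] <- f
  }
  for (field in c("qc", "demographics")) {
    if (!is.null(bundle[[field]])) {
      f <- paste0(bundle$name, "_", field, ".tsv")
      write_tsv_exact(bundle[[field]], file.path(dir, f))
      man[[field]] <- f
    }
  }
  path <- file.path(dir, paste0(bundle$name, "_manifest.yaml"))
  yaml::write_yaml(man, path)
  invisible(path)
}

write_matrix_tsv <- function(M, path, rownames_col = "row") {
  tb <- tibble::as_tibble(M, .name_repair = "minimal")
  if (!is.null(rownames(M))) {
    tb <- dplyr::bind_cols(
      tibble::tibble(!!rownames_col := rownames(M)), tb)
  }
  readr::write_tsv(tb, path, progress = FALSE)
}

#' Write pipeline outputs to a directory
#'
#' Writes whatever stage outputs are present in `results` under deterministic
#' file names: the MMCU membership and per-unit statistics as one tabular
#' summary, one co-variance matrix TSV per unit, validation, overall-summary,
#' test, dendrogram and demographic tables, plus a machine-readable
#' `run_log.json` with the configuration, seeds, and provenance fields.
#'
#' @param results Named list; recognized elements: `mmcus` (`mmcu_set`),
#'   `validation` (`validation_report`), `overall` (`overall_covariance`),
#'   `tests` (tibble), `dendrogram` (`hclust`), `demographics` (tibble),
#'   `recovery` (`recovery_report`), `seed`, `config` (any list).
#' @param out_dir Output directory.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    rlang::abort(paste0("Cannot create directory ", out_dir))
  }
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) rlang::abort(paste0("Directory not writable: ", out_dir))
  unlink(probe)
  written <- character(0)
  put <- function(name) {
    written <<- c(written, name)
    file.path(out_dir, name)
  }
  if (!is.null(results$mmcus)) {
    mm <- results$mmcus
    summary_tbl <- mmcu_membership(mm)
    if (!is.null(results$validation)) {
      summary_tbl <- dplyr::left_join(summary_tbl,
                                      results$validation$units,
                                      by = "unit_id")
    }
    readr::write_tsv(summary_tbl, put("mmcu_membership.tsv"), progress = FALSE)
    for (u in mm$units) {
      write_matrix_tsv(u$covariance,
                       put(sprintf("mmcu_%03d_covariance.tsv", u$unit_id)),
                       rownames_col = "metric")
    }
    if (!is.null(mm$fsm$popularity)) {
      readr::write_tsv(tibble::tibble(scm = mm$fsm$scm_labels,
                                      popularity = mm$fsm$popularity),
                       put("popularity.tsv"), progress = FALSE)
      write_matrix_tsv(mm$fsm$sims, put("fsm.tsv"), rownames_col = "scm")
    }
  }
  if (!is.null(results$validation)) {
    readr::write_tsv(tibble::tibble(null_icc = results$validation$null_icc),
                     put("null_icc.tsv"), progress = FALSE)
  }
  if (!is.null(results$overall)) {
    write_matrix_tsv(results$overall$z_matrix, put("overall_z.tsv"),
                     rownames_col = "metric")
    write_matrix_tsv(results$overall$support, put("support.tsv"),
                     rownames_col = "metric")
  }
  if (!is.null(results$tests)) {
    readr::write_tsv(results$tests, put("tests.tsv"), progress = FALSE)
  }
  if (!is.null(results$dendrogram)) {
    hc <- results$dendrogram
    readr::write_tsv(tibble::tibble(step = seq_along(hc$height),
                                    merge_a = hc$merge[, 1],
                                    merge_b = hc$merge[, 2],
                                    height = hc$height),
                     put("dendrogram.tsv"), progress = FALSE)
  }
  if (!is.null(results$demographics)) {
    readr::write_tsv(results$demographics, put("demographics.tsv"),
                     progress = FALSE)
  }
  if (!is.null(results$recovery)) {
    readr::write_tsv(glance(results$recovery), put("recovery.tsv"),
                     progress = FALSE)
  }
  log <- list(
    package = "covunits",
    package_version = as.character(utils::packageVersion("covunits")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = results$seed,
    config = results$config,
    files = written
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  written <- c(written, "run_log.json")
  invisible(written)
}

#' Read a flat run configuration
#'
#' A single flat key-value YAML file; every recognized key maps onto an
#' argument of [synthetic_config()] or a pipeline option, and every stochastic
#' operation takes its seed from it. Unknown keys are an error so typos fail
#' loudly.
#'
#' @param path YAML file path.
#' @return Named list of options.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("n_discover", "n_confirm", "v", "metrics",
               "components_per_metric", "n_units", "rho", "replicable",
               "snr", "sparsity", "seed", "k", "n_perm", "fair_threshold",
               "percentile", "alpha", "row_standardize", "min_standardized",
               "recompute_rank")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    rlang::abort(paste0("Unknown config key(s): ",
                        paste(unknown, collapse = ", ")))
  }
  cfg
}
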
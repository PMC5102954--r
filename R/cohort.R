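#' Construct a cohort bundle
#'
#' A cohort bundle holds everything the pipeline needs for one sample: one
#' subjects-by-vertices matrix per metric (all sharing the same subjects in the
#' same order), optional per-subject acquisition QC scalars, and optional
#' demographics. Vertices are opaque ordered features (0-based indices in the
#' on-disk format); no mesh geometry is carried.
#'
#' @param name Cohort label, e.g. `"discover"`.
#' @param subject_ids Character vector of subject identifiers; defines the row
#'   order enforced across every metric matrix and table.
#' @param metrics Named list of numeric matrices, one per metric, each
#'   `length(subject_ids)` rows by `v` columns with identical `v`.
#' @param qc Optional tibble with columns `subject_id`, `maxTran` (mm),
#'   `maxRot` (degrees), `meanFD` (mm), `mcBBR` (unitless). Missing values are
#'   treated as failing downstream.
#' @param demographics Optional tibble with columns `subject_id`, `age`
#'   (years), `sex` (0/1), `handedness` (0/1). Missing values are permitted
#'   and flagged.
#' @return An object of class `cohort_bundle`.
#' @examples
#' m <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("s", 1:4), NULL))
#' cohort_bundle("demo", paste0("s", 1:4), list(thick = m))
#' @export
cohort_bundle <- function(name, subject_ids, metrics, qc = NULL,
                          demographics = NULL) {
  stopifnot(is.character(subject_ids), length(subject_ids) > 0,
            is.list(metrics), length(metrics) > 0)
  if (is.null(names(metrics)) || any(names(metrics) == "")) {
    rlang::abort("`metrics` must be a fully named list of matrices.")
  }
  n <- length(subject_ids)
  v <- ncol(metrics[[1]])
  for (m in names(metrics)) {
    x <- metrics[[m]]
    if (!is.matrix(x) || !is.numeric(x)) {
      rlang::abort(paste0("Metric '", m, "' is not a numeric matrix."))
    }
    if (nrow(x) != n) {
      rlang::abort(paste0("Metric '", m, "' has ", nrow(x),
                          " subjects; expected ", n, "."))
    }
    if (ncol(x) != v) {
      rlang::abort(paste0("Metric '", m, "' has ", ncol(x),
                          " vertices; expected ", v, "."))
    }
    if (any(!is.finite(x))) {
      rlang::abort(paste0("Metric '", m, "' contains non-finite values."))
    }
    rownames(metrics[[m]]) <- subject_ids
  }
  for (tbl_name in c("qc", "demographics")) {
    tbl <- get(tbl_name)
    if (!is.null(tbl)) {
      tbl <- tibble::as_tibble(tbl)
      if (!"subject_id" %in% names(tbl)) {
        rlang::abort(paste0("`", tbl_name, "` must have a subject_id column."))
      }
      if (!identical(as.character(tbl$subject_id), subject_ids)) {
        rlang::abort(paste0("`", tbl_name,
                            "` rows do not align one-to-one with subject_ids."))
      }
      assign(tbl_name, tbl)
    }
  }
  structure(
    list(name = name, subject_ids = subject_ids, metrics = metrics,
         qc = qc, demographics = demographics),
    class = "cohort_bundle"
  )
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle> '", x$name, "': ", length(x$subject_ids),
      " subjects x ", ncol(x$metrics[[1]]), " vertices; metrics: ",
      paste(names(x$metrics), collapse = ", "), "\n", sep = "")
  cat("  qc: ", if (is.null(x$qc)) "absent" else "present",
      "; demographics: ",
      if (is.null(x$demographics)) "absent" else "present", "\n", sep = "")
  invisible(x)
}

#' Number of subjects / vertices in a cohort bundle
#' @param bundle A `cohort_bundle`.
#' @return Integer.
#' @export
n_subjects <- function(bundle) length(bundle$subject_ids)

#' @rdname n_subjects
#' @export
n_vertices <- function(bundle) ncol(bundle$metrics[[1]])

#' Restrict a cohort bundle to a subject subset
#'
#' Used after QC filtering; preserves the original relative order.
#'
#' @param bundle A `cohort_bundle`.
#' @param subject_ids Subjects to keep.
#' @return A new `cohort_bundle`.
#' @export
subset_subjects <- function(bundle, subject_ids) {
  keep <- bundle$subject_ids[bundle$subject_ids %in% subject_ids]
  idx <- match(keep, bundle$subject_ids)
  cohort_bundle(
    name = bundle$name,
    subject_ids = keep,
    metrics = lapply(bundle$metrics, function(m) m[idx, , drop = FALSE]),
    qc = if (is.null(bundle$qc)) NULL else bundle$qc[idx, ],
    demographics = if (is.null(bundle$demographics)) NULL else
      bundle$demographics[idx, ]
  )
}
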
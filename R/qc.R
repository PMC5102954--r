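#' Generalized extreme Studentized deviate (ESD) outlier test
#'
#' Rosner's generalized ESD test for up to `max_outliers` outliers in a
#' univariate sample. At step `i` the most extreme studentized value
#' `R_i = max |x - mean| / sd` (over the remaining values) is removed and
#' compared against the critical value
#' `lambda_i = (n - i) * t / sqrt((n - i - 1 + t^2) * (n - i + 1))` with
#' `t` the upper `alpha / (2 (n - i + 1))` quantile of the t-distribution on
#' `n - i - 1` degrees of freedom. The largest `i` with `R_i > lambda_i`
#' fixes the number of outliers; all values removed up to that step are
#' flagged.
#'
#' @param values Numeric vector, length >= 10.
#' @param alpha Significance level in (0, 1).
#' @param max_outliers Upper bound on the number of outliers tested
#'   (default `max(1, ceiling(0.05 * n))`, must be `< n / 2`).
#' @return Integer vector of flagged indices into `values` (possibly empty).
#'   A constant series (zero SD at the first step) yields an empty set.
#' @examples
#' x <- c(rnorm(49), 10)
#' esd_outliers(x, alpha = 0.001)
#' @export
esd_outliers <- function(values, alpha = 0.001,
                         max_outliers = max(1L, ceiling(0.05 * length(values)))) {
  n <- length(values)
  if (n < 10) rlang::abort("esd_outliers requires at least 10 values.")
  if (!(alpha > 0 && alpha < 1)) {
    if (alpha == 0) return(integer(0))  # degenerate: no test can reject
    rlang::abort("alpha must lie in (0, 1).")
  }
  if (max_outliers < 1 || max_outliers >= n / 2) {
    rlang::abort("max_outliers must satisfy 1 <= max_outliers < n/2.")
  }
  remaining <- seq_len(n)
  removed <- integer(max_outliers)
  R <- numeric(max_outliers)
  lambda <- numeric(max_outliers)
  n_steps <- 0L
  for (i in seq_len(max_outliers)) {
    x <- values[remaining]
    s <- sd(x)
    if (!is.finite(s) || s == 0) break
    dev <- abs(x - mean(x))
    j <- which.max(dev)
    R[i] <- dev[j] / s
    ni <- n - i + 1L                       # sample size at this step
    p <- 1 - alpha / (2 * ni)
    tq <- qt(p, df = ni - 2L)
    lambda[i] <- (ni - 1L) * tq / sqrt((ni - 2L + tq^2) * ni)
    removed[i] <- remaining[j]
    remaining <- remaining[-j]
    n_steps <- i
  }
  if (n_steps == 0L) return(integer(0))
  hits <- which(R[seq_len(n_steps)] > lambda[seq_len(n_steps)])
  if (length(hits) == 0) return(integer(0))
  sort(removed[seq_len(max(hits))])
}

new_qc_report <- function(retained_ids, excluded) {
  structure(list(retained_ids = retained_ids, excluded = excluded),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> retained ", length(x$retained_ids), ", excluded ",
      nrow(x$excluded), "\n", sep = "")
  if (nrow(x$excluded) > 0) print(x$excluded)
  invisible(x)
}

#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(subject_id = x$retained_ids, retained = TRUE,
                   reason = NA_character_),
    dplyr::mutate(x$excluded, retained = FALSE)
  )
}

#' Exclude subjects with aberrant metric values at any vertex
#'
#' Applies [esd_outliers()] per vertex per listed metric across subjects. A
#' subject flagged at one or more (metric, vertex) combinations is excluded.
#'
#' @param cohort A [cohort_bundle()].
#' @param structural_metrics Metric names to screen (default: every metric of
#'   class `"structural"` present in the cohort).
#' @param alpha Per-vertex ESD significance level.
#' @param max_outliers Passed to [esd_outliers()].
#' @return A `qc_report` with `retained_ids` and an `excluded` tibble
#'   (`subject_id`, `reason`) where the reason names the first offending
#'   metric and 0-based vertex.
#' @export
structural_outlier_filter <- function(cohort,
                                      structural_metrics = NULL,
                                      alpha = 0.001,
                                      max_outliers = NULL) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  if (is.null(structural_metrics)) {
    d <- default_metrics()
    structural_metrics <- intersect(d$metric[d$class == "structural"],
                                    names(cohort$metrics))
  }
  n <- n_subjects(cohort)
  if (is.null(max_outliers)) max_outliers <- max(1L, ceiling(0.05 * n))
  first_reason <- rep(NA_character_, n)
  for (m in structural_metrics) {
    X <- cohort$metrics[[m]]
    for (j in seq_len(ncol(X))) {
      out <- esd_outliers(X[, j], alpha = alpha, max_outliers = max_outliers)
      hit <- out[is.na(first_reason[out])]
      if (length(hit) > 0) {
        first_reason[hit] <- paste0("esd_outlier:", m, ":", j - 1L)
      }
    }
  }
  bad <- which(!is.na(first_reason))
  new_qc_report(
    retained_ids = cohort$subject_ids[setdiff(seq_len(n), bad)],
    excluded = tibble::tibble(subject_id = cohort$subject_ids[bad],
                              reason = first_reason[bad])
  )
}

#' Default functional acquisition QC thresholds
#'
#' Inclusive upper bounds on the four per-subject acquisition scalars:
#' maximum translational head movement (mm), maximum rotation (degrees),
#' mean frame-wise displacement (mm), and the minimal cost of boundary-based
#' functional-structural registration (unitless).
#'
#' @return Named numeric vector.
#' @export
qc_thresholds <- function() {
  c(maxTran = 2, maxRot = 2, meanFD = 0.2, mcBBR = 0.75)
}

#' Threshold-based functional QC filter
#'
#' Retains subjects whose four acquisition scalars all satisfy the inclusive
#' bounds (`value <= threshold`). A missing scalar excludes the subject with
#' reason `"missing_qc"`; otherwise the reason names the first failed
#' threshold.
#'
#' @param cohort A [cohort_bundle()] with a `qc` table.
#' @param thresholds Named vector as in [qc_thresholds()].
#' @return A `qc_report`.
#' @export
functional_qc_filter <- function(cohort, thresholds = qc_thresholds()) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  if (is.null(cohort$qc)) rlang::abort("Cohort has no qc table.")
  qc <- cohort$qc
  missing_cols <- setdiff(names(thresholds), names(qc))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("qc table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  reason <- rep(NA_character_, nrow(qc))
  for (nm in names(thresholds)) {
    x <- qc[[nm]]
    fail <- is.na(reason) & (is.na(x) | x > thresholds[[nm]])
    reason[fail] <- ifelse(is.na(x[fail]), "missing_qc", nm)
  }
  bad <- which(!is.na(reason))
  new_qc_report(
    retained_ids = cohort$subject_ids[setdiff(seq_along(reason), bad)],
    excluded = tibble::tibble(subject_id = cohort$subject_ids[bad],
                              reason = reason[bad])
  )
}
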
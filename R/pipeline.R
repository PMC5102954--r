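#' Run the full discover-confirm pipeline
#'
#' Convenience wrapper chaining every stage on a pair of cohorts:
#' optional QC filtering, per-metric spatial ICA in the discover cohort,
#' alignment of the resulting surface component maps into multi-metric
#' co-variance units, confirm-cohort validation (ICC + permutation null),
#' overall summary (Fisher-Z matrix, pair-group tests, metric clustering),
#' and the demographic scan over reliable units.
#'
#' @param discover,confirm [cohort_bundle()]s sharing metrics and vertex
#'   count.
#' @param k `NULL` for Laplace order selection or fixed order(s), see
#'   [decompose_cohort()].
#' @param seed Integer seed controlling ICA initialization and the
#'   permutation null.
#' @param apply_qc Run [functional_qc_filter()] (when qc tables are present)
#'   and [structural_outlier_filter()] before decomposition.
#' @param structural_alpha Per-vertex ESD level for the structural filter.
#' @param n_perm Permutation replicates for the null.
#' @param fair_threshold,percentile Reliability thresholds, see
#'   [classify_reliability()].
#' @param classes Optional metric -> class map for the pair-group tests.
#' @param demographics_on Which units enter the demographic scan:
#'   `"reliable"` (fair or significant; default), `"significant"`, or
#'   `"all"`.
#' @return A `covunit_pipeline` list: `decompositions`, `mmcus`,
#'   `validation`, `overall`, `tests`, `dendrogram`, `demographics`, `qc`
#'   (per-cohort reports or `NULL`), `seed`.
#' @export
run_pipeline <- function(discover, confirm, k = NULL, seed = 1L,
                         apply_qc = FALSE, structural_alpha = 0.001,
                         n_perm = 1000L, fair_threshold = 0.4,
                         percentile = 95.5, classes = NULL,
                         demographics_on = c("reliable", "significant",
                                             "all")) {
  demographics_on <- match.arg(demographics_on)
  qc_reports <- NULL
  if (apply_qc) {
    qc_reports <- list()
    for (role in c("discover", "confirm")) {
      bundle <- get(role)
      keep <- bundle$subject_ids
      if (!is.null(bundle$qc)) {
        rep_f <- functional_qc_filter(bundle)
        keep <- intersect(keep, rep_f$retained_ids)
        qc_reports[[paste0(role, "_functional")]] <- rep_f
      }
      rep_s <- structural_outlier_filter(bundle, alpha = structural_alpha)
      keep <- intersect(keep, rep_s$retained_ids)
      qc_reports[[paste0(role, "_structural")]] <- rep_s
      assign(role, subset_subjects(bundle, keep))
    }
  }
  decomps <- decompose_cohort(discover, k = k, seed = seed)
  mmcus <- graicar_align(decomps)
  validation <- validate_mmcus(mmcus, decomps, confirm, n_perm = n_perm,
                               seed = seed, fair_threshold = fair_threshold,
                               percentile = percentile)
  retained_ids <- validation$units$unit_id[validation$units$label !=
                                             "unreliable"]
  retained <- mmcus$units[vapply(mmcus$units, `[[`, integer(1), "unit_id")
                          %in% retained_ids]
  overall <- if (length(retained) > 0) {
    overall_covariance(retained, metrics = mmcus$fsm$metric_levels)
  } else NULL
  tests <- if (!is.null(overall)) {
    tryCatch(pair_group_tests(overall, classes = classes),
             error = function(e) NULL)
  } else NULL
  dendro <- if (!is.null(overall)) {
    suppressWarnings(cluster_metrics(overall))
  } else NULL
  demo_units <- switch(demographics_on,
    all = mmcus$units,
    reliable = retained,
    significant = mmcus$units[vapply(mmcus$units, `[[`, integer(1),
                                     "unit_id") %in%
      validation$units$unit_id[validation$units$label == "significant"]])
  demo <- if (length(demo_units) > 0 && !is.null(discover$demographics)) {
    demographic_scan(demo_units, decomps, discover$demographics)
  } else NULL
  structure(list(decompositions = decomps, mmcus = mmcus,
                 validation = validation, overall = overall, tests = tests,
                 dendrogram = dendro, demographics = demo, qc = qc_reports,
                 seed = seed),
            class = "covunit_pipeline")
}

#' @export
print.covunit_pipeline <- function(x, ...) {
  cat("<covunit_pipeline>\n")
  print(glance(x$mmcus))
  print(glance(x$validation))
  invisible(x)
}
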
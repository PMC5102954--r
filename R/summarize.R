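#' Overall inter-metric co-variance matrix across retained units
#'
#' For each metric pair, averages the Fisher-Z transformed subject-course
#' correlations over the units in which both metrics are members. A support
#' matrix records how many units contributed to each cell; pairs supported by
#' no unit are `NA` and flagged.
#'
#' @param mmcus An `mmcu_set`, or a plain list of units (each with `members`
#'   and `covariance`), e.g. the retained subset after validation.
#' @param metrics Metric order for the output (default: the fsm's metric
#'   levels, or the union of member metrics).
#' @return An `overall_covariance`: list with `z_matrix` (mean Fisher-Z,
#'   symmetric, `NA` diagonal), `support` (counts), `pair_z` (tibble of
#'   per-unit pair values: `unit_id`, `metric_i`, `metric_j`, `r`, `z`), and
#'   `metrics`.
#' @export
overall_covariance <- function(mmcus, metrics = NULL) {
  units <- if (inherits(mmcus, "mmcu_set")) mmcus$units else mmcus
  if (length(units) == 0) rlang::abort("Need at least one retained unit.")
  if (is.null(metrics)) {
    metrics <- if (inherits(mmcus, "mmcu_set")) mmcus$fsm$metric_levels else
      unique(unlist(lapply(units, function(u) names(u$members))))
  }
  q <- length(metrics)
  zsum <- matrix(0, q, q, dimnames = list(metrics, metrics))
  support <- matrix(0L, q, q, dimnames = list(metrics, metrics))
  pair_rows <- list()
  for (u in units) {
    mem <- names(u$members)
    cv <- u$covariance
    if (length(mem) < 2) next
    cmb <- utils::combn(length(mem), 2)
    r <- cv[cbind(cmb[1, ], cmb[2, ])]
    z <- fisher_z(r)
    mi <- mem[cmb[1, ]]; mj <- mem[cmb[2, ]]
    pair_rows[[length(pair_rows) + 1L]] <- tibble::tibble(
      unit_id = u$unit_id, metric_i = mi, metric_j = mj, r = r, z = z)
    for (t in seq_along(r)) {
      zsum[mi[t], mj[t]] <- zsum[mi[t], mj[t]] + z[t]
      zsum[mj[t], mi[t]] <- zsum[mj[t], mi[t]] + z[t]
      support[mi[t], mj[t]] <- support[mi[t], mj[t]] + 1L
      support[mj[t], mi[t]] <- support[mj[t], mi[t]] + 1L
    }
  }
  z_matrix <- ifelse(support > 0, zsum / pmax(support, 1L), NA_real_)
  diag(z_matrix) <- NA_real_
  structure(list(z_matrix = z_matrix, support = support,
                 pair_z = dplyr::bind_rows(pair_rows), metrics = metrics),
            class = "overall_covariance")
}

#' @export
print.overall_covariance <- function(x, ...) {
  cat("<overall_covariance> ", length(x$metrics), " metrics, ",
      length(unique(x$pair_z$unit_id)), " units; mean r = ",
      round(mean(tanh(x$pair_z$z)), 3), "\n", sep = "")
  invisible(x)
}

#' @method tidy overall_covariance
#' @export
tidy.overall_covariance <- function(x, ...) {
  q <- length(x$metrics)
  idx <- which(upper.tri(x$z_matrix), arr.ind = TRUE)
  tibble::tibble(
    metric_i = x$metrics[idx[, 1]], metric_j = x$metrics[idx[, 2]],
    mean_z = x$z_matrix[idx], mean_r = tanh(x$z_matrix[idx]),
    support = x$support[idx]
  )
}

# per-pair mean Fisher-Z over supporting units, with pair-group labels
pair_group_table <- function(overall, classes = NULL) {
  tidy(overall) |>
    dplyr::mutate(
      class_i = metric_class_of(.data$metric_i, classes),
      class_j = metric_class_of(.data$metric_j, classes),
      group = dplyr::case_when(
        .data$class_i == "structural" & .data$class_j == "structural" ~
          "within_structural",
        .data$class_i == "functional" & .data$class_j == "functional" ~
          "within_functional",
        TRUE ~ "cross"
      )
    )
}

#' Pair-group t tests on the overall co-variance matrix
#'
#' Each metric pair contributes one value: its mean Fisher-Z over supporting
#' units. One-sample t-tests ask whether mean pair-group Z exceeds zero for
#' (a) all unique pairs and (b) the structure-function (cross) pairs. Welch
#' two-sample tests (Satterthwaite fractional df) compare within-structural
#' vs cross pairs, within-functional vs cross pairs, and within-structural vs
#' within-functional pairs. With the full 12-metric panel the group sizes are
#' 66, 36, 15, 36 and 15 pairs, so the one-sample tests have 65 and 35
#' degrees of freedom.
#'
#' @param overall An [overall_covariance()] result (or an `mmcu_set`, which is
#'   summarized first).
#' @param classes Optional named metric -> class vector
#'   (see [default_metrics()]).
#' @return Tibble: `test`, `group_a`, `group_b` (`NA` for one-sample), `n_a`,
#'   `n_b`, `estimate` (mean Z or difference), `t`, `df`, `p`, `skipped`.
#' @export
pair_group_tests <- function(overall, classes = NULL) {
  if (inherits(overall, "mmcu_set")) overall <- overall_covariance(overall)
  tbl <- pair_group_table(overall, classes) |>
    dplyr::filter(!is.na(.data$mean_z))
  groups <- split(tbl$mean_z, tbl$group)
  cross <- groups[["cross"]] %||% numeric(0)
  ws <- groups[["within_structural"]] %||% numeric(0)
  wf <- groups[["within_functional"]] %||% numeric(0)

  one_sample <- function(name, x) {
    if (length(x) < 2 || sd(x) == 0) {
      return(tibble::tibble(test = "one_sample", group_a = name,
                            group_b = NA_character_, n_a = length(x),
                            n_b = NA_integer_, estimate = mean(x),
                            t = NA_real_, df = NA_real_, p = NA_real_,
                            skipped = TRUE))
    }
    ht <- t.test(x, mu = 0)
    tibble::tibble(test = "one_sample", group_a = name,
                   group_b = NA_character_, n_a = length(x),
                   n_b = NA_integer_, estimate = mean(x),
                   t = unname(ht$statistic), df = unname(ht$parameter),
                   p = ht$p.value, skipped = FALSE)
  }
  welch <- function(name_a, a, name_b, b) {
    if (length(a) < 2 || length(b) < 2) {
      return(tibble::tibble(test = "welch", group_a = name_a,
                            group_b = name_b, n_a = length(a),
                            n_b = length(b), estimate = mean(a) - mean(b),
                            t = NA_real_, df = NA_real_, p = NA_real_,
                            skipped = TRUE))
    }
    ht <- t.test(a, b, var.equal = FALSE)
    tibble::tibble(test = "welch", group_a = name_a, group_b = name_b,
                   n_a = length(a), n_b = length(b),
                   estimate = mean(a) - mean(b), t = unname(ht$statistic),
                   df = unname(ht$parameter), p = ht$p.value, skipped = FALSE)
  }
  dplyr::bind_rows(
    one_sample("all_pairs", tbl$mean_z),
    one_sample("cross", cross),
    welch("within_structural", ws, "cross", cross),
    welch("within_functional", wf, "cross", cross),
    welch("within_structural", ws, "within_functional", wf)
  )
}

#' Hierarchical clustering of metrics on the overall co-variance
#'
#' Converts the mean Fisher-Z matrix to a dissimilarity
#' `d(i, j) = max(Z) - Z(i, j)` (missing cells imputed as 0 with a warning)
#' and runs agglomerative clustering.
#'
#' @param overall An [overall_covariance()] result.
#' @param method Linkage passed to [stats::hclust()] (default
#'   `"average"`).
#' @return An `hclust` object over the metrics.
#' @export
cluster_metrics <- function(overall, method = "average") {
  Z <- overall$z_matrix
  off <- Z[upper.tri(Z)]
  if (any(is.na(off))) {
    rlang::warn("Missing metric-pair cells imputed as Z = 0 for clustering.")
    Z[is.na(Z)] <- 0
  }
  diag(Z) <- max(Z, na.rm = TRUE)
  D <- max(Z) - Z
  diag(D) <- 0
  hclust(as.dist(D), method = method)
}

#' Rank MMCUs by spatial consistency with a vertex set
#'
#' Supports the lookup workflow behind region-driven queries: given a metric
#' and a query set of vertex indices (e.g. an anatomical label), ranks units
#' by how concentrated their member SCM for that metric is on the query set.
#' Consistency is the mean absolute SCM Z-weight inside the set (default), or
#' the correlation of the SCM with the set's indicator vector
#' (`mode = "indicator"`).
#'
#' @param metric Metric name to query.
#' @param vertex_set Integer vertex indices (1-based, nonempty).
#' @param mmcus An `mmcu_set`.
#' @param decompositions The decompositions the units came from.
#' @param mode `"mean_abs_z"` or `"indicator"`.
#' @return Tibble ranked by descending consistency: `unit_id`, `component`,
#'   `consistency`, plus a `covariates` list-column of tibbles giving each
#'   co-varying member and its correlation with the queried SCM. Empty when
#'   the metric occurs in no unit.
#' @export
locate_dominant_mmcu <- function(metric, vertex_set, mmcus, decompositions,
                                 mode = c("mean_abs_z", "indicator")) {
  mode <- match.arg(mode)
  stopifnot(length(vertex_set) > 0)
  qmetric <- metric  # avoid masking by the membership table's metric column
  membership <- mmcu_membership(mmcus)
  hits <- membership[membership$metric == qmetric, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(tibble::tibble(unit_id = integer(), component = integer(),
                          consistency = double(), covariates = list()))
  }
  v <- ncol(decompositions[[metric]]$scms)
  indicator <- as.numeric(seq_len(v) %in% vertex_set)
  hits |>
    dplyr::mutate(
      consistency = purrr::map_dbl(.data$component, function(cp) {
        w <- decompositions[[qmetric]]$scms[cp, ]
        if (mode == "mean_abs_z") mean(abs(w[vertex_set])) else {
          r <- suppressWarnings(cor(w, indicator))
          if (is.na(r)) 0 else r
        }
      }),
      covariates = purrr::map(.data$unit_id, function(uid) {
        u <- mmcus$units[[which(vapply(mmcus$units, `[[`, integer(1),
                                       "unit_id") == uid)]]
        cv <- u$covariance
        others <- setdiff(names(u$members), qmetric)
        tibble::tibble(metric = others, r = cv[qmetric, others])
      })
    ) |>
    dplyr::select("unit_id", "component", "consistency", "covariates") |>
    dplyr::arrange(dplyr::desc(.data$consistency))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
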
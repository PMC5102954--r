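#' Configuration for the synthetic two-cohort generator
#'
#' Defines two independent cohorts of multi-metric vertex maps with planted
#' multi-metric co-variance units (MMCUs): latent subject loadings shared
#' (up to a coupling factor) across a subset of metrics, sparse spatial
#' component maps, and i.i.d. Gaussian vertex noise. The defaults are the
#' package's reference simulation: twelve metrics, discover/confirm cohorts of
#' 184 and 340 subjects, 2000 vertices, eight components per metric and five
#' planted replicable units spanning all metrics with coupling `rho = 0.9`
#' at `snr = 3`.
#'
#' For a planted unit with coupling `rho`, each member metric's loading is
#' `u = rho * g + sqrt(1 - rho^2) * h`, with `g` shared across the unit's
#' metrics and `h` metric-specific (both standard normal over subjects), so
#' the expected cross-metric subject-course correlation is `rho^2`, not `rho`.
#'
#' @param n_discover,n_confirm Subject counts for the two cohorts.
#' @param v Number of vertices.
#' @param metrics Character vector of metric names.
#' @param components_per_metric Integer, or named integer vector per metric:
#'   number of latent components per metric (planted + nuisance).
#' @param planted_units Tibble with columns `unit` (integer id), `metrics`
#'   (list-column of member metric names, each of length >= 2), `rho`
#'   (coupling in `[0, 1]`) and `replicable` (logical: reuse spatial maps in
#'   the confirm cohort). `NULL` builds `n_units` units spanning staggered
#'   subsets of `unit_size` metrics (unit `i` covers metrics `i, i+1, ...`
#'   cyclically), so each unit's co-variance matrix mixes coupled and
#'   uncoupled pairs the way partial-membership units do in practice — the
#'   heterogeneity the ICC consistency measure relies on.
#' @param n_units,rho,replicable,unit_size Used only when `planted_units` is
#'   `NULL`.
#' @param snr Ratio of per-component signal amplitude to noise SD (noise SD is
#'   `1 / snr` with unit component amplitude); must be positive.
#' @param demographic_effects Optional tibble with columns `unit`, `predictor`
#'   (one of `"age"`, `"sex"`, `"handedness"`) and `beta` (effect size in SD
#'   units added to the unit's shared loading).
#' @param sparsity Fraction of vertices carrying nonzero weight in each
#'   spatial map (focal "bump" maps).
#' @param seed Integer seed; the full generation is reproducible from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_discover = 184L, n_confirm = 340L, v = 2000L,
                             metrics = default_metrics()$metric,
                             components_per_metric = 8L,
                             planted_units = NULL,
                             n_units = 5L, rho = 0.9, replicable = TRUE,
                             unit_size = min(8L, length(metrics)),
                             snr = 3, demographic_effects = NULL,
                             sparsity = 0.05, seed = 1L) {
  if (is.null(planted_units)) {
    q <- length(metrics)
    planted_units <- tibble::tibble(
      unit = seq_len(n_units),
      metrics = lapply(seq_len(n_units), function(i) {
        metrics[(i - 1 + seq_len(unit_size) - 1) %% q + 1]
      }),
      rho = rep(rho, length.out = n_units),
      replicable = rep(replicable, length.out = n_units)
    )
  }
  planted_units <- tibble::as_tibble(planted_units)
  if (nrow(planted_units) > 0) {
    sizes <- vapply(planted_units$metrics, length, integer(1))
    if (any(sizes < 2)) {
      rlang::abort("Each planted unit must span at least 2 metrics.")
    }
    if (any(planted_units$rho < 0 | planted_units$rho > 1)) {
      rlang::abort("Coupling rho must lie in [0, 1].")
    }
  }
  if (snr <= 0) rlang::abort("snr must be positive.")
  k_per <- if (length(components_per_metric) == 1L) {
    stats::setNames(rep(as.integer(components_per_metric), length(metrics)),
                    metrics)
  } else {
    stopifnot(all(metrics %in% names(components_per_metric)))
    vapply(metrics, function(m) as.integer(components_per_metric[[m]]),
           integer(1))
  }
  for (m in metrics) {
    n_touch <- if (nrow(planted_units) == 0) 0L else
      sum(vapply(planted_units$metrics, function(s) m %in% s, logical(1)))
    if (k_per[[m]] < n_touch) {
      rlang::abort(paste0("Component budget exceeded for metric '", m, "': ",
                          n_touch, " planted units but only ", k_per[[m]],
                          " components."))
    }
  }
  structure(
    list(n_discover = as.integer(n_discover), n_confirm = as.integer(n_confirm),
         v = as.integer(v), metrics = metrics,
         components_per_metric = k_per, planted_units = planted_units,
         snr = snr, demographic_effects = demographic_effects,
         sparsity = sparsity, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# sparse focal map: a random fraction of vertices gets half-normal weight.
# Positive bumps give the map positive skewness, the property real focal
# component maps have and the ICA sign convention relies on.
draw_spatial_map <- function(v, sparsity) {
  w <- numeric(v)
  nz <- sample.int(v, max(2L, ceiling(sparsity * v)))
  w[nz] <- abs(rnorm(length(nz)))
  w
}

draw_demographics <- function(n, prefix) {
  tibble::tibble(
    subject_id = sprintf("%s%03d", prefix, seq_len(n)),
    age = round(runif(n, 18, 30), 1),
    sex = as.integer(runif(n) < 0.6),
    handedness = as.integer(runif(n) < 0.13)
  )
}

draw_qc <- function(demog) {
  n <- nrow(demog)
  tibble::tibble(
    subject_id = demog$subject_id,
    maxTran = abs(rnorm(n, 0.5, 0.35)),
    maxRot = abs(rnorm(n, 0.5, 0.35)),
    meanFD = abs(rnorm(n, 0.08, 0.04)),
    mcBBR = runif(n, 0.3, 0.65)
  )
}

#' Generate two synthetic cohorts with planted co-variance structure
#'
#' Builds a discover and a confirm cohort whose metric matrices follow
#' `X_m = sum_k u_{k,m} w_{k,m}^T + sigma * E` with standard-normal noise `E`
#' and `sigma = 1 / snr`. Planted units share a latent subject loading across
#' their member metrics (coupling `rho`, see [synthetic_config()]); replicable
#' units reuse their spatial maps in the confirm cohort with fresh loadings,
#' non-replicable units get fresh maps as well. Nuisance components have
#' independent loadings and maps. Demographic effects, if configured, shift
#' the designated unit's shared loading by `beta` times the standardized
#' predictor.
#'
#' @param config A [synthetic_config()].
#' @return A `covunit_simulation` list with elements `discover` and `confirm`
#'   (both [cohort_bundle()]s) and `truth`, which holds `membership`
#'   (tibble `unit`, `metric`, `component`), `loadings` (per unit, per cohort
#'   shared loading vectors), and `spatial_maps` (per cohort, per unit, per
#'   metric vertex vectors).
#' @examples
#' sim <- simulate_cohorts(synthetic_config(
#'   n_discover = 30, n_confirm = 40, v = 120,
#'   metrics = c("thick", "area", "alff"), components_per_metric = 3,
#'   n_units = 1, seed = 7))
#' sim$truth$membership
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, simulate_cohorts_impl(config))
}

simulate_cohorts_impl <- function(config) {
  metrics <- config$metrics
  units <- config$planted_units
  n_units <- nrow(units)
  k_per <- config$components_per_metric
  sigma <- 1 / config$snr
  v <- config$v

  # component slot assignment: units occupy leading slots per metric, in unit order
  membership <- if (n_units == 0) {
    tibble::tibble(unit = integer(), metric = character(),
                   component = integer())
  } else {
    purrr::map_dfr(seq_len(n_units), function(i) {
      tibble::tibble(unit = units$unit[i], metric = units$metrics[[i]])
    }) |>
      dplyr::group_by(.data$metric) |>
      dplyr::mutate(component = dplyr::row_number()) |>
      dplyr::ungroup()
  }

  # discover-cohort spatial maps for planted units, reused for replicable ones
  unit_maps_discover <- lapply(seq_len(n_units), function(i) {
    maps <- lapply(units$metrics[[i]], function(m) draw_spatial_map(v, config$sparsity))
    stats::setNames(maps, units$metrics[[i]])
  })
  unit_maps_confirm <- lapply(seq_len(n_units), function(i) {
    if (isTRUE(units$replicable[i])) unit_maps_discover[[i]] else {
      maps <- lapply(units$metrics[[i]], function(m) draw_spatial_map(v, config$sparsity))
      stats::setNames(maps, units$metrics[[i]])
    }
  })

  gen_cohort <- function(n, prefix, unit_maps) {
    demog <- draw_demographics(n, prefix)
    qc <- draw_qc(demog)
    shared <- lapply(seq_len(n_units), function(i) {
      g <- rnorm(n)
      eff <- config$demographic_effects
      if (!is.null(eff)) {
        eff_i <- eff[eff$unit == units$unit[i], , drop = FALSE]
        for (r in seq_len(nrow(eff_i))) {
          pred <- demog[[eff_i$predictor[r]]]
          g <- g + eff_i$beta[r] * as.numeric(scale(pred))
        }
      }
      g
    })
    mats <- lapply(metrics, function(m) {
      k <- k_per[[m]]
      touching <- membership[membership$metric == m, , drop = FALSE]
      U <- matrix(0, n, k)
      W <- matrix(0, k, v)
      for (r in seq_len(nrow(touching))) {
        ui <- match(touching$unit[r], units$unit)
        slot <- touching$component[r]
        rho_u <- units$rho[ui]
        U[, slot] <- rho_u * shared[[ui]] + sqrt(1 - rho_u^2) * rnorm(n)
        W[slot, ] <- unit_maps[[ui]][[m]]
      }
      free <- setdiff(seq_len(k), touching$component)
      for (slot in free) {
        U[, slot] <- rnorm(n)
        W[slot, ] <- draw_spatial_map(v, config$sparsity)
      }
      X <- U %*% W + sigma * matrix(rnorm(n * v), n, v)
      rownames(X) <- demog$subject_id
      X
    })
    names(mats) <- metrics
    list(bundle = cohort_bundle(prefix, demog$subject_id, mats,
                                qc = qc, demographics = demog),
         shared = shared)
  }

  disc <- gen_cohort(config$n_discover, "discover", unit_maps_discover)
  conf <- gen_cohort(config$n_confirm, "confirm", unit_maps_confirm)

  truth <- list(
    membership = membership,
    loadings = list(discover = disc$shared, confirm = conf$shared),
    spatial_maps = list(discover = unit_maps_discover,
                        confirm = unit_maps_confirm),
    units = units
  )
  structure(list(discover = disc$bundle, confirm = conf$bundle,
                 truth = truth, config = config),
            class = "covunit_simulation")
}

#' @export
print.covunit_simulation <- function(x, ...) {
  cat("<covunit_simulation> ", length(x$config$metrics), " metrics, ",
      x$config$n_discover, "/", x$config$n_confirm, " subjects, v = ",
      x$config$v, ", ", nrow(x$truth$units), " planted units\n", sep = "")
  invisible(x)
}

#' Score recovery of planted units by the alignment pipeline
#'
#' Each planted (unit, metric) slot is matched to the surface component map
#' (SCM) in that metric's decomposition with the highest absolute spatial
#' correlation to the unit's true map. A planted cross-metric pair is counted
#' as recovered when its two matched SCMs were co-assigned to one MMCU.
#'
#' @param mmcus An `mmcu_set` from [extract_mmcus()] / [graicar_align()].
#' @param truth The `truth` element of a [simulate_cohorts()] result.
#' @param decompositions Named list of [decompose_metric()] results used to
#'   build the MMCUs.
#' @return A `recovery_report`: list with `units` (tibble: `unit`,
#'   `matched_mmcu`, `mean_abs_spatial_cor`), `pairs` (tibble of planted pairs
#'   with a `recovered` flag), and scalars `precision`, `recall`. With no
#'   planted units both scalars are `NA` and the tibbles are empty.
#' @export
score_recovery <- function(mmcus, truth, decompositions) {
  membership <- truth$membership
  if (nrow(membership) == 0) {
    return(structure(list(
      units = tibble::tibble(unit = integer(), matched_mmcu = integer(),
                             mean_abs_spatial_cor = double()),
      pairs = tibble::tibble(), precision = NA_real_, recall = NA_real_),
      class = "recovery_report"))
  }
  # match every (unit, metric) to the best-correlated SCM of that metric
  matched <- membership |>
    dplyr::mutate(purrr::map2_dfr(.data$unit, .data$metric, function(u, m) {
      ui <- match(u, truth$units$unit)
      w <- truth$spatial_maps$discover[[ui]][[m]]
      scms <- decompositions[[m]]$scms
      rs <- abs(as.vector(cor(t(scms), w)))
      tibble::tibble(scm = which.max(rs), spatial_cor = max(rs))
    }))

  assign_tbl <- mmcu_membership(mmcus)
  matched <- matched |>
    dplyr::left_join(assign_tbl, by = c("metric", "scm" = "component"))

  units_tbl <- matched |>
    dplyr::group_by(.data$unit) |>
    dplyr::summarise(
      matched_mmcu = if (all(is.na(.data$unit_id))) NA_integer_ else
        as.integer(names(which.max(table(.data$unit_id)))),
      mean_abs_spatial_cor = mean(.data$spatial_cor),
      .groups = "drop")

  # planted cross-metric pairs: two slots of the same unit
  pair_of <- function(df) {
    combs <- utils::combn(nrow(df), 2)
    tibble::tibble(
      unit = df$unit[1],
      metric_i = df$metric[combs[1, ]], metric_j = df$metric[combs[2, ]],
      recovered = !is.na(df$unit_id[combs[1, ]]) &
        !is.na(df$unit_id[combs[2, ]]) &
        df$unit_id[combs[1, ]] == df$unit_id[combs[2, ]]
    )
  }
  pairs <- matched |>
    dplyr::group_by(.data$unit) |>
    dplyr::group_split() |>
    purrr::map_dfr(pair_of)
  recall <- mean(pairs$recovered)

  # precision: of co-assigned matched-SCM pairs, fraction that are planted pairs
  co <- matched[!is.na(matched$unit_id), , drop = FALSE]
  n_pred <- 0L; n_true_pred <- 0L
  if (nrow(co) >= 2) {
    cmb <- utils::combn(nrow(co), 2)
    same_mmcu <- co$unit_id[cmb[1, ]] == co$unit_id[cmb[2, ]]
    distinct_scm <- !(co$metric[cmb[1, ]] == co$metric[cmb[2, ]] &
                        co$scm[cmb[1, ]] == co$scm[cmb[2, ]])
    pred <- same_mmcu & distinct_scm
    n_pred <- sum(pred)
    n_true_pred <- sum(pred & co$unit[cmb[1, ]] == co$unit[cmb[2, ]])
  }
  precision <- if (n_pred == 0) NA_real_ else n_true_pred / n_pred

  structure(list(units = units_tbl, pairs = pairs,
                 precision = precision, recall = recall),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> recall = ", round(x$recall, 3),
      ", precision = ", round(x$precision, 3), "\n", sep = "")
  print(x$units)
  invisible(x)
}

#' @rdname score_recovery
#' @param x A `recovery_report`.
#' @param ... Unused.
#' @method glance recovery_report
#' @export
glance.recovery_report <- function(x, ...) {
  tibble::tibble(precision = x$precision, recall = x$recall,
                 n_units = nrow(x$units),
                 mean_abs_spatial_cor = mean(x$units$mean_abs_spatial_cor))
}
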
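#' Fisher Z transform with clipping
#'
#' `atanh(r)` with `|r|` clipped to `1 - 1e-6` so degenerate correlations stay
#' finite.
#'
#' @param r Correlations.
#' @param clip Clipping bound on `|r|`.
#' @return Numeric vector/matrix of Z scores.
#' @export
fisher_z <- function(r, clip = 1 - 1e-6) {
  atanh(pmin(pmax(r, -clip), clip))
}

#' Project a discover-stage SCM onto a confirm cohort metric
#'
#' Correlates the SCM's vertex weights with each confirm subject's metric map,
#' yielding that subject's "fluctuation" value: the per-subject analogue of a
#' subject-course loading in the independent cohort.
#'
#' @param scm Numeric vertex-weight vector (length `v`).
#' @param confirm_metric Subjects-by-vertices matrix of the same metric in the
#'   confirm cohort (`v` columns).
#' @return Numeric vector of Pearson correlations, one per confirm subject.
#'   A zero-variance subject map yields 0 with a warning.
#' @export
project_scm <- function(scm, confirm_metric) {
  if (length(scm) != ncol(confirm_metric)) {
    rlang::abort(paste0("Vertex mismatch: SCM has ", length(scm),
                        " vertices, confirm metric has ",
                        ncol(confirm_metric), "."))
  }
  v <- length(scm)
  sc <- scm - mean(scm)
  s_sd <- sqrt(sum(sc^2))
  Xc <- confirm_metric - rowMeans(confirm_metric)
  x_sd <- sqrt(rowSums(Xc^2))
  bad <- x_sd == 0
  if (any(bad)) {
    rlang::warn(paste0(sum(bad), " zero-variance subject map(s); entries set to 0."))
    x_sd[bad] <- Inf
  }
  r <- as.vector(Xc %*% sc) / unname(x_sd * s_sd)
  r[bad] <- 0
  r
}

# fluctuation courses for all member SCMs of one unit: n_confirm x p
fluctuation_courses <- function(mmcu, decompositions, confirm) {
  p <- length(mmcu$members)
  out <- matrix(NA_real_, n_subjects(confirm), p)
  colnames(out) <- names(mmcu$members)
  for (j in seq_len(p)) {
    m <- names(mmcu$members)[j]
    if (!m %in% names(confirm$metrics)) {
      rlang::abort(paste0("Metric '", m, "' missing from confirm cohort."))
    }
    scm <- decompositions[[m]]$scms[mmcu$members[[j]], ]
    out[, j] <- project_scm(scm, confirm$metrics[[m]])
  }
  rownames(out) <- confirm$subject_ids
  out
}

#' Confirm-stage inter-metric co-variance matrix of one unit
#'
#' Pairwise Pearson correlations between the member SCMs' fluctuation courses
#' in the confirm cohort, ordered as in the unit's discover-stage matrix.
#'
#' @param mmcu A unit element of an `mmcu_set`.
#' @param decompositions The discover-stage decompositions.
#' @param confirm The confirm [cohort_bundle()].
#' @return A `p x p` symmetric correlation matrix with unit diagonal.
#' @export
confirm_covariance <- function(mmcu, decompositions, confirm) {
  cor(fluctuation_courses(mmcu, decompositions, confirm))
}

#' Intra-class correlation between two co-variance matrices
#'
#' Measures the consistency of the discover- and confirm-stage inter-metric
#' co-variance matrices of one unit. The `p(p-1)/2` unique off-diagonal
#' correlations of each matrix are Fisher-Z transformed; elements are treated
#' as targets and the two matrices as repeated measurements of the same
#' variable, giving the one-way random-effects ICC(1,1)
#' `(MSB - MSW) / (MSB + MSW)`. ICC(3,1) (two-way mixed, consistency) is
#' available via `model = "icc3"`.
#'
#' @param matA,matB `p x p` symmetric correlation matrices, `p >= 2`.
#' @param model `"icc1"` (default) or `"icc3"`.
#' @return ICC value in `(-1, 1]`.
#' @examples
#' a <- matrix(c(1, .1, .5, .1, 1, .9, .5, .9, 1), 3)
#' b <- matrix(c(1, .2, .4, .2, 1, .8, .4, .8, 1), 3)
#' icc_consistency(a, b)
#' @export
icc_consistency <- function(matA, matB, model = c("icc1", "icc3")) {
  model <- match.arg(model)
  stopifnot(identical(dim(matA), dim(matB)))
  p <- nrow(matA)
  if (p < 2) rlang::abort("icc_consistency needs matrices of size >= 2.")
  zA <- fisher_z(matA[upper.tri(matA)])
  zB <- fisher_z(matB[upper.tri(matB)])
  icc_from_pairs(zA, zB, model)
}

icc_from_pairs <- function(zA, zB, model = "icc1") {
  q <- length(zA)  # targets
  k <- 2           # measurements per target
  tm <- (zA + zB) / 2
  gm <- mean(tm)
  msb <- k * sum((tm - gm)^2) / (q - 1)
  msw <- sum((zA - tm)^2 + (zB - tm)^2) / q
  if (model == "icc1") {
    if (msb + msw == 0) return(1)
    (msb - msw) / (msb + msw)
  } else {
    mm <- (mean(zA) + mean(zB)) / 2
    msc <- q * ((mean(zA) - mm)^2 + (mean(zB) - mm)^2)  # df = k - 1 = 1
    mse <- (sum((zA - tm)^2 + (zB - tm)^2) - msc) / (q - 1)
    if (msb + mse == 0) return(1)
    (msb - mse) / (msb + mse)
  }
}

#' Permutation null distribution of ICC values
#'
#' Each replicate draws one SCM uniformly at random from every metric (no
#' reuse within a replicate), forms the "fake unit"'s discover co-variance
#' matrix from subject courses and its confirm matrix from fluctuation
#' courses, and records the ICC between them. Fluctuation courses for every
#' SCM are computed once up front, so replicates only correlate short
#' vectors.
#'
#' @param decompositions Discover-stage decompositions (named list).
#' @param confirm Confirm [cohort_bundle()].
#' @param n_perm Number of replicates (>= 100; the reference analysis uses
#'   5000).
#' @param seed Integer seed.
#' @param model ICC model, see [icc_consistency()].
#' @return Numeric vector of `n_perm` null ICC values, with attribute
#'   `"fluctuations"` carrying the precomputed per-SCM fluctuation course
#'   matrix.
#' @export
permutation_null <- function(decompositions, confirm, n_perm = 5000L,
                             seed = 1L, model = "icc1") {
  if (n_perm < 100) rlang::abort("n_perm must be at least 100.")
  metrics <- names(decompositions)
  ks <- vapply(decompositions, function(d) d$k, integer(1))
  courses <- do.call(cbind, lapply(decompositions, function(d) d$courses))
  block_start <- cumsum(c(0L, ks[-length(ks)]))
  names(block_start) <- metrics

  fl <- matrix(NA_real_, n_subjects(confirm), sum(ks))
  col <- 0L
  for (m in metrics) {
    X <- confirm$metrics[[m]]
    for (j in seq_len(ks[[m]])) {
      col <- col + 1L
      fl[, col] <- project_scm(decompositions[[m]]$scms[j, ], X)
    }
  }

  null_icc <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(rep) {
      pick <- block_start + vapply(ks, function(k) sample.int(k, 1L),
                                   integer(1))
      ca <- cor(courses[, pick, drop = FALSE])
      cb <- cor(fl[, pick, drop = FALSE])
      icc_from_pairs(fisher_z(ca[upper.tri(ca)]),
                     fisher_z(cb[upper.tri(cb)]), model)
    }, numeric(1))
  })
  attr(null_icc, "fluctuations") <- fl
  null_icc
}

#' Empirical p from a null distribution (add-one rule)
#'
#' `p = (1 + #null >= observed) / (1 + n_perm)`, never exactly zero.
#'
#' @param observed Observed statistic(s).
#' @param null Null distribution vector.
#' @return Empirical p value(s) in `(0, 1]`.
#' @export
empirical_p <- function(observed, null) {
  vapply(observed, function(o) (1 + sum(null >= o)) / (1 + length(null)),
         numeric(1))
}

#' Reliability labels for validated units
#'
#' A unit is `fair` when its ICC exceeds the fair-reproducibility threshold
#' (0.4 by convention), and `significant` when it additionally exceeds the
#' stated percentile of the permutation null; otherwise `unreliable`.
#'
#' @param icc Numeric vector of ICC values.
#' @param null Null ICC distribution.
#' @param fair_threshold Fair-reproducibility cutoff (default 0.4).
#' @param percentile Null percentile for significance (default 95.5).
#' @return Factor with levels `unreliable`, `fair`, `significant`.
#' @export
classify_reliability <- function(icc, null, fair_threshold = 0.4,
                                 percentile = 95.5) {
  cut_val <- quantile(null, percentile / 100, names = FALSE)
  lab <- ifelse(icc > fair_threshold,
                ifelse(icc > cut_val, "significant", "fair"),
                "unreliable")
  factor(lab, levels = c("unreliable", "fair", "significant"))
}

#' Validate MMCUs in an independent confirm cohort
#'
#' For every unit: builds confirm-cohort fluctuation courses and co-variance
#' matrix, computes the ICC against the discover-stage matrix, and calibrates
#' significance against a shared permutation null of fake full-size units.
#' Following the reference procedure, the permutation p is only reported for
#' units above the fair threshold. Note the null is built from fake units
#' spanning every metric; units with fewer members are still compared against
#' this full-size null (reported as-is).
#'
#' @param mmcus An `mmcu_set`.
#' @param decompositions The discover-stage decompositions.
#' @param confirm Confirm [cohort_bundle()].
#' @param n_perm,seed,model Passed to [permutation_null()].
#' @param fair_threshold,percentile Passed to [classify_reliability()].
#' @return A `validation_report`: list with `units` tibble (`unit_id`, `p`
#'   members, `icc`, `perm_p`, `percentile_p`, `label`), `confirm_covariance`
#'   and `fluctuation_courses` lists, `null_icc`, `percentile_cut`, and the
#'   parameters.
#' @export
validate_mmcus <- function(mmcus, decompositions, confirm, n_perm = 5000L,
                           seed = 1L, model = "icc1", fair_threshold = 0.4,
                           percentile = 95.5) {
  stopifnot(inherits(mmcus, "mmcu_set"))
  null_icc <- permutation_null(decompositions, confirm, n_perm = n_perm,
                               seed = seed, model = model)
  cut_val <- quantile(null_icc, percentile / 100, names = FALSE)
  fls <- lapply(mmcus$units, fluctuation_courses, decompositions, confirm)
  cms <- lapply(fls, cor)
  icc <- vapply(seq_along(mmcus$units), function(i) {
    icc_consistency(mmcus$units[[i]]$covariance, cms[[i]], model = model)
  }, numeric(1))
  label <- classify_reliability(icc, null_icc, fair_threshold, percentile)
  perm_p <- ifelse(icc > fair_threshold, empirical_p(icc, null_icc), NA_real_)
  percentile_p <- ifelse(icc > fair_threshold,
                         vapply(icc, function(o) mean(null_icc >= o),
                                numeric(1)),
                         NA_real_)
  units <- tibble::tibble(
    unit_id = vapply(mmcus$units, `[[`, integer(1), "unit_id"),
    p = vapply(mmcus$units, function(u) length(u$members), integer(1)),
    icc = icc, perm_p = perm_p, percentile_p = percentile_p, label = label
  )
  structure(list(units = units, confirm_covariance = cms,
                 fluctuation_courses = fls, null_icc = as.numeric(null_icc),
                 percentile_cut = cut_val, fair_threshold = fair_threshold,
                 percentile = percentile, n_perm = n_perm, seed = seed,
                 model = model),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", nrow(x$units), " units; ",
      sum(x$units$label != "unreliable"), " fair, ",
      sum(x$units$label == "significant"), " significant (ICC > ",
      round(x$percentile_cut, 3), " = ", x$percentile,
      "th null percentile)\n", sep = "")
  print(x$units)
  invisible(x)
}

#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) x$units

#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(
    n_units = nrow(x$units),
    n_fair = sum(x$units$label != "unreliable"),
    n_significant = sum(x$units$label == "significant"),
    percentile_cut = x$percentile_cut,
    n_perm = x$n_perm
  )
}
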
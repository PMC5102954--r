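#' Full similarity matrix between subject courses of all SCMs
#'
#' Stacks the subject courses of every surface component map (SCM) from every
#' metric's decomposition and computes all pairwise Pearson correlations. The
#' matrix is organized in metric-blocks: rows/columns are grouped by source
#' metric, which the alignment steps ([zrow_normalize()], [zmax_mask()],
#' [popularity_rank()], [extract_mmcus()]) rely on.
#'
#' @param decompositions Named list of [decompose_metric()] results sharing
#'   subject count and order.
#' @return A `covunit_fsm`: list with `sims` (`M x M` signed Pearson r, unit
#'   diagonal), `block` (integer metric index per row), `metric_levels`,
#'   `scm_labels`, `courses` (`n x M`), and `k_per_metric`.
#' @export
build_fsm <- function(decompositions) {
  stopifnot(length(decompositions) >= 2)
  ns <- vapply(decompositions, function(d) nrow(d$courses), integer(1))
  if (length(unique(ns)) != 1) {
    rlang::abort("All decompositions must share the same subject count.")
  }
  metric_levels <- names(decompositions)
  courses <- do.call(cbind, lapply(decompositions, function(d) d$courses))
  block <- rep(seq_along(decompositions),
               vapply(decompositions, function(d) d$k, integer(1)))
  sds <- apply(courses, 2, sd)
  if (any(sds == 0)) {
    rlang::abort(paste0("Zero-variance subject course: ",
                        paste(colnames(courses)[sds == 0], collapse = ", ")))
  }
  sims <- cor(courses)
  structure(list(sims = sims, block = block, metric_levels = metric_levels,
                 scm_labels = colnames(courses), courses = courses,
                 k_per_metric = vapply(decompositions, function(d) d$k,
                                       integer(1))),
            class = "covunit_fsm")
}

#' @export
print.covunit_fsm <- function(x, ...) {
  cat("<covunit_fsm> ", nrow(x$sims), " SCMs over ",
      length(x$metric_levels), " metrics",
      if (!is.null(x$popularity)) " (popularity computed)", "\n", sep = "")
  invisible(x)
}

#' Row-wise per-block standardization of the similarity matrix
#'
#' Within each row, the similarity values falling inside each metric-block
#' segment are converted to relative values: standardized to zero mean and
#' unit SD across that segment. Segments of size one (a metric with a single
#' component) and zero-variance segments map to 0. The row's own-metric block
#' is standardized like any other; it is excluded from matching later, not
#' here.
#'
#' @param fsm A `covunit_fsm` from [build_fsm()].
#' @return The fsm with a `zrow` matrix added.
#' @export
zrow_normalize <- function(fsm) {
  sims <- fsm$sims
  M <- nrow(sims)
  zrow <- matrix(0, M, M, dimnames = dimnames(sims))
  for (b in seq_along(fsm$metric_levels)) {
    idx <- which(fsm$block == b)
    seg <- sims[, idx, drop = FALSE]
    if (length(idx) == 1L) next  # single-component metric: relative value 0
    mu <- rowMeans(seg)
    s <- sqrt(rowMeans((seg - mu)^2))  # population SD over the segment
    z <- (seg - mu) / ifelse(s > 0, s, Inf)
    zrow[, idx] <- z
  }
  fsm$zrow <- zrow
  fsm
}

#' Per-block maximum mask of the standardized similarity matrix
#'
#' Per row and per off-metric block segment, retains only the maximal `zrow`
#' value (ties broken toward the lowest column index) and zeroes all other
#' entries; own-metric block segments are zeroed entirely. Each row of the
#' result points at the single most similar SCM in every other metric.
#'
#' @param fsm A `covunit_fsm` with `zrow` (see [zrow_normalize()]).
#' @return The fsm with a `zmax` matrix added.
#' @export
zmax_mask <- function(fsm) {
  if (is.null(fsm$zrow)) fsm <- zrow_normalize(fsm)
  z <- fsm$zrow
  M <- nrow(z)
  zmax <- matrix(0, M, M, dimnames = dimnames(z))
  for (i in seq_len(M)) {
    for (b in seq_along(fsm$metric_levels)) {
      if (b == fsm$block[i]) next
      idx <- which(fsm$block == b)
      j <- idx[which.max(z[i, idx])]  # which.max takes the first (lowest) index
      zmax[i, j] <- z[i, j]
    }
  }
  fsm$zmax <- zmax
  fsm
}

#' Popularity centrality of each SCM
#'
#' Multiplies the max-mask matrix elementwise with its transpose, so a pair
#' contributes only when the two SCMs are mutual best matches within their
#' metric-blocks (unpaired maxima are eliminated), then sums each row. Also
#' computes the standardized similarity matrix `zrow + t(zrow)` used during
#' extraction.
#'
#' @param fsm A `covunit_fsm`; missing `zrow`/`zmax` are computed.
#' @return The fsm with `popularity` (length-M vector) and `standardized`
#'   (`M x M`) added.
#' @export
popularity_rank <- function(fsm) {
  if (is.null(fsm$zmax)) fsm <- zmax_mask(fsm)
  P <- fsm$zmax * t(fsm$zmax)
  fsm$popularity <- rowSums(P)
  names(fsm$popularity) <- fsm$scm_labels
  fsm$standardized <- fsm$zrow + t(fsm$zrow)
  fsm
}

#' Greedy extraction of multi-metric co-variance units
#'
#' Walks the popularity rank computed once on the full matrix: the unassigned
#' SCM with the highest popularity anchors a unit; for every other metric the
#' anchor picks, among that metric's still-unassigned SCMs, the one maximizing
#' the standardized similarity on the anchor's row (ties toward the lowest
#' index). Members are marked assigned and the procedure repeats until every
#' SCM is assigned. Anchors left without any partner are discarded as
#' singletons — a unit associates at least two metrics. When every anchor
#' finds at least one partner per other metric, the number of units equals the
#' second-largest per-metric component count.
#'
#' @param fsm A `covunit_fsm`; missing stages are computed.
#' @param min_standardized Optional floor on the standardized similarity an
#'   anchor accepts for a partner (default `-Inf`: unthresholded).
#' @param recompute_rank Recompute zrow/zmax/popularity on the residual SCM
#'   set after each extraction instead of walking the fixed initial rank.
#' @return An `mmcu_set`: list with `units` (each a list `unit_id`,
#'   `members` named integer vector metric -> component, `scm_indices`,
#'   `covariance` from [mmcu_covariance()]), `singletons` (row indices), and
#'   the `fsm`.
#' @export
extract_mmcus <- function(fsm, min_standardized = -Inf,
                          recompute_rank = FALSE) {
  if (is.null(fsm$popularity)) fsm <- popularity_rank(fsm)
  M <- nrow(fsm$sims)
  assigned <- rep(FALSE, M)
  units <- list()
  singletons <- integer(0)
  unit_id <- 0L
  pop <- fsm$popularity
  std <- fsm$standardized
  block <- fsm$block

  while (any(!assigned)) {
    if (recompute_rank) {
      keep <- which(!assigned)
      sub <- fsm
      sub$sims <- fsm$sims[keep, keep, drop = FALSE]
      sub$block <- fsm$block[keep]
      sub$scm_labels <- fsm$scm_labels[keep]
      sub$zrow <- sub$zmax <- sub$popularity <- sub$standardized <- NULL
      sub <- popularity_rank(sub)
      a_local <- which.max(sub$popularity)
      anchor <- keep[a_local]
      std <- matrix(-Inf, M, M)
      std[keep, keep] <- sub$standardized
    } else {
      cand <- which(!assigned)
      anchor <- cand[which.max(pop[cand])]
    }
    members <- anchor
    for (b in seq_along(fsm$metric_levels)) {
      if (b == block[anchor]) next
      avail <- which(!assigned & block == b)
      avail <- setdiff(avail, members)
      if (length(avail) == 0) next
      best <- avail[which.max(std[anchor, avail])]
      if (std[anchor, best] >= min_standardized) members <- c(members, best)
    }
    if (length(members) < 2) {
      assigned[anchor] <- TRUE
      singletons <- c(singletons, anchor)
      next
    }
    assigned[members] <- TRUE
    unit_id <- unit_id + 1L
    # fix member order to the configured metric list
    members <- members[order(block[members])]
    comp_within <- vapply(members, function(i) {
      sum(block[seq_len(i)] == block[i])
    }, integer(1))
    unit <- list(
      unit_id = unit_id,
      members = stats::setNames(comp_within,
                                fsm$metric_levels[block[members]]),
      scm_indices = members
    )
    unit$covariance <- mmcu_covariance(unit, fsm)
    units[[unit_id]] <- unit
  }
  structure(list(units = units, singletons = singletons, fsm = fsm),
            class = "mmcu_set")
}

#' Inter-metric co-variance matrix of one unit
#'
#' The raw signed Pearson correlations (from the full similarity matrix, not
#' the standardized values) between the subject courses of a unit's member
#' SCMs, ordered by the configured metric list.
#'
#' @param mmcu A unit element of an `mmcu_set` (needs `scm_indices`).
#' @param fsm The `covunit_fsm` the unit was extracted from.
#' @return A `p x p` symmetric matrix with unit diagonal, dimnames = member
#'   metric names.
#' @export
mmcu_covariance <- function(mmcu, fsm) {
  idx <- mmcu$scm_indices
  cv <- fsm$sims[idx, idx, drop = FALSE]
  dimnames(cv) <- list(names(mmcu$members), names(mmcu$members))
  cv
}

#' @export
print.mmcu_set <- function(x, ...) {
  cat("<mmcu_set> ", length(x$units), " units, ",
      length(x$singletons), " discarded singletons\n", sep = "")
  print(mmcu_membership(x))
  invisible(x)
}

#' Tidy membership table of an MMCU set
#'
#' @param mmcus An `mmcu_set`.
#' @return Tibble with columns `unit_id`, `metric`, `component`, `scm_label`.
#' @export
mmcu_membership <- function(mmcus) {
  if (length(mmcus$units) == 0) {
    return(tibble::tibble(unit_id = integer(), metric = character(),
                          component = integer(), scm_label = character()))
  }
  purrr::map_dfr(mmcus$units, function(u) {
    tibble::tibble(unit_id = u$unit_id, metric = names(u$members),
                   component = unname(u$members),
                   scm_label = mmcus$fsm$scm_labels[u$scm_indices])
  })
}

#' @method tidy mmcu_set
#' @export
tidy.mmcu_set <- function(x, ...) mmcu_membership(x)

#' @method glance mmcu_set
#' @export
glance.mmcu_set <- function(x, ...) {
  sizes <- vapply(x$units, function(u) length(u$members), integer(1))
  tibble::tibble(n_units = length(x$units),
                 n_singletons = length(x$singletons),
                 mean_size = mean(sizes), max_size = max(sizes))
}

#' One-call alignment: decompositions to MMCUs
#'
#' Convenience wrapper running [build_fsm()], [zrow_normalize()],
#' [zmax_mask()], [popularity_rank()] and [extract_mmcus()].
#'
#' @inheritParams build_fsm
#' @inheritParams extract_mmcus
#' @return An `mmcu_set`.
#' @export
graicar_align <- function(decompositions, min_standardized = -Inf,
                          recompute_rank = FALSE) {
  fsm <- popularity_rank(zmax_mask(zrow_normalize(build_fsm(decompositions))))
  extract_mmcus(fsm, min_standardized = min_standardized,
                recompute_rank = recompute_rank)
}
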
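#' Representative subject course of one unit
#'
#' Z-scores each member SCM's subject course, stacks them as variables and
#' takes the first principal component scores, rescaled to unit variance. The
#' first component captures the variance most common to all member courses
#' and serves as the unit's single representative course. Its sign is fixed
#' so it correlates positively with the mean of the standardized courses.
#'
#' @param mmcu A unit element of an `mmcu_set` (needs >= 2 members).
#' @param decompositions The decompositions the unit was built from.
#' @return Numeric length-`n` vector with attribute `"var_explained"`.
#' @export
representative_course <- function(mmcu, decompositions) {
  if (length(mmcu$members) < 2) {
    rlang::abort("representative_course needs a unit with >= 2 members.")
  }
  C <- vapply(seq_along(mmcu$members), function(j) {
    m <- names(mmcu$members)[j]
    as.numeric(scale(decompositions[[m]]$courses[, mmcu$members[[j]]]))
  }, numeric(nrow(decompositions[[1]]$courses)))
  pc <- prcomp(C, center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1]
  anchor <- rowMeans(C)
  # an exactly balanced pair of anti-correlated courses has a zero mean
  # course; anchor on the first member instead so the sign stays defined
  if (sd(anchor) == 0) anchor <- C[, 1]
  if (cor(scores, anchor) < 0) scores <- -scores
  out <- as.numeric(scale(scores))
  attr(out, "var_explained") <- pc$sdev[1]^2 / sum(pc$sdev^2)
  out
}

#' Regress a representative course on demographic predictors
#'
#' Ordinary least squares of the unit's representative subject course on
#' centered age, sex and handedness (0/1 indicators) jointly, with intercept.
#' Standardized coefficients are reported so results are invariant to affine
#' predictor rescaling. Subjects with any missing predictor are dropped
#' listwise (logged via the `n_used` column). Constant predictors are dropped
#' with a warning; a constant response returns p = 1 for every predictor.
#'
#' @param course Numeric response vector (one value per subject).
#' @param demographics Tibble with columns `age`, `sex`, `handedness` aligned
#'   with `course`.
#' @param predictors Character vector of predictors to include.
#' @return Tibble: `predictor`, `beta` (standardized), `t`, `p`, `n_used`.
#' @export
demographic_regression <- function(course, demographics,
                                   predictors = c("age", "sex",
                                                  "handedness")) {
  stopifnot(length(course) == nrow(demographics))
  df <- tibble::as_tibble(demographics)[, predictors, drop = FALSE]
  df$.course <- course
  keep <- complete.cases(df)
  df <- df[keep, , drop = FALSE]
  constant <- vapply(predictors, function(p) sd(df[[p]]) == 0, logical(1))
  if (any(constant)) {
    rlang::warn(paste0("Constant predictor(s) dropped: ",
                       paste(predictors[constant], collapse = ", ")))
  }
  used <- predictors[!constant]
  if (sd(df$.course) == 0 || length(used) == 0) {
    return(tibble::tibble(predictor = predictors,
                          beta = ifelse(constant, NA_real_, 0),
                          t = NA_real_, p = 1, n_used = nrow(df)))
  }
  for (p in used) df[[p]] <- as.numeric(scale(df[[p]]))
  df$.course <- as.numeric(scale(df$.course))
  fit <- lm(stats::reformulate(used, response = ".course"), data = df)
  sm <- summary(fit)$coefficients
  tibble::tibble(predictor = predictors,
                 beta = ifelse(constant, NA_real_, sm[used, 1][match(predictors, used)]),
                 t = ifelse(constant, NA_real_, sm[used, 3][match(predictors, used)]),
                 p = ifelse(constant, 1, sm[used, 4][match(predictors, used)]),
                 n_used = nrow(df))
}

#' Demographic scan over a set of units
#'
#' Runs [representative_course()] + [demographic_regression()] for every
#' listed unit and applies Bonferroni control with family size
#' `n_units x n_predictors`.
#'
#' @param mmcus An `mmcu_set` or list of units (typically the reliable ones).
#' @param decompositions The discover-stage decompositions.
#' @param demographics Demographics tibble for the discover cohort.
#' @param predictors Predictors to test.
#' @param legacy_alpha Optional fixed raw-p threshold reported alongside the
#'   Bonferroni flag (`NULL` to omit).
#' @return A `demographic_scan` tibble: `unit_id`, `predictor`, `beta`, `t`,
#'   `p`, `p_bonferroni`, `significant` (adjusted p < 0.05), and
#'   `significant_legacy` when `legacy_alpha` is given.
#' @export
demographic_scan <- function(mmcus, decompositions, demographics,
                             predictors = c("age", "sex", "handedness"),
                             legacy_alpha = NULL) {
  units <- if (inherits(mmcus, "mmcu_set")) mmcus$units else mmcus
  if (length(units) == 0) {
    return(tibble::tibble(unit_id = integer(), predictor = character(),
                          beta = double(), t = double(), p = double(),
                          p_bonferroni = double(), significant = logical()))
  }
  res <- purrr::map_dfr(units, function(u) {
    rc <- representative_course(u, decompositions)
    demographic_regression(rc, demographics, predictors) |>
      dplyr::mutate(unit_id = u$unit_id, .before = 1)
  })
  res$p_bonferroni <- pmin(1, res$p * length(units) * length(predictors))
  res$significant <- res$p_bonferroni < 0.05
  if (!is.null(legacy_alpha)) res$significant_legacy <- res$p < legacy_alpha
  class(res) <- c("demographic_scan", class(res))
  res
}
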
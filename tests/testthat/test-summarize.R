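mk_unit <- function(id, members, off) {
  p <- length(members)
  cv <- diag(p)
  cv[upper.tri(cv)] <- off
  cv[lower.tri(cv)] <- t(cv)[lower.tri(cv)]
  dimnames(cv) <- list(names(members), names(members))
  list(unit_id = id, members = members, covariance = cv)
}

test_that("overall covariance averages Fisher-Z over supporting units only", {
  u1 <- mk_unit(1L, c(a = 1L, b = 1L, c = 1L), c(0.5, 0.3, 0.2))
  u2 <- mk_unit(2L, c(a = 2L, b = 2L), 0.7)
  u3 <- mk_unit(3L, c(b = 3L, c = 2L), -0.5)
  ov <- overall_covariance(list(u1, u2, u3), metrics = c("a", "b", "c"))
  expect_equal(ov$z_matrix["a", "b"], mean(atanh(c(0.5, 0.7))))
  expect_equal(ov$z_matrix["a", "c"], atanh(0.3))
  expect_equal(ov$z_matrix["b", "c"], mean(atanh(c(0.2, -0.5))))
  expect_equal(ov$support["a", "b"], 2L)
  expect_equal(ov$support["a", "c"], 1L)
  expect_equal(ov$z_matrix, t(ov$z_matrix))
  # opposite correlations cancel in Z space
  w1 <- mk_unit(1L, c(a = 1L, b = 1L), 0.5)
  w2 <- mk_unit(2L, c(a = 2L, b = 2L), -0.5)
  expect_equal(overall_covariance(list(w1, w2),
                                  metrics = c("a", "b"))$z_matrix["a", "b"],
               0)
  # single unit: overall = its Fisher-Z matrix
  ov1 <- overall_covariance(list(u1), metrics = c("a", "b", "c"))
  expect_equal(ov1$z_matrix["a", "b"], atanh(0.5))
  # invariant to unit ordering
  ov_rev <- overall_covariance(list(u3, u2, u1), metrics = c("a", "b", "c"))
  expect_equal(ov$z_matrix, ov_rev$z_matrix)
  # unsupported pair flagged missing
  ov2 <- overall_covariance(list(u2), metrics = c("a", "b", "c"))
  expect_true(is.na(ov2$z_matrix["a", "c"]))
})

test_that("pair-group tests report the expected degrees of freedom", {
  # complete 12-metric unit set: one unit holding all metrics per component
  mets <- default_metrics()$metric
  set.seed(51)
  units <- lapply(1:3, function(i) {
    mk_unit(i, stats::setNames(rep(i, 12L), mets), runif(66, 0.05, 0.6))
  })
  tests <- pair_group_tests(overall_covariance(units, metrics = mets))
  one_sample <- tests[tests$test == "one_sample", ]
  expect_equal(one_sample$df[one_sample$group_a == "all_pairs"], 65)
  expect_equal(one_sample$df[one_sample$group_a == "cross"], 35)
  expect_equal(one_sample$n_a, c(66L, 36L))
  welch <- tests[tests$test == "welch", ]
  expect_equal(welch$n_a, c(15L, 15L, 15L))
  expect_equal(welch$n_b, c(36L, 36L, 15L))
  expect_false(any(tests$skipped))
})

test_that("Welch test reduces to Student's df when variances and sizes match", {
  # 4 structural + 4 functional metrics: 6 within-pairs per class
  mets <- c("s1", "s2", "s3", "s4", "f1", "f2", "f3", "f4")
  classes <- stats::setNames(rep(c("structural", "functional"), each = 4),
                             mets)
  within_str <- c(0.10, 0.20, 0.30, 0.40, 0.50, 0.60)
  within_fun <- within_str + 0.15  # identical spread -> equal variance
  z <- matrix(0.05, 8, 8, dimnames = list(mets, mets))
  z[1:4, 1:4][upper.tri(diag(4))] <- within_str
  z[5:8, 5:8][upper.tri(diag(4))] <- within_fun
  z[lower.tri(z)] <- t(z)[lower.tri(z)]
  diag(z) <- NA
  ov <- structure(list(z_matrix = z, support = matrix(1L, 8, 8),
                       metrics = mets), class = "overall_covariance")
  tests <- pair_group_tests(ov, classes = classes)
  w <- tests[tests$test == "welch" & tests$group_b == "within_functional", ]
  expect_equal(w$df, 2 * 6 - 2, tolerance = 1e-12)
  expect_equal(w$estimate, -0.15)
})

test_that("groups too small to test are flagged as skipped", {
  u <- mk_unit(1L, c(vol = 1L, area = 1L), 0.4)
  tests <- pair_group_tests(overall_covariance(list(u),
                                               metrics = c("vol", "area")))
  expect_true(any(tests$skipped))
  expect_true(all(is.na(tests$p[tests$skipped])))
})

test_that("metric clustering follows a hand-traced average linkage", {
  mets <- c("m1", "m2", "m3", "m4")
  z <- matrix(0.1, 4, 4, dimnames = list(mets, mets))
  z["m1", "m2"] <- z["m2", "m1"] <- 0.9
  z["m3", "m4"] <- z["m4", "m3"] <- 0.8
  diag(z) <- NA
  ov <- structure(list(z_matrix = z, support = matrix(1L, 4, 4),
                       metrics = mets), class = "overall_covariance")
  hc <- cluster_metrics(ov)
  # d = max(Z) - Z: merge (m1,m2) at 0, (m3,m4) at 0.1, then both at 0.8
  expect_equal(hc$height, c(0, 0.1, 0.8), tolerance = 1e-12)
  # first cut separates the two planted blocks
  groups <- stats::cutree(hc, k = 2)
  expect_equal(groups[["m1"]], groups[["m2"]])
  expect_equal(groups[["m3"]], groups[["m4"]])
  expect_false(groups[["m1"]] == groups[["m3"]])
  # permuting metric order preserves tree topology
  perm <- c("m3", "m1", "m4", "m2")
  ovp <- structure(list(z_matrix = z[perm, perm],
                        support = matrix(1L, 4, 4), metrics = perm),
                   class = "overall_covariance")
  hcp <- cluster_metrics(ovp)
  expect_equal(sort(hcp$height), sort(hc$height), tolerance = 1e-12)
  gp <- stats::cutree(hcp, k = 2)
  expect_equal(gp[["m1"]], gp[["m2"]])
  # missing cells impute to 0 with a warning
  z2 <- z; z2["m1", "m3"] <- z2["m3", "m1"] <- NA
  ov2 <- structure(list(z_matrix = z2, support = matrix(1L, 4, 4),
                        metrics = mets), class = "overall_covariance")
  expect_warning(cluster_metrics(ov2), "imputed")
})

test_that("dominant-unit lookup ranks by spatial consistency with a query set", {
  sim <- small_sim(seed = 52, snr = 5)
  dec <- decompose_cohort(sim$discover, k = 4, seed = 52)
  mm <- graicar_align(dec)
  rec <- score_recovery(mm, sim$truth, dec)
  # query = the support of unit 1's vol map: its MMCU must rank first
  w <- sim$truth$spatial_maps$discover[[1]]$vol
  query <- which(w != 0)
  ranked <- locate_dominant_mmcu("vol", query, mm, dec)
  expect_equal(ranked$unit_id[1], rec$units$matched_mmcu[1])
  # covariates column carries co-varying members with their r
  expect_true(all(c("metric", "r") %in% names(ranked$covariates[[1]])))
  # indicator mode: disjoint query has ~zero consistency for a flat SCM
  flat <- structure(list(units = mm$units, singletons = integer(0),
                         fsm = mm$fsm), class = "mmcu_set")
  ranked_ind <- locate_dominant_mmcu("vol", query, flat, dec,
                                     mode = "indicator")
  expect_equal(ranked_ind$unit_id[1], rec$units$matched_mmcu[1])
  # metric absent from all units: empty result
  none <- locate_dominant_mmcu("notametric", query, mm, dec)
  expect_equal(nrow(none), 0)
})
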
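test_that("generated cohorts have declared shapes, finite values, and planted membership", {
  sim <- small_sim(seed = 3)
  expect_s3_class(sim$discover, "cohort_bundle")
  expect_equal(n_subjects(sim$discover), 80)
  expect_equal(n_subjects(sim$confirm), 120)
  expect_equal(n_vertices(sim$discover), 400)
  expect_named(sim$discover$metrics, c("vol", "area", "alff", "ec"))
  for (m in sim$discover$metrics) expect_true(all(is.finite(m)))
  # two units over staggered 3-metric subsets
  expect_equal(nrow(sim$truth$membership), 6)
  expect_true(all(table(sim$truth$membership$metric) <= 4))
  # per-metric slots are distinct
  dup <- sim$truth$membership |>
    dplyr::count(metric, component) |>
    dplyr::filter(n > 1)
  expect_equal(nrow(dup), 0)
})

test_that("identical seed and config give identical cohorts; different seeds differ", {
  a <- small_sim(seed = 9)
  b <- small_sim(seed = 9)
  c <- small_sim(seed = 10)
  expect_identical(a$discover$metrics, b$discover$metrics)
  expect_identical(a$truth$loadings, b$truth$loadings)
  expect_false(identical(a$discover$metrics$vol, c$discover$metrics$vol))
})

test_that("coupling rho controls cross-metric loading correlation (rho^2 law)", {
  two_metric_cfg <- function(rho, n, seed) {
    synthetic_config(n_discover = n, n_confirm = 20, v = 60,
                     metrics = c("m1", "m2"), components_per_metric = 1L,
                     planted_units = tibble::tibble(
                       unit = 1L, metrics = list(c("m1", "m2")),
                       rho = rho, replicable = TRUE),
                     snr = 100, seed = seed)
  }
  loading_cor <- function(rho, n, seed) {
    sim <- simulate_cohorts(two_metric_cfg(rho, n, seed))
    # recover per-metric planted loadings from the noiseless-ish matrices:
    # regress each metric matrix onto its true spatial map
    w1 <- sim$truth$spatial_maps$discover[[1]]$m1
    w2 <- sim$truth$spatial_maps$discover[[1]]$m2
    u1 <- sim$discover$metrics$m1 %*% w1
    u2 <- sim$discover$metrics$m2 %*% w2
    cor(u1, u2)
  }
  # rho = 1: loadings shared exactly (snr high)
  expect_gt(loading_cor(1, 100, 1), 0.99)
  # rho = 0.9, n = 200: mean empirical correlation ~ 0.81 within +/- 0.05
  rs <- vapply(1:40, function(s) loading_cor(0.9, 200, s), numeric(1))
  expect_lt(abs(mean(rs) - 0.81), 0.05)
  # rho = 0: mean correlation ~ 0
  r0 <- vapply(1:40, function(s) loading_cor(0, 200, s), numeric(1))
  expect_lt(abs(mean(r0)), 0.05)
})

test_that("empirical loading correlation converges to rho^2 as n grows", {
  dev_at_n <- function(n) {
    errs <- vapply(1:12, function(s) {
      sim <- simulate_cohorts(synthetic_config(
        n_discover = n, n_confirm = 20, v = 60,
        metrics = c("m1", "m2"), components_per_metric = 1L,
        planted_units = tibble::tibble(unit = 1L,
                                       metrics = list(c("m1", "m2")),
                                       rho = 0.9, replicable = TRUE),
        snr = 100, seed = 1000 + s))
      w1 <- sim$truth$spatial_maps$discover[[1]]$m1
      w2 <- sim$truth$spatial_maps$discover[[1]]$m2
      abs(cor(sim$discover$metrics$m1 %*% w1,
              sim$discover$metrics$m2 %*% w2) - 0.81)
    }, numeric(1))
    mean(errs)
  }
  devs <- vapply(c(50, 200, 800), dev_at_n, numeric(1))
  expect_lt(devs[3], devs[1])  # tighter at larger n
  expect_lt(devs[3], 0.03)
})

test_that("replicable units reuse spatial maps across cohorts; non-replicable do not", {
  rep_sim <- small_sim(seed = 5, replicable = TRUE)
  expect_identical(rep_sim$truth$spatial_maps$discover,
                   rep_sim$truth$spatial_maps$confirm)
  non_sim <- small_sim(seed = 5, replicable = FALSE)
  expect_false(identical(non_sim$truth$spatial_maps$discover[[1]]$vol,
                         non_sim$truth$spatial_maps$confirm[[1]]$vol))
  # loadings are independently drawn per cohort either way
  expect_false(identical(rep_sim$truth$loadings$discover[[1]],
                         rep_sim$truth$loadings$confirm[[1]]))
})

test_that("component budget violations and bad configs are rejected", {
  expect_error(synthetic_config(metrics = c("a", "b"),
                                components_per_metric = 1L,
                                n_units = 2L, unit_size = 2L),
               "budget")
  expect_error(synthetic_config(
    planted_units = tibble::tibble(unit = 1L, metrics = list("vol"),
                                   rho = 0.5, replicable = TRUE)),
    "at least 2 metrics")
  expect_error(synthetic_config(rho = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_config(snr = 0), "snr")
})

test_that("demographic effects shift the designated unit's shared loading", {
  sim <- simulate_cohorts(synthetic_config(
    n_discover = 200, n_confirm = 20, v = 60,
    metrics = c("m1", "m2"), components_per_metric = 1L,
    planted_units = tibble::tibble(unit = 1L, metrics = list(c("m1", "m2")),
                                   rho = 0.9, replicable = TRUE),
    demographic_effects = tibble::tibble(unit = 1L, predictor = "sex",
                                         beta = 1.5),
    snr = 10, seed = 2))
  g <- sim$truth$loadings$discover[[1]]
  expect_gt(abs(cor(g, sim$discover$demographics$sex)), 0.5)
})

test_that("recovery scoring handles exact, partial, and empty assignments", {
  truth0 <- list(membership = tibble::tibble(unit = integer(),
                                             metric = character(),
                                             component = integer()))
  r0 <- score_recovery(NULL, truth0, NULL)
  expect_true(is.na(r0$recall))
  expect_true(is.na(r0$precision))

  # hand-built instance: 2 units x 3 metrics, decompositions = truth maps,
  # mmcu assignment correct except metric C of unit 2 swapped into unit 1
  v <- 30
  set.seed(4)
  maps <- lapply(1:2, function(u) lapply(1:3, function(m) rnorm(v)))
  metrics <- c("A", "B", "C")
  truth <- list(
    membership = tibble::tibble(unit = rep(1:2, each = 3),
                                metric = rep(metrics, 2),
                                component = rep(1:2, each = 3)),
    units = tibble::tibble(unit = 1:2),
    spatial_maps = list(discover = lapply(1:2, function(u) {
      stats::setNames(maps[[u]], metrics)
    }))
  )
  decs <- stats::setNames(lapply(1:3, function(m) {
    scms <- rbind(maps[[1]][[m]], maps[[2]][[m]])
    rownames(scms) <- paste0(metrics[m], "_", 1:2)
    list(metric = metrics[m], scms = scms, k = 2L)
  }), metrics)
  fake_fsm <- list(scm_labels = c("A_1", "A_2", "B_1", "B_2", "C_1", "C_2"))
  mk_unit <- function(id, members, idx) {
    list(unit_id = id, members = members, scm_indices = idx,
         covariance = diag(length(members)))
  }
  mm <- structure(list(units = list(
    mk_unit(1L, c(A = 1L, B = 1L, C = 2L), c(1L, 3L, 6L)),
    mk_unit(2L, c(A = 2L, B = 2L, C = 1L), c(2L, 4L, 5L))),
    singletons = integer(0), fsm = fake_fsm), class = "mmcu_set")
  rec <- score_recovery(mm, truth, decs)
  # per unit: pairs (A,B), (A,C), (B,C); with C swapped only (A,B) survives
  expect_equal(rec$recall, 2 / 6)
  expect_equal(rec$units$mean_abs_spatial_cor, c(1, 1), tolerance = 1e-12)

  # fully correct assignment: recall and precision 1
  mm2 <- structure(list(units = list(
    mk_unit(1L, c(A = 1L, B = 1L, C = 1L), c(1L, 3L, 5L)),
    mk_unit(2L, c(A = 2L, B = 2L, C = 2L), c(2L, 4L, 6L))),
    singletons = integer(0), fsm = fake_fsm), class = "mmcu_set")
  rec2 <- score_recovery(mm2, truth, decs)
  expect_equal(rec2$recall, 1)
  expect_equal(rec2$precision, 1)
})
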
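make_decomp <- function(metric, courses) {
  k <- ncol(courses)
  list(metric = metric, courses = courses,
       scms = matrix(rnorm(k * 10), k, 10), k = k)
}

test_that("full similarity matrix holds signed course correlations in metric blocks", {
  n <- 20
  set.seed(31)
  base <- rnorm(n)
  dA <- make_decomp("A", cbind(base, rnorm(n)))
  dB <- make_decomp("B", cbind(base, rnorm(n)))
  fsm <- build_fsm(list(A = dA, B = dB))
  expect_equal(dim(fsm$sims), c(4, 4))
  expect_equal(diag(fsm$sims), rep(1, 4), ignore_attr = TRUE)
  expect_equal(fsm$sims, t(fsm$sims))
  expect_equal(fsm$sims[1, 3], 1)   # identical courses
  expect_equal(fsm$block, c(1, 1, 2, 2))
  # orthogonal +/-1 patterns give exactly zero similarity
  o1 <- rep(c(1, -1), each = 10)
  o2 <- rep(c(1, -1), times = 10)
  f2 <- build_fsm(list(A = make_decomp("A", cbind(o1, rnorm(n))),
                       B = make_decomp("B", cbind(o2, rnorm(n)))))
  expect_equal(f2$sims[1, 3], 0)
  # hand-computed Pearson r for (1,2,3,4) vs (2,4,6,9): 11.5 / sqrt(5 * 26.75)
  f3 <- build_fsm(list(A = make_decomp("A", cbind(1:4, c(1, 3, 2, 4))),
                       B = make_decomp("B", cbind(c(2, 4, 6, 9),
                                                  c(4, 1, 3, 2)))))
  expect_equal(round(f3$sims[1, 3], 4), round(11.5 / sqrt(5 * 26.75), 4))
  # zero-variance course is a hard error naming the component
  dz <- make_decomp("B", cbind(rep(1, n), rnorm(n)))
  colnames(dz$courses) <- c("B_1", "B_2")
  expect_error(build_fsm(list(A = dA, B = dz)), "Zero-variance")
})

test_that("zrow standardizes within row-block segments with population SD", {
  fsm <- toy_fsm()
  fsm <- zrow_normalize(fsm)
  # two-element segments always standardize to -1 / +1
  expect_equal(unname(fsm$zrow[1, 3:4]), c(1, -1))
  expect_equal(unname(fsm$zrow[2, 3:4]), c(-1, 1))
  # three-element segment check on a larger synthetic block:
  # (0, 0.5, 1) -> (-1.2247, 0, 1.2247)
  S <- diag(5)
  S[1, 3:5] <- c(0, 0.5, 1); S[3:5, 1] <- c(0, 0.5, 1)
  f <- structure(list(sims = S, block = c(1, 1, 2, 2, 2),
                      metric_levels = c("A", "B"),
                      scm_labels = paste0("s", 1:5)),
                 class = "covunit_fsm")
  z <- zrow_normalize(f)$zrow[1, 3:5]
  expect_equal(unname(round(z, 4)), c(-1.2247, 0, 1.2247))
  # location invariance: adding a constant to the whole segment changes nothing
  S2 <- S; S2[1, 3:5] <- S[1, 3:5] + 5
  f2 <- f; f2$sims <- S2
  expect_equal(zrow_normalize(f2)$zrow[1, 3:5], z)
  # zero-variance segment maps to 0
  S3 <- S; S3[1, 3:5] <- 0.1
  f3 <- f; f3$sims <- S3
  expect_equal(unname(zrow_normalize(f3)$zrow[1, 3:5]), c(0, 0, 0))
})

test_that("zmax keeps one maximum per off-block segment with low-index ties", {
  fsm <- zmax_mask(zrow_normalize(toy_fsm()))
  # own-metric block fully zeroed
  expect_true(all(fsm$zmax[1:2, 1:2] == 0))
  # one nonzero per row per other metric
  for (i in 1:6) {
    for (b in 1:3) {
      idx <- which(fsm$block == b)
      nz <- sum(fsm$zmax[i, idx] != 0)
      expect_equal(nz, if (fsm$block[i] == b) 0L else 1L)
    }
  }
  # tie within a segment goes to the lower column index
  S <- diag(5)
  S[1, 3:5] <- c(0.5, 0.5, 0.1); S[3:5, 1] <- c(0.5, 0.5, 0.1)
  S[2, 3:5] <- c(0.1, 0.2, 0.7); S[3:5, 2] <- c(0.1, 0.2, 0.7)
  f <- structure(list(sims = S, block = c(1, 1, 2, 2, 2),
                      metric_levels = c("A", "B"),
                      scm_labels = paste0("s", 1:5)),
                 class = "covunit_fsm")
  zm <- zmax_mask(zrow_normalize(f))$zmax
  expect_true(zm[1, 3] != 0)   # first of the tied maxima
  expect_true(zm[1, 4] == 0)
})

test_that("popularity matches hand arithmetic on the 6x6 toy and drops unpaired maxima", {
  fsm <- popularity_rank(toy_fsm())
  # every 2-element segment z-scores to +/-1, so each mutual best match
  # contributes exactly 1; hand count: A1<->B1, A1<->C1, A2<->B2, B1<->C1,
  # B2<->C2 are mutual; A2->C1 and C2->A2 are unpaired and contribute 0
  expect_equal(unname(fsm$popularity), c(2, 1, 2, 2, 2, 1))
  # standardized FSM is zrow + its transpose
  expect_equal(fsm$standardized, fsm$zrow + t(fsm$zrow))
  # two metrics, one strongly-matched component pair: popularity is the
  # product of the two (here trivially z = 0 segments of size 1 -> 0)
  S <- matrix(c(1, 0.8, 0.8, 1), 2)
  f1 <- structure(list(sims = S, block = c(1, 2),
                       metric_levels = c("A", "B"), scm_labels = c("a", "b")),
                  class = "covunit_fsm")
  p1 <- popularity_rank(f1)
  expect_equal(unname(p1$popularity), c(0, 0))  # single-component segments
})

test_that("extraction reproduces the toy matching and discards singletons", {
  mm <- extract_mmcus(toy_fsm())
  expect_length(mm$units, 2)
  expect_equal(mm$units[[1]]$members, c(A = 1L, B = 1L, C = 1L))
  expect_equal(mm$units[[2]]$members, c(A = 2L, B = 2L, C = 2L))
  # covariance = raw sims submatrix in configured metric order
  expect_equal(mm$units[[1]]$covariance["A", "B"], 0.9)
  expect_equal(mm$units[[1]]$covariance["A", "C"], 0.7)
  expect_equal(mm$units[[1]]$covariance["B", "C"], 0.5)
  expect_equal(diag(mm$units[[1]]$covariance), c(A = 1, B = 1, C = 1))

  # block-diagonal perfect matching on 2 metrics x 2 components
  S <- diag(4)
  S[1, 3] <- S[3, 1] <- 0.9
  S[2, 4] <- S[4, 2] <- 0.85
  S[1, 4] <- S[4, 1] <- -0.2
  S[2, 3] <- S[3, 2] <- -0.1
  f <- structure(list(sims = S, block = c(1, 1, 2, 2),
                      metric_levels = c("A", "B"),
                      scm_labels = paste0("s", 1:4)),
                 class = "covunit_fsm")
  mm2 <- extract_mmcus(f)
  expect_length(mm2$units, 2)
  # exact popularity ties make the anchor order arbitrary; the matching is not
  sets <- lapply(mm2$units, `[[`, "members")
  expect_true(list(c(A = 1L, B = 1L)) %in% sets || any(vapply(sets, identical, logical(1), c(A = 1L, B = 1L))))
  expect_true(any(vapply(sets, identical, logical(1), c(A = 2L, B = 2L))))
})

test_that("every SCM lands in exactly one unit or the singleton list", {
  sim <- small_sim(seed = 12)
  dec <- decompose_cohort(sim$discover, k = 4, seed = 12)
  mm <- graicar_align(dec)
  all_idx <- sort(c(unlist(lapply(mm$units, `[[`, "scm_indices")),
                    mm$singletons))
  expect_equal(all_idx, seq_len(sum(vapply(dec, `[[`, integer(1), "k"))))
  # no metric appears twice within one unit
  for (u in mm$units) {
    expect_equal(anyDuplicated(names(u$members)), 0)
  }
  # unit count = second-largest per-metric component count when all anchors
  # find partners
  if (length(mm$singletons) == 0) {
    ks <- sort(unname(vapply(dec, `[[`, integer(1), "k")), decreasing = TRUE)
    expect_equal(length(mm$units), ks[2])
  }
  # covariance entries equal direct recomputation from stored courses
  u <- mm$units[[1]]
  mets <- names(u$members)
  for (a in seq_along(mets)) {
    for (b in seq_along(mets)) {
      ca <- dec[[mets[a]]]$courses[, u$members[[a]]]
      cb <- dec[[mets[b]]]$courses[, u$members[[b]]]
      expect_equal(u$covariance[a, b], cor(ca, cb), tolerance = 1e-12)
    }
  }
})

test_that("metric relabeling permutes alignment outputs consistently", {
  sim <- small_sim(seed = 13)
  dec <- decompose_cohort(sim$discover, k = 4, seed = 13)
  mm <- graicar_align(dec)
  perm <- c("ec", "vol", "alff", "area")
  mm_p <- graicar_align(dec[perm])
  # same number of units; each unit's member set identical up to metric order
  expect_equal(length(mm$units), length(mm_p$units))
  sets <- function(m) {
    lapply(m$units, function(u) sort(paste0(names(u$members), ":",
                                            u$members)))
  }
  expect_setequal(sets(mm), sets(mm_p))
})

test_that("unpaired best matches contribute zero popularity", {
  # A1 best-matches B1, but B1 best-matches A2: the (A1, B1) product is 0
  S <- diag(4)
  S[1, 3] <- S[3, 1] <- 0.6   # A1-B1
  S[1, 4] <- S[4, 1] <- 0.2   # A1-B2
  S[2, 3] <- S[3, 2] <- 0.9   # A2-B1
  S[2, 4] <- S[4, 2] <- -0.5  # A2-B2
  f <- structure(list(sims = S, block = c(1, 1, 2, 2),
                      metric_levels = c("A", "B"),
                      scm_labels = paste0("s", 1:4)),
                 class = "covunit_fsm")
  p <- popularity_rank(f)
  # zrow: A1 row (0.6, 0.2) -> (+1, -1); A2 row (0.9, -0.5) -> (+1, -1)
  # B1 row over A: (0.6, 0.9) -> (-1, +1); B2 row over A: (0.2, -0.5) -> (+1, -1)
  # mutual products: A1-B1: 1 * (-1) = -1? no: zmax keeps maxima only:
  # A1->B1 (1), A2->B1 (1), B1->A2 (1), B2->A1 (1)
  # elementwise products: (A1,B1): zmax[1,3]*zmax[3,1] = 1 * 0 = 0
  # (A2,B1): zmax[2,3] * zmax[3,2] = 1 * 1 = 1; (B2,A1): 1 * 0 = 0
  expect_equal(unname(p$popularity), c(0, 1, 1, 0))
})
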
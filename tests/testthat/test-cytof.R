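test_that("arsinh transform matches its closed form and is odd", {
  expect_identical(arsinhTransform(0), 0)
  expect_equal(arsinhTransform(5, cofactor = 5), log(1 + sqrt(2)),
               tolerance = 1e-12)
  expect_equal(arsinhTransform(-5, 5), -arsinhTransform(5, 5))
  x <- seq(-20, 20, by = 2.5)
  expect_true(all(diff(arsinhTransform(x, 5)) > 0))
  expect_error(arsinhTransform(Inf), "finite")
  expect_error(arsinhTransform(1, cofactor = 0), "positive")
})

test_that("reference construction recovers known mean and covariance", {
  panel <- MarkerPanel(c("m1", "m2"), cofactor = 5)
  set.seed(11)
  mu <- c(1.2, -0.4)                       # arsinh scale
  z <- cbind(rnorm(6000, mu[1]), rnorm(6000, mu[2]))
  raw <- sinh(z) * 5
  colnames(raw) <- c("m1", "m2")
  ref <- buildReference(list(stage1 = raw), panel, shrinkage = 0)
  expect_equal(unname(stageMeans(ref)[1, ]), mu, tolerance = 0.05)
  expect_equal(unname(stageCovariances(ref)[[1]]), diag(2),
               tolerance = 0.07)
})

test_that("degenerate gated stages are rejected or regularized", {
  panel <- MarkerPanel(c("m1", "m2"))
  dup <- matrix(rep(c(1, 2), each = 10), ncol = 2,
                dimnames = list(NULL, c("m1", "m2")))
  expect_error(buildReference(list(s = dup), panel, shrinkage = 0),
               "singular")
  expect_error(buildReference(list(s = dup[1:3, ]), panel),
               "at least")
  # shrinkage = 1 forces an exactly diagonal covariance
  set.seed(2)
  m <- matrix(rnorm(400), ncol = 2, dimnames = list(NULL, c("m1", "m2")))
  ref <- buildReference(list(s = m), panel, shrinkage = 1)
  S <- stageCovariances(ref)[[1]]
  expect_identical(S[1, 2], 0)
})

test_that("Mahalanobis distance matches hand values and the solve() oracle", {
  expect_equal(mahalanobisDistance(c(0, 0), c(0, 0), diag(2)), 0)
  expect_equal(mahalanobisDistance(c(3, 4), c(0, 0), diag(2)), 5)
  expect_equal(mahalanobisDistance(c(2, 1), c(0, 0), diag(c(4, 1))),
               sqrt(2), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:25) {
    p <- sample(2:6, 1)
    A <- matrix(rnorm(p * p), p)
    S <- crossprod(A) + diag(p)
    x <- rnorm(p); mu <- rnorm(p)
    expect_equal(mahalanobisDistance(x, mu, S), oracle_mahal(x, mu, S),
                 tolerance = 1e-9)
  }
  expect_error(mahalanobisDistance(c(1, 2, 3), c(0, 0), diag(2)),
               "dimension")
})

test_that("event classification agrees exactly with the per-stage argmin oracle", {
  sim <- simulateCytof(cytofSimConfig(seed = 9, n_events = 2000,
                                      separation = 3))
  gated <- lapply(split(as.data.frame(sim$events), sim$labels), as.matrix)
  ref <- buildReference(gated, MarkerPanel())
  asn <- classifyEvents(sim$events, ref)

  z <- arsinhTransform(sim$events[, markerNames(ref)], arsinhCofactor(ref))
  oracle <- apply(z, 1L, function(x) {
    d <- vapply(seq_along(stageLabels(ref)), function(j)
      oracle_mahal(x, stageMeans(ref)[j, ], stageCovariances(ref)[[j]]),
      numeric(1))
    stageLabels(ref)[which.min(d)]
  })
  expect_identical(as.character(assignedStages(asn)), unname(oracle))
  expect_true(all(stageDistances(asn) >= 0))
  # assigned label attains the row minimum
  expect_equal(unname(apply(stageDistances(asn), 1L, min)),
               unname(stageDistances(asn)[cbind(seq_len(length(asn)),
                                    as.integer(assignedStages(asn)))]))
})

test_that("an event at a stage mean is assigned there with distance zero", {
  sim <- simulateCytof(cytofSimConfig(seed = 4, n_events = 3000,
                                      stage_labels = sprintf("s%d", 1:4)))
  gated <- lapply(split(as.data.frame(sim$events), sim$labels), as.matrix)
  ref <- buildReference(gated, MarkerPanel())
  raw_at_mean <- matrix(sinh(stageMeans(ref)[3, ]) * arsinhCofactor(ref),
                        nrow = 1, dimnames = list(NULL, markerNames(ref)))
  asn <- classifyEvents(raw_at_mean, ref)
  expect_identical(as.character(assignedStages(asn)), "s3")
  expect_equal(unname(stageDistances(asn)[1, "s3"]), 0,
               tolerance = 1e-8)
})

test_that("distances are invariant to marker order and ties go to the earliest stage", {
  sim <- simulateCytof(cytofSimConfig(seed = 13, n_events = 500))
  gated <- lapply(split(as.data.frame(sim$events), sim$labels), as.matrix)
  ref <- buildReference(gated, MarkerPanel())
  perm <- sample(colnames(sim$events))
  a1 <- classifyEvents(sim$events, ref)
  a2 <- classifyEvents(sim$events[, perm], ref)
  expect_identical(assignedStages(a1), assignedStages(a2))
  expect_equal(stageDistances(a1), stageDistances(a2))

  # two identical stages: the earlier one wins every tie
  panel <- MarkerPanel(c("m1", "m2"))
  set.seed(3)
  m <- matrix(rnorm(600), ncol = 2, dimnames = list(NULL, c("m1", "m2")))
  ref2 <- buildReference(list(first = m, second = m), panel)
  ev <- matrix(rnorm(40), ncol = 2, dimnames = list(NULL, c("m1", "m2")))
  asn <- classifyEvents(ev, ref2)
  expect_true(all(assignedStages(asn) == "first"))

  expect_error(classifyEvents(ev[, 1, drop = FALSE], ref2), "missing")
})

test_that("classification accuracy rises with stage-mean separation", {
  acc <- vapply(c(1.5, 3, 6), function(sep) {
    tr <- simulateCytof(cytofSimConfig(seed = 21, n_events = 3300,
                                       separation = sep))
    gated <- lapply(split(as.data.frame(tr$events), tr$labels), as.matrix)
    ref <- buildReference(gated, MarkerPanel())
    te <- simulateCytof(cytofSimConfig(seed = 22, n_events = 2200,
                                       separation = sep))
    mean(as.character(classifyEvents(te$events, ref)@labels) ==
           as.character(te$labels))
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
  expect_gt(acc[3], 0.95)
})

test_that("stage composition rows are frequencies in developmental order", {
  sim <- simulateCytof(cytofSimConfig(seed = 31, n_events = 2000,
                                      stage_labels = sprintf("s%d", 1:3)))
  gated <- lapply(split(as.data.frame(sim$events), sim$labels), as.matrix)
  ref <- buildReference(gated, MarkerPanel())
  asn <- classifyEvents(sim$events, ref)
  comp <- stageComposition(asn)
  expect_identical(colnames(comp), stageLabels(ref))
  expect_equal(unname(rowSums(comp)), rep(1, nrow(comp)), tolerance = 1e-12)

  # duplicating every event leaves frequencies unchanged
  asn2 <- classifyEvents(rbind(sim$events, sim$events), ref)
  expect_equal(stageComposition(asn2), comp, tolerance = 1e-12)

  # grouped composition: all-one-stage group and an empty-level group
  by <- rep(c("a", "b"), length.out = length(asn))
  comp2 <- suppressWarnings(
    stageComposition(asn, by = factor(by, levels = c("a", "b", "c"))))
  expect_true(all(is.nan(comp2["c", ])))
})

test_that("empty groups warn rather than report silent zeros", {
  sim <- simulateCytof(cytofSimConfig(seed = 31, n_events = 200,
                                      stage_labels = sprintf("s%d", 1:3)))
  gated <- lapply(split(as.data.frame(sim$events), sim$labels), as.matrix)
  ref <- buildReference(gated, MarkerPanel())
  asn <- classifyEvents(sim$events, ref)
  expect_warning(
    stageComposition(asn, by = factor(rep("a", length(asn)),
                                      levels = c("a", "zz"))),
    "no events")
})
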
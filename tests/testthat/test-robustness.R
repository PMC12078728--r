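test_that("error rate counts optimally matched misassignments", {
  truth <- rep(1:4, c(10, 10, 10, 20))
  expect_equal(error_rate(truth, truth)$er, 0)
  # one of 50 items moved
  moved <- truth; moved[1] <- 2L
  expect_equal(error_rate(moved, truth)$er, 2)
  # label permutations are absorbed by the matching
  perm <- c(3L, 1L, 4L, 2L)[truth]
  expect_equal(error_rate(perm, truth)$er, 0)
  expect_equal(error_rate(perm, moved)$er, 2)
})

test_that("error rate is symmetric and label-invariant under random relabels", {
  set.seed(13)
  for (rep in 1:20) {
    truth <- sample(1:4, 40, TRUE)
    pred <- sample(1:5, 40, TRUE)
    er <- error_rate(pred, truth)$er
    relab <- sample(5)[pred]
    expect_equal(error_rate(relab, truth)$er, er)
    expect_equal(error_rate(truth, pred)$er, er)
    expect_gte(er, 0)
    expect_lte(er, 100)
  }
})

test_that("error rate matches items by name and rejects disjoint sets", {
  pred <- c(a = 1L, b = 1L, c = 2L)
  truth <- c(c = 1L, a = 2L, b = 2L)  # same items, different order
  expect_equal(error_rate(pred, truth)$er, 0)
  expect_error(error_rate(pred, c(x = 1L, y = 2L, z = 1L)), "no items")
  expect_error(error_rate(c(1, 2), c(1, 2, 3)), "same item set")
})

test_that("unmatched surplus clusters count entirely as errors", {
  truth <- rep(1:2, each = 4)
  pred <- c(1L, 1L, 3L, 3L, 2L, 2L, 4L, 4L)  # 4 predicted vs 2 true clusters
  # best matching pairs two predicted clusters; the other four items err
  expect_equal(error_rate(pred, truth)$er, 50)
})

test_that("profile distance is the 1-norm", {
  expect_equal(profile_distance(c(0.5, 0.9), c(0.5, 0.1)), 0.8)
  expect_equal(profile_distance(1:3, 1:3), 0)
  expect_error(profile_distance(1:3, 1:2), "length")
  set.seed(4)
  for (rep in 1:20) {
    a <- rnorm(5); b <- rnorm(5); c <- rnorm(5)
    expect_lte(profile_distance(a, c),
               profile_distance(a, b) + profile_distance(b, c) + 1e-12)
  }
})

test_that("robust sensitivity curve is bounded, classical is not", {
  gi <- c(0.5, 0.9); gk <- c(0.5, 0.1)
  grid <- seq(-10, 10, by = 0.5)
  rob <- sensitivity_curve(gi, gk, grid, mode = "robust", reference = 0.5)
  expect_equal(rob$sc, 3 * abs(plogis(grid) - 0.5), tolerance = 1e-12)
  expect_equal(rob$sc[grid == 0], 0)
  # exact bound n * max(ref, 1 - ref)
  expect_true(all(abs(rob$sc) <= 3 * 0.5))
  cls <- sensitivity_curve(gi, gk, grid, mode = "classical", reference = 0.5)
  expect_equal(cls$sc, 3 * abs(grid - 0.5), tolerance = 1e-12)
  expect_gt(max(cls$sc), max(rob$sc))
  # contaminant whose transformed value equals the reference has no influence
  expect_equal(sensitivity_curve(gi, gk, 0, mode = "robust",
                                 reference = 0.5)$sc, 0)
})

test_that("default reference is the mean of gene k's analysis-scale profile", {
  gi <- c(-1, 0, 2); gk <- c(1, 0, -2)
  rob <- sensitivity_curve(gi, gk, c(-10, 0, 10), mode = "robust")
  ref <- mean(plogis(gk))
  expect_equal(attr(rob, "reference"), ref)
  expect_equal(rob$sc, 4 * abs(plogis(c(-10, 0, 10)) - ref))
  expect_error(sensitivity_curve(numeric(0), numeric(0)), "non-empty")
})

test_that("classical curve dominates the robust one at grid extremes", {
  set.seed(21)
  for (rep in 1:10) {
    gi <- runif(6, -3, 3); gk <- runif(6, -3, 3)
    rob <- sensitivity_curve(gi, gk, c(-10, 10), mode = "robust")
    cls <- sensitivity_curve(gi, gk, c(-10, 10), mode = "classical")
    expect_true(all(cls$sc >= rob$sc))
    n <- length(gi) + 1
    ref <- attr(rob, "reference")
    expect_true(all(abs(rob$sc) <= n * max(ref, 1 - ref) + 1e-12))
  }
})

test_that("a small contamination sweep has the right structure and baseline", {
  sw <- contamination_sweep(n_seeds = 3, thcm_rates = c(0, 0.2),
                            icm_rates = 0.0125,
                            combos = data.frame(metric = "euclidean",
                                                linkage = "ward.D2"),
                            seed = 11)
  expect_equal(nrow(sw), 3 * 1 * 2)  # |rates| x |combos| x |modes|
  expect_setequal(sw$mode, c("robust", "classical"))
  # no contamination: both modes recover the truth exactly
  base <- sw[sw$model == "thcm" & sw$rate == 0, ]
  expect_equal(base$mean_er, c(0, 0))
  # contaminated: robust no worse than classical
  cont <- sw[sw$rate > 0, ]
  for (m in unique(cont$model)) {
    expect_lte(cont$mean_er[cont$model == m & cont$mode == "robust"],
               cont$mean_er[cont$model == m & cont$mode == "classical"])
  }
})
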
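test_that("pooled subgroup-means limits match the hand computation", {
  lim <- control_limits(c(0.4, 0.6, 0.2, 0.4), subgroups = c(1, 1, 2, 2),
                        estimator = "xbar_pooled", k_sigma = 3)
  expect_equal(lim$CL, 0.4)
  expect_equal(lim$sigma_hat, sqrt(0.02))
  expect_equal(lim$LCL, 0.1)
  expect_equal(lim$UCL, 0.7)
  expect_equal(lim$nbar, 2)
})

test_that("limits collapse for constant data or k_sigma = 0", {
  for (est in c("individuals", "xbar_pooled")) {
    lim <- control_limits(rep(2, 6), subgroups = rep(1:3, each = 2),
                          estimator = est)
    expect_equal(lim$LCL, 2)
    expect_equal(lim$UCL, 2)
  }
  lim0 <- control_limits(c(1, 2, 3, 4), k_sigma = 0, estimator = "individuals")
  expect_equal(lim0$LCL, lim0$CL)
  expect_equal(lim0$UCL, lim0$CL)
})

test_that("degenerate groupings are rejected", {
  expect_error(control_limits(1:4, estimator = "xbar_pooled"), "subgroups")
  expect_error(control_limits(1:4, subgroups = c(1, 1, 1, 2),
                              estimator = "xbar_pooled"), "2 members")
  expect_error(control_limits(1, estimator = "individuals"), "2 values")
})

test_that("cell calls use inclusive boundaries", {
  f <- matrix(c(-2, 0, 1, 2), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  lim <- structure(list(CL = 0, LCL = -2, UCL = 2, estimator = "individuals",
                        k_sigma = 1, sigma_hat = 2, nbar = 1),
                   class = "control_limits")
  calls <- classify_cells(f, lim)
  expect_equal(as.vector(calls), c("down", "unregulated", "unregulated", "up"))
  # a single cell above the UCL yields exactly one up call
  f2 <- matrix(0, 3, 3); f2[2, 2] <- 5
  expect_equal(sum(classify_cells(f2, lim) == "up"), 1)
})

test_that("noise-free block design cells are called from the mixture sd", {
  sim <- simulate_fcge(noise_var = 0, seed = 1)
  # mixture of 200 cells at +3, 200 at -3, 1400 at 0: sd = sqrt(3600/1799);
  # a 2-sigma chart separates the +/-3 blocks, a 3-sigma chart does not
  lim2 <- control_limits(sim$fcge, estimator = "individuals", k_sigma = 2)
  expect_equal(lim2$sigma_hat, sqrt(3600 / 1799))
  calls <- classify_cells(sim$fcge, lim2)
  expect_true(all(calls[sim$fcge == 3] == "up"))
  expect_true(all(calls[sim$fcge == -3] == "down"))
  expect_true(all(calls[sim$fcge == 0] == "unregulated"))
  lim3 <- control_limits(sim$fcge, estimator = "individuals", k_sigma = 3)
  expect_true(all(classify_cells(sim$fcge, lim3) == "unregulated"))
})

test_that("individuals chart calls are scale equivariant", {
  set.seed(2)
  f <- matrix(rnorm(200), 20, dimnames = list(paste0("g", 1:20), NULL))
  for (c_scale in c(0.5, 3)) {
    a <- classify_cells(f, control_limits(f, estimator = "individuals"))
    b <- classify_cells(c_scale * f,
                        control_limits(c_scale * f, estimator = "individuals"))
    expect_identical(a, b)
  }
})

test_that("widening k_sigma never grows the significant set", {
  sim <- simulate_fcge(seed = 6)
  x <- logistic_transform(sim$fcge)
  blocks <- paste(sim$gene_clusters[rep(rownames(x), ncol(x))],
                  sim$dc_clusters[rep(colnames(x), each = nrow(x))])
  grid <- build_cocluster_grid(x, sim$gene_clusters, sim$dc_clusters)
  n_sig <- vapply(c(0.5, 1, 2, 3, 5, 10), function(k) {
    lim <- control_limits(as.vector(x), blocks, "xbar_pooled", k_sigma = k)
    g <- classify_coclusters(grid, lim)
    sum(g$significance != "insignificant")
  }, numeric(1))
  expect_true(all(diff(n_sig) <= 0))
})

test_that("block calls use strict inequalities", {
  g <- structure(data.frame(gc = 1:2, dcc = c(1L, 1L),
                            aLFCGE = c(0.5, 0.5), n_cells = c(2L, 2L),
                            rank = NA_integer_,
                            significance = NA_character_),
                 gc_map = c(`1` = 1L, `2` = 2L), dcc_map = c(`1` = 1L),
                 ranked = FALSE,
                 class = c("cocluster_grid", "data.frame"))
  lim <- structure(list(CL = 0.5, LCL = 0.5, UCL = 0.5,
                        estimator = "xbar_pooled", k_sigma = 0,
                        sigma_hat = 0, nbar = 2),
                   class = "control_limits")
  out <- classify_coclusters(g, lim)
  expect_equal(out$significance, rep("insignificant", 2))
})
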
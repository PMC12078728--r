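test_that("default design has the documented shape, labels and truth", {
  sim <- simulate_fcge(seed = 1)
  expect_equal(dim(sim$fcge), c(50L, 36L))
  expect_equal(rownames(sim$fcge)[c(1, 50)], c("G1", "G50"))
  expect_true(all(c("C1_High", "C11_Middle", "C12_Low") %in%
                    colnames(sim$fcge)))
  expect_equal(unname(table(sim$gene_clusters)), c(10L, 10L, 10L, 20L),
               ignore_attr = TRUE)
  expect_equal(unname(table(sim$dc_clusters)), c(10L, 10L, 16L),
               ignore_attr = TRUE)
  expect_equal(sim$regulation["GC1", "DCC1"], "up")
  expect_equal(sim$regulation["GC2", "DCC1"], "down")
  expect_equal(sim$regulation["GC4", "DCC3"], "none")
  expect_equal(sum(sim$regulation == "up"), 2)
  expect_equal(sum(sim$regulation == "down"), 2)
})

test_that("zero noise returns the exact block means", {
  sim <- simulate_fcge(noise_var = 0, seed = 1)
  bm <- default_block_means()
  expect_equal(unique(as.vector(sim$fcge)), c(3, -3, 0),
               ignore_attr = TRUE)
  expect_equal(sim$fcge["G1", "C1_High"], bm[1, 1], ignore_attr = TRUE)
  expect_equal(sim$fcge["G15", "C1_High"], bm[2, 1], ignore_attr = TRUE)
})

test_that("noise variance and block means are as configured", {
  set.seed(99)
  pooled <- unlist(lapply(1:20, function(i) {
    sim <- simulate_fcge()
    zero <- sim$fcge[sim$gene_clusters == 4, ]  # all-zero blocks
    as.vector(zero)
  }))
  v <- var(pooled)
  se <- sqrt(2 / (length(pooled) - 1)) * v  # SE of a variance estimate
  expect_lt(abs(v - 0.35), 3 * se)
  # block-mean convergence at n_cells >= 100 within +-3 SE
  sim <- simulate_fcge(seed = 42)
  b11 <- sim$fcge[sim$gene_clusters == 1, sim$dc_clusters == 1]
  expect_lt(abs(mean(b11) - 3), 3 * sqrt(0.35 / length(b11)))
})

test_that("replicate-level mode averages to the returned matrix", {
  sim <- simulate_fcge(m = 3, seed = 7)
  expect_equal(dim(sim$replicates), c(50L, 36L, 3L))
  expect_equal(apply(sim$replicates, c(1, 2), mean), sim$fcge)
})

test_that("config validation catches inconsistent shapes", {
  expect_error(simulate_fcge(gc_sizes = c(5, 5), block_means = default_block_means()),
               "block_means")
  expect_error(simulate_fcge(noise_var = -1), "noise_var")
})

test_that("casewise contamination replaces whole rows at the given rate", {
  sim <- simulate_fcge(seed = 1)
  none <- contaminate_thcm(sim$fcge, 0, seed = 2)
  expect_identical(none$fcge, sim$fcge)
  expect_false(any(none$mask))
  all_rows <- contaminate_thcm(sim$fcge, 1, seed = 2)
  expect_true(all(all_rows$mask))
  # rows are all-or-nothing
  part <- contaminate_thcm(sim$fcge, 0.4, seed = 3)
  per_row <- rowSums(part$mask)
  expect_true(all(per_row %in% c(0L, ncol(sim$fcge))))
  # binomial mean across seeds
  frac <- vapply(1:200, function(s)
    mean(rowSums(contaminate_thcm(sim$fcge, 0.4, seed = s)$mask) > 0),
    numeric(1))
  expect_equal(mean(frac), 0.4, tolerance = 0.03)
})

test_that("cellwise contamination hits cells independently", {
  sim <- simulate_fcge(seed = 1)
  none <- contaminate_icm(sim$fcge, 0, seed = 2)
  expect_identical(none$fcge, sim$fcge)
  full <- contaminate_icm(sim$fcge, 1, seed = 2)
  expect_true(all(full$mask))
  expect_true(all(abs(abs(full$fcge) - 10) < 6))  # contaminant N(+/-10, 1)
  # casewise-equivalent rate at the sweep endpoint
  expect_equal(icm_casewise_rate(0.025, 36), 1 - 0.975^36)
  expect_equal(icm_casewise_rate(0.025, 36), 0.598, tolerance = 1e-3)
  touched <- vapply(1:300, function(s)
    mean(rowSums(contaminate_icm(sim$fcge, 0.025, seed = s)$mask) > 0),
    numeric(1))
  expect_equal(mean(touched), icm_casewise_rate(0.025, 36), tolerance = 0.02)
})

test_that("contamination is reproducible given the seed", {
  sim <- simulate_fcge(seed = 1)
  a <- contaminate_thcm(sim$fcge, 0.3, seed = 5)
  b <- contaminate_thcm(sim$fcge, 0.3, seed = 5)
  expect_identical(a, b)
  c1 <- contaminate_icm(sim$fcge, 0.1, seed = 5)
  c2 <- contaminate_icm(sim$fcge, 0.1, seed = 5)
  expect_identical(c1, c2)
  s1 <- simulate_fcge(seed = 123)
  s2 <- simulate_fcge(seed = 123)
  expect_identical(s1$fcge, s2$fcge)
})
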
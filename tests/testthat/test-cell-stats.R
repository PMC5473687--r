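test_that("erosion split reproduces square-frame arithmetic", {
  mask <- matrix(FALSE, 25, 25)
  mask[3:23, 3:23] <- TRUE  # solid 21 x 21 square
  rm2 <- split_periphery_interior(mask, depth = 2)
  expect_equal(sum(rm2$interior), 17^2)
  expect_equal(sum(rm2$periphery), 21^2 - 17^2)  # 152
  expect_true(all(xor(rm2$interior, rm2$periphery) == mask))
  expect_error(split_periphery_interior(mask, depth = 11), "smaller depth")
})

test_that("internal holes belong to the interior side of the split", {
  mask <- matrix(FALSE, 31, 31)
  mask[4:28, 4:28] <- TRUE
  mask[14:18, 14:18] <- FALSE   # nucleus-like hole
  rms <- split_periphery_interior(mask, depth = 2)
  # no periphery pixels adjacent to the hole: the band hugs the outline only
  expect_true(all(which(rms$periphery, arr.ind = TRUE)[, 1] %in%
                    c(4, 5, 27, 28) |
                  which(rms$periphery, arr.ind = TRUE)[, 2] %in%
                    c(4, 5, 27, 28)))
})

test_that("manual region masks pass validation unchanged", {
  a <- matrix(FALSE, 10, 10); a[3:8, 3:8] <- TRUE
  b <- matrix(FALSE, 10, 10); b[1, ] <- TRUE
  rm <- region_masks(interior = a, periphery = b)
  expect_identical(rm$interior, a)
  expect_identical(rm$periphery, b)
  expect_error(region_masks(a, a), "overlap")
})

test_that("homogeneous cells show no periphery/interior lifetime contrast", {
  g <- small_geometry()
  cell <- simulate_cell(g, "donor_only", 750000, seed = 18, n_bins = 250L)
  pair <- region_lifetime_pair(cell$cube,
                               split_periphery_interior(g$cell, 2),
                               DEFAULT_IRF)
  expect_lt(abs(pair["tau_P"] - pair["tau_I"]), 0.020)
})

test_that("the endosomal preset flips the periphery/interior sign", {
  g <- small_geometry()
  cell <- simulate_cell(g, "stx3_vamp8", 400000, seed = 19, n_bins = 250L,
                        acceptor_intensity = 1.5)
  pair <- region_lifetime_pair(cell$cube,
                               split_periphery_interior(g$cell, 2),
                               DEFAULT_IRF)
  expect_gt(pair["tau_P"], pair["tau_I"])  # quenching inside, not at the rim
})

test_that("linear_regression matches hand-computed OLS", {
  r <- linear_regression(c(1, 2, 3), c(1, 3, 2))
  expect_equal(r$slope, 0.5)
  expect_equal(r$r_squared, 0.25)
  exact <- linear_regression(1:10, 2 * (1:10))
  expect_equal(exact$slope, 2)
  expect_equal(exact$r_squared, 1)
  flat <- linear_regression(1:10, rep(3, 10))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_error(linear_regression(rep(1, 5), 1:5), "zero variance")
  expect_error(linear_regression(1:2, 1:2), "at least 3")
})

test_that("group comparison handles identical, separated and invalid designs", {
  # two identical groups: adjusted p = 1
  v <- c(1, 2, 3, 4, 1, 2, 3, 4)
  g <- rep(c("a", "b"), each = 4)
  res <- compare_groups(v, g, design = "paired")
  expect_equal(res$pairwise$p_adjusted, 1)
  # constant positive paired difference: p below any conventional level
  res2 <- compare_groups(c(1, 2, 3, 4, 1.9, 3.1, 3.9, 5.1),
                         g, design = "paired")
  expect_lt(res2$pairwise$p_value, 0.01)
  expect_lt(res2$pairwise$statistic, 0)  # first group is uniformly lower
  # independent design reports ANOVA and bonferroni over declared pairs
  withr::with_seed(7, {
    v3 <- rnorm(30)
    g3 <- rep(c("a", "b", "c"), each = 10)
  })
  res3 <- compare_groups(v3, g3, pairs = list(c("a", "b"), c("a", "c")))
  expect_equal(nrow(res3$pairwise), 2)
  expect_equal(res3$pairwise$p_adjusted,
               pmin(res3$pairwise$p_value * 2, 1))
  expect_true(res3$anova$p > 0 && res3$anova$p <= 1)
  expect_error(compare_groups(1:3, c("a", "a", "b")), "at least 2 obs")
  expect_error(compare_groups(1:4, rep("a", 4)), "at least 2 groups")
})

test_that("bonferroni-corrected null comparisons keep type-I error at bay", {
  # split a null cohort into 3 groups at random, many replicates
  withr::with_seed(123, {
    rej <- replicate(200, {
      v <- rnorm(30, mean = 2.79, sd = 0.02)
      g <- sample(rep(c("a", "b", "c"), each = 10))
      res <- compare_groups(v, g)
      any(res$pairwise$p_adjusted < 0.05)
    })
  })
  expect_lte(mean(rej), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 200))
})

test_that("pearson colocalization obeys its identities", {
  withr::with_seed(3, a <- matrix(runif(100), 10, 10))
  expect_equal(pearson_colocalization(a, a), 1)
  expect_equal(pearson_colocalization(a, -a + 5), -1)
  # affine invariance of either channel
  b <- matrix(runif(100), 10, 10)
  expect_equal(pearson_colocalization(a, b),
               pearson_colocalization(2 * a + 1, 0.3 * b - 7))
  expect_error(pearson_colocalization(a, matrix(1, 10, 10)), "variance")
})

test_that("a juxtanuclear acceptor blob lowers colocalization monotonically", {
  g <- small_geometry()
  r <- vapply(c(0.3, 1, 3), function(contrast) {
    cell <- simulate_cell(g, "tandem", 200000, seed = 44, n_bins = 32L,
                          acceptor_blob_contrast = contrast)
    pearson_colocalization(cube_intensity(cell$cube), cell$acceptor_map,
                           g$cell)
  }, 0)
  expect_true(all(r > 0 & r < 1))
  expect_true(all(diff(r) < 0))
})
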
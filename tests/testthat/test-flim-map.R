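test_that("radius 0 binning is the identity and radius 3 covers 29 offsets", {
  expect_equal(nrow(disc_offsets(3)), 29)
  expect_error(disc_offsets(-1), ">= 0")
  g <- small_geometry()
  cell <- simulate_cell(g, "donor_only", 50000, seed = 1, n_bins = 32L)
  expect_identical(circular_bin(cell$cube, 0), cell$cube)
})

test_that("a single photon spreads to exactly the 29 disc neighbours", {
  counts <- array(0, c(21, 21, 8))
  counts[11, 11, 3] <- 1
  b <- circular_bin(tcspc_cube(counts, 12.5), 3)
  expect_equal(sum(b$counts > 0), 29)
  expect_equal(sum(b$counts), 29)
  expect_equal(b$counts[11, 11, 3], 1)
  expect_equal(b$counts[11, 14, 3], 1)  # offset (0, 3): on the disc edge
  expect_equal(b$counts[13, 13, 3], 1)  # offset (2, 2): dist sqrt(8) < 3
  expect_equal(b$counts[14, 12, 3], 0)  # offset (3, 1): dist sqrt(10) > 3
})

test_that("binning equals convolution with the disc kernel (exact integers)", {
  withr::with_seed(2, {
    counts <- array(rpois(15 * 15 * 4, 3), c(15, 15, 4))
  })
  b <- circular_bin(tcspc_cube(counts, 12.5), 3)
  off <- disc_offsets(3)
  inten <- rowSums(counts, dims = 2)
  binten <- cube_intensity(b)
  # interior pixel: direct 29-term sum
  for (p in list(c(8, 8), c(5, 9))) {
    s <- sum(vapply(seq_len(nrow(off)), function(k) {
      y <- p[1] + off[k, 1]; x <- p[2] + off[k, 2]
      if (y >= 1 && y <= 15 && x >= 1 && x <= 15) inten[y, x] else 0
    }, 0))
    expect_identical(binten[p[1], p[2]], s)
  }
  # uniform cube: interior pixels scale by exactly 29
  u <- array(2, c(15, 15, 2))
  bu <- circular_bin(tcspc_cube(u, 12.5), 3)
  expect_equal(bu$counts[8, 8, 1], 2 * 29)
})

test_that("threshold mask implements the percent-of-maximum window", {
  img <- matrix(0, 10, 10)
  img[1, 1] <- 1000; img[5, 5] <- 150; img[6, 6] <- 149; img[7, 7] <- 500
  m <- intensity_threshold_mask(img, 0.15, 1)
  expect_true(m[5, 5])    # exactly at the 15% cutoff of 150 counts
  expect_false(m[6, 6])
  expect_true(m[1, 1] && m[7, 7])
  # low 0, high 1: every pixel (zeros included by the >= 0 bound)
  expect_true(all(intensity_threshold_mask(img, 0, 1)))
  # constant image: every pixel is at the maximum
  expect_true(all(intensity_threshold_mask(matrix(5, 4, 4), 0.15, 1)))
  expect_warning(z <- intensity_threshold_mask(matrix(0, 3, 3), 0.15, 1),
                 "all-zero")
  expect_false(any(z))
})

test_that("raising the lower threshold never adds pixels", {
  withr::with_seed(5, img <- matrix(rpois(400, 40), 20, 20))
  prev <- intensity_threshold_mask(img, 0, 1)
  for (lo in c(0.1, 0.3, 0.6, 0.9)) {
    cur <- intensity_threshold_mask(img, lo, 1)
    expect_true(all(prev | !cur))  # cur subset of prev
    prev <- cur
  }
})

test_that("pixel-wise fits recover the donor-only lifetime and the FRET geography", {
  g <- cell_geometry(size = 40, cell_axes = c(16, 13), nucleus_axes = c(6, 5),
                     seed = 2)
  cell <- simulate_cell(g, "stx3_vamp3", 300000, seed = 31, n_bins = 128L,
                        acceptor_intensity = 1)
  binned <- circular_bin(cell$cube, 3)
  mask <- intensity_threshold_mask(cube_intensity(binned), 0.15, 1) & g$cell
  lt <- fit_pixelwise(binned, DEFAULT_IRF, mask)
  expect_true(all(is.na(lt[!mask])))
  expect_true(all(lt[!is.na(lt)] > 0))
  # truth ordering: membrane ring fits shorter than interior
  expect_lt(median(lt[g$membrane], na.rm = TRUE),
            median(lt[g$interior], na.rm = TRUE))
  # homogeneous reference: defined pixels center on the truth
  dcell <- simulate_cell(g, "donor_only", 300000, seed = 32, n_bins = 128L)
  dlt <- fit_pixelwise(circular_bin(dcell$cube, 3), DEFAULT_IRF,
                       g$cell & intensity_threshold_mask(
                         cube_intensity(circular_bin(dcell$cube, 3)), 0.15, 1))
  expect_equal(median(dlt, na.rm = TRUE), 2.79, tolerance = 0.05 / 2.79)
  # all-false mask gives an all-undefined map
  empty <- fit_pixelwise(binned, DEFAULT_IRF, matrix(FALSE, 40, 40))
  expect_true(all(is.na(empty)))
})

test_that("FLIM rendering encodes lifetime as hue and intensity as brightness", {
  lt <- matrix(c(2.0, 2.0, 3.0, NA), 2, 2)
  inten <- matrix(c(100, 50, 100, 100), 2, 2)
  img <- render_flim(lt, inten, display_range = c(2, 3))
  expect_equal(dim(img), c(2, 2, 3))
  # same lifetime, graded intensity: same hue, scaled brightness
  expect_equal(img[2, 1, ], img[1, 1, ] / 2, tolerance = 0.01)
  # range endpoints map to opposite hue ramp ends (red vs blue here)
  expect_equal(img[1, 1, ], c(1, 0, 0), tolerance = 0.01)
  expect_gt(img[1, 2, 3], 0.9)
  # undefined pixels are black
  expect_equal(img[2, 2, ], c(0, 0, 0))
  expect_error(render_flim(lt, inten, display_range = c(3, 2)), "increasing")
})
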
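test_that("simulated histograms conserve the photon budget exactly", {
  for (n in c(1, 537, 50000)) {
    h <- simulate_decay_histogram(donor_model(), DEFAULT_IRF, n, seed = 3)
    expect_equal(h$n_photons, n)
  }
})

test_that("pure background simulation is uniform within Poisson error", {
  m <- decay_model(2.5, 0, 1)
  h <- simulate_decay_histogram(m, DEFAULT_IRF, 1e6, n_bins = 250, seed = 4)
  expected <- 1e6 / 250
  stat <- sum((h$counts - expected)^2 / expected)
  expect_gt(pchisq(stat, 249, lower.tail = FALSE), 0.001)
})

test_that("mean arrival time of a wide-period mono decay equals the lifetime", {
  # delta IRF at 0, period 50 ns >> tau: no wrap correction needed
  h <- simulate_decay_histogram(decay_model(2.5, 1), NULL, 200000,
                                period = 50, n_bins = 2000, seed = 5)
  tc <- (h$bin_edges[-1] + h$bin_edges[-2001]) / 2
  mu <- sum(h$counts * tc) / h$n_photons
  expect_lt(abs(mu - 2.5), 3 * 2.5 / sqrt(200000))
})

test_that("identical seeds give bit-identical histograms and cubes", {
  h1 <- simulate_decay_histogram(mixture_model(0.3), DEFAULT_IRF, 5e4,
                                 seed = 99)
  h2 <- simulate_decay_histogram(mixture_model(0.3), DEFAULT_IRF, 5e4,
                                 seed = 99)
  expect_identical(h1$counts, h2$counts)
  g <- small_geometry()
  c1 <- simulate_cell(g, "stx3_vamp3", 60000, seed = 7, n_bins = 64L)
  c2 <- simulate_cell(g, "stx3_vamp3", 60000, seed = 7, n_bins = 64L)
  expect_identical(c1$cube$counts, c2$cube$counts)
  expect_identical(c1$truth, c2$truth)
})

test_that("a short period relative to the lifetime warns about wrap-around", {
  expect_warning(
    simulate_decay_histogram(decay_model(6, 1), NULL, 1000, period = 12.5,
                             n_bins = 50, seed = 1),
    "wrap-around")
})

test_that("condition presets define the expected FRET geography", {
  g <- small_geometry()
  d <- simulate_cell(g, "donor_only", 50000, seed = 2, n_bins = 64L)
  expect_true(all(d$fret_map == 0))
  tan <- simulate_cell(g, "tandem", 50000, seed = 2, n_bins = 64L)
  expect_true(all(tan$fret_map[g$cell] == 1))
  v3 <- simulate_cell(g, "stx3_vamp3", 50000, seed = 2, n_bins = 64L)
  expect_gt(mean(v3$fret_map[g$membrane]), mean(v3$fret_map[g$interior]))
  v8 <- simulate_cell(g, "stx3_vamp8", 50000, seed = 2, n_bins = 64L)
  expect_lt(mean(v8$fret_map[g$membrane]), mean(v8$fret_map[g$interior]))
  expect_error(simulate_cell(g, "no_such_condition", 50000), "unknown")
})

test_that("cell geometry masks nest correctly", {
  g <- cell_geometry(seed = 3)
  expect_true(all(!(g$nucleus & g$cell)))          # nucleus is a hole
  expect_true(all(g$membrane[g$membrane] %in% TRUE))
  expect_true(all((g$membrane | g$interior) == g$cell))
  expect_true(all(!(g$endosomes & g$membrane)))
})

test_that("cohorts are deterministic and acceptor drives FRET positively", {
  cfg <- list(conditions = "stx3_vamp3", donors = 4, cells_per_donor = 6,
              photon_budget = 1000, spatial = FALSE)
  a <- simulate_cohort(cfg, seed = 21)
  b <- simulate_cohort(cfg, seed = 21)
  expect_identical(a$truth, b$truth)
  expect_equal(nrow(a$truth), 24)
  rho <- cor(a$truth$acceptor_intensity, a$truth$fret_fraction,
             method = "spearman")
  expect_gt(rho, 0.99)  # monotone saturating link by construction
})

test_that("donor-only cohorts carry zero FRET truth; empty request is empty", {
  a <- simulate_cohort(list(conditions = "donor_only", donors = 4,
                            cells_per_donor = 10, photon_budget = 1000),
                       seed = 1)
  expect_equal(nrow(a$truth), 40)
  expect_true(all(a$truth$fret_fraction == 0))
  z <- simulate_cohort(list(conditions = "donor_only", donors = 0,
                            cells_per_donor = 0, photon_budget = 1000),
                       seed = 1)
  expect_equal(nrow(z$truth), 0)
  expect_length(z$cells, 0)
})

test_that("the acceptor link saturates toward fmax", {
  f <- acceptor_fret_link(c(0.1, 1, 10, 1000), fmax = 0.8, k_sat = 1)
  expect_true(all(diff(f) > 0))
  expect_lt(f[4], 0.8)
  expect_gt(f[4], 0.79)
})
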
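test_that("histogram percentiles interpolate linearly within bins", {
  # uniform counts over [0, 10) in unit bins: median is 5.0
  h <- tibble::tibble(bin_left = 0:9, count = rep(10, 10))
  expect_equal(hist_percentile(h, 0.5), 5.0)
  expect_equal(hist_percentile(h, 0.25), 2.5)
  # single occupied bin: any q stays inside it
  h1 <- tibble::tibble(bin_left = c(3, 4, 5), count = c(0, 7, 0))
  q <- hist_percentile(h1, 0.37)
  expect_gte(q, 4)
  expect_lte(q, 5)
  expect_error(hist_percentile(h, 0), "inside")
  expect_error(
    hist_percentile(tibble::tibble(bin_left = numeric(), count = numeric()), 0.5),
    "empty"
  )
})

test_that("percentiles of a sampled Gaussian match the quantile oracle", {
  set.seed(11)
  e <- rnorm(2e5, 150, 1.05)
  sp <- plane_spectrum(tibble::tibble(energy = e, weight = 1))
  p1 <- hist_percentile(sp$energy_hist, 0.01)
  expect_equal(p1, 150 + qnorm(0.01) * 1.05, tolerance = 0.001)
  p99 <- hist_percentile(sp$energy_hist, 0.99)
  expect_equal(p99, 150 + qnorm(0.99) * 1.05, tolerance = 0.001)
})

test_that("scatter fraction is the sub-threshold count fraction", {
  # pure Gaussian spectrum: the -3 sigma Normal tail, ~0.00135
  set.seed(12)
  e <- rnorm(4e5, 150, 1.05)
  sp <- plane_spectrum(tibble::tibble(energy = e, weight = 1))
  sf <- scatter_fraction(sp$energy_hist, 150, 1.05)
  expect_equal(sf, pnorm(-3), tolerance = 0.15)
  # all counts below threshold
  low <- plane_spectrum(tibble::tibble(energy = runif(100, 10, 60), weight = 1))
  expect_equal(scatter_fraction(low$energy_hist, 150, 1.05), 1.0)
  expect_error(
    scatter_fraction(tibble::tibble(bin_left = numeric(), count = numeric()), 150, 1),
    "empty"
  )
})

test_that("spectral features summarize one spectrum consistently", {
  set.seed(13)
  e <- c(rnorm(5e4, 150, 1.05), runif(500, 20, 140))
  sp <- plane_spectrum(tibble::tibble(energy = e, weight = 1))
  f <- spectral_features(sp, 150, 1.05)
  expect_equal(f$mean_energy, mean(e), tolerance = 0.005)
  expect_lt(f$p1_energy, f$mean_energy)
  expect_gt(f$scatter_fraction, pnorm(-3))
  expect_gt(f$p99_lett, let_in_water(150))
})

test_that("scatter fraction decreases with offset and grows with blades", {
  # paired-seed sweep at reduced histories
  sims <- lapply(c(0.05, 0.3, 0.8), function(off) {
    cached_sim(150, n = 1.5e4, scenario = "X1", offset = off, seed = 31)
  })
  sfs <- vapply(sims, function(s) {
    scatter_fraction(plane_spectrum(s$crossings)$energy_hist, 150, 1.05)
  }, numeric(1))
  expect_true(all(diff(sfs) < 0))
  # adding the orthogonal blade at equal offset never decreases it
  xy <- cached_sim(150, n = 1.5e4, scenario = "XY_pair", offset = 0.05, seed = 31)
  sf_xy <- scatter_fraction(plane_spectrum(xy$crossings)$energy_hist, 150, 1.05)
  expect_gte(sf_xy, sfs[1] * 0.9)
  # collimated p99 track LET never falls below the uncollimated value
  unc <- cached_sim(150, n = 1.5e4, seed = 31)
  expect_gte(
    hist_percentile(plane_spectrum(sims[[1]]$crossings)$lett_hist, 0.99),
    hist_percentile(plane_spectrum(unc$crossings)$lett_hist, 0.99) - 1e-9
  )
})

test_that("feature_sweep tabulates scenarios with an uncollimated reference", {
  ft <- feature_sweep(
    energies = 150, scenarios = "X1", offsets = c(0.2, 0.6),
    n = 5000, seed = 3
  )
  expect_equal(nrow(ft), 3)
  expect_true("uncollimated" %in% ft$scenario)
  expect_true(all(c("mean_E", "p1_E", "p99_LETt", "scatter_fraction") %in% names(ft)))
  ref <- ft[ft$scenario == "uncollimated", ]
  expect_equal(ref$mean_E, 150, tolerance = 0.01)
})
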
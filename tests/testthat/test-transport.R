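test_that("Highland angle matches the closed form and its scaling laws", {
  w <- material_water()
  expect_equal(highland_theta0(150, 0, 36.08), 0)
  # frozen direct evaluation at 150 MeV through 1 cm of water
  expect_equal(highland_theta0(150, 1, 36.08), 0.0070013, tolerance = 1e-4)
  # doubling the path scales by ~sqrt(2) up to the slow log term
  r <- highland_theta0(150, 2, 36.08) / highland_theta0(150, 1, 36.08)
  expect_equal(r, sqrt(2) * (1 + 0.038 * log(2 / 36.08)) /
    (1 + 0.038 * log(1 / 36.08)), tolerance = 1e-6)
  expect_error(highland_theta0(150, -1, 36.08), "nonnegative")
})

test_that("condensed step reproduces stopping power and Bohr straggling", {
  w <- material_water()
  # eps/l -> S * rho as ds -> 0
  st <- condensed_history_step(150, w, 1e-4)
  expect_equal(st$eps / st$l, mass_stopping_power(w, 150) * w$density,
    tolerance = 1e-3
  )
  # frozen Bohr sigma for 1 mm of water
  expect_equal(bohr_sigma(w, 0.1), 0.093325, tolerance = 1e-5)
  # ranging out inside the step deposits everything
  st2 <- condensed_history_step(1, w, 0.5)
  expect_equal(st2$eps, 1)
  expect_false(st2$alive)
  expect_error(condensed_history_step(150, w, -0.1), "positive")
})

test_that("a single proton without stochastics closes the CSDA exactly", {
  src <- source_model(90, energy_sigma = 1e-9, spot_sigma_x = 1e-6)
  p <- sample_primaries(src, 1, seed = 1)
  cfg <- transport_config(
    nuclear_model = FALSE, straggling = FALSE, scattering = FALSE
  )
  tr <- transport(p, grid = beamlet_grid(), config = cfg)
  expect_equal(sum(tr$maps$sum_dose), 90, tolerance = 1e-9)
  i <- idd(tr)
  stop_depth <- max(i$depth[i$dose > 0])
  expect_equal(stop_depth, csda_range(material_water(), 90),
    tolerance = 0.06
  )
  # entrance voxel LET_t equals the stopping power there
  lt <- lett_map(tr$maps, mask_rel = 0)
  k <- which(!is.na(lt), arr.ind = TRUE)[1, ]
  expect_equal(lt[k[1], k[2], 1],
    let_in_water(90),
    tolerance = 0.01
  )
})

test_that("energy bookkeeping closes and runs are bit-reproducible", {
  sim <- cached_sim(90, n = 4000, seed = 42)
  expect_equal(sim$ledger$closure, 1, tolerance = 1e-6)
  sim2 <- simulate_beamlet(90, n = 4000, seed = 42)
  expect_identical(sim$maps$sum_e, sim2$maps$sum_e)
  expect_identical(sim$maps$sum_e2l, sim2$maps$sum_e2l)
  expect_identical(sim$crossings$energy, sim2$crossings$energy)
  sim3 <- simulate_beamlet(90, n = 4000, seed = 43)
  expect_false(identical(sim$maps$sum_e, sim3$maps$sum_e))
})

test_that("LET_d >= LET_t on every scored voxel (Cauchy-Schwarz)", {
  sim <- cached_sim(90, n = 4000, seed = 42)
  ld <- letd_map(sim$maps)
  lt <- lett_map(sim$maps)
  ok <- !is.na(ld) & !is.na(lt)
  expect_true(any(ok))
  expect_true(all(ld[ok] >= lt[ok] - 1e-9))
})

test_that("Bragg peaks deepen with energy and match the printed anchors", {
  cfg <- transport_config(nuclear_model = FALSE)
  pk <- vapply(c(90, 120), function(e) {
    i <- idd(cached_sim(e, n = 2e4, seed = 5, config = cfg))
    find_bragg_peak(i$depth, i$dose)
  }, numeric(1))
  expect_true(pk[2] > pk[1])
  expect_equal(pk, c(6.4, 10.65), tolerance = 0.004)
})

test_that("nuclear surrogate attenuates primaries and raises entrance LET_d", {
  on <- cached_sim(120, n = 6000, seed = 9)
  off <- cached_sim(120, n = 6000, seed = 9,
    config = transport_config(nuclear_model = FALSE)
  )
  # primary fluence at depth decreases when the model is on
  dose_deep_ratio <- sum(on$maps$sum_dose[, , 95:105]) /
    sum(off$maps$sum_dose[, , 95:105])
  expect_lt(dose_deep_ratio, 0.98)
  letd_on <- letd_map(on$maps)[, , 15]
  letd_off <- letd_map(off$maps)[, , 15]
  expect_gt(
    mean(letd_on, na.rm = TRUE), mean(letd_off, na.rm = TRUE)
  )
})

test_that("a trimmer blade at small offset adds a low-energy tail", {
  unc <- cached_sim(150, n = 2e4, seed = 21)
  col <- cached_sim(150, n = 2e4, scenario = "X1", offset = 0.1, seed = 21)
  thr <- 150 - 3 * 1.05
  tail_unc <- mean(unc$crossings$energy < thr)
  tail_col <- sum(col$crossings$energy < thr) / nrow(col$crossings)
  expect_gt(tail_col, tail_unc * 3)
  expect_true(any(col$crossings$origin == "collimator_scatter"))
  expect_false(any(unc$crossings$origin == "collimator_scatter"))
})
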
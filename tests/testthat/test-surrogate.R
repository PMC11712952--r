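test_that("surrogate depth dose peaks at the model's predicted peak depth", {
  par <- surrogate_params(100)
  z <- seq(0.05, par$range + 0.4, by = 0.002)
  d <- surrogate_depth_dose(par, z)
  # dense grid-search oracle for the argmax
  expect_equal(z[which.max(d)], predicted_peak_depth(100), tolerance = 0.05)
  expect_lt(d[1], max(d)) # entrance below peak
  expect_equal(surrogate_depth_dose(par, par$range + 3.4 * par$bragg_width), 0)
  expect_error(surrogate_depth_dose(par, -1), "nonnegative")
})

test_that("surrogate and MC integral depth dose agree", {
  sim <- cached_sim(90, n = 2e4, seed = 5,
    config = transport_config(nuclear_model = FALSE)
  )
  i <- idd(sim)
  par <- surrogate_params(90)
  # peak depths agree within 1 mm
  expect_equal(
    find_bragg_peak(i$depth, i$dose),
    find_bragg_peak(i$depth, surrogate_depth_dose(par, i$depth)),
    tolerance = 0.1
  )
})

test_that("surrogate LETd hits its anchors and stays laterally flat uncollimated", {
  par <- surrogate_params(150)
  expect_equal(surrogate_letd(par, 0), par$letd_entrance, tolerance = 1e-6)
  expect_equal(surrogate_letd(par, par$range), par$letd_peak, tolerance = 1e-6)
  expect_gt(par$letd_peak, par$letd_entrance)
  # uncollimated: flat within 5% across +-1 sigma
  xs <- seq(-par$spot_sigma0, par$spot_sigma0, length.out = 21)
  lets <- surrogate_letd(par, 5, x = xs)
  expect_lt(diff(range(lets)) / mean(lets), 0.05)
  expect_error(surrogate_letd(par, par$range + 5), "falloff")
})

test_that("collimated surrogate shows the edge ridge and erf penumbra", {
  par <- surrogate_params(150, aperture = list(x = c(-0.5, 0.5), y = NULL))
  # LET ridge at the collimated edge exceeds the center
  expect_gt(
    surrogate_letd(par, 3, x = 0.5),
    surrogate_letd(par, 3, x = 0) * 1.2
  )
  # erf-truncation property: where the fluence is locally flat across
  # the aperture edge, the dose at the projected edge is ~50% of the
  # open-field value (a wide spot makes the fluence flat at the edge)
  par_open <- surrogate_params(150,
    spot_sigma0 = 5, scatter_tail_amplitude = 0
  )
  par_cut <- surrogate_params(150,
    spot_sigma0 = 5,
    aperture = list(x = c(-0.5, 0.5), y = NULL),
    scatter_tail_amplitude = 0
  )
  fx_edge <- surrogate_lateral(par_cut, 0.5, z = 0.2, axis = "x")
  fx_open <- surrogate_lateral(par_open, 0.5, z = 0.2, axis = "x")
  expect_equal(fx_edge / fx_open, 0.5, tolerance = 0.03)
  # with the spot sigma comparable to the aperture, the falling fluence
  # pushes the edge value above half
  fx_edge2 <- surrogate_lateral(
    surrogate_params(150,
      aperture = list(x = c(-0.5, 0.5), y = NULL),
      scatter_tail_amplitude = 0
    ),
    0.5,
    z = 0.2, axis = "x"
  )
  fx_open2 <- surrogate_lateral(
    surrogate_params(150, scatter_tail_amplitude = 0), 0.5,
    z = 0.2, axis = "x"
  )
  expect_gt(fx_edge2 / fx_open2, 0.5)
  expect_lt(fx_edge2 / fx_open2, 0.85)
  # uncollimated axis is a pure Gaussian
  fy <- surrogate_lateral(par, c(-0.3, 0, 0.3), z = 0.2, axis = "y")
  expect_equal(fy[1], fy[3], tolerance = 1e-9)
})

test_that("surrogate score maps round-trip LETd exactly and scale linearly", {
  par <- surrogate_params(90)
  g <- voxel_grid(c(-2, -2, 0), c(0.2, 0.2, 0.2), c(20, 20, 36))
  m <- make_surrogate_scoremaps(par, g)
  ld <- letd_map(m, mask_rel = 1e-6)
  zs <- grid_depths(g)
  xs <- g$origin[1] + (seq_len(g$dims[1]) - 0.5) * g$spacing[1]
  k <- 10
  i <- 11
  expect_equal(
    ld[i, 11, k],
    surrogate_letd(par, zs[k], x = xs[i], y = xs[11]),
    tolerance = 1e-9
  )
  # LET_t is LET_d / 1.05 by construction
  lt <- lett_map(m, mask_rel = 1e-6)
  expect_equal(ld[i, 11, k] / lt[i, 11, k], 1.05, tolerance = 1e-9)
  # dose linearity under amplitude scaling
  m2 <- make_surrogate_scoremaps(par, g, amplitude = 2.5)
  expect_equal(dose_map(m2), 2.5 * dose_map(m), tolerance = 1e-12)
  expect_equal(letd_map(m2), letd_map(m))
})

test_that("LET anchors come from the range-straggling quadrature", {
  an <- surrogate_let_anchors(90)
  expect_gt(an$letd_peak, 4)
  expect_lt(an$letd_peak, 12)
  expect_gt(an$letd_entrance, let_in_water(90))
  expect_lt(an$letd_entrance, 1.5)
  # monotone rise of the LETd profile toward the range
  zz <- c(1, 3, 5, 6, 6.3)
  expect_true(all(diff(an$letd_profile(zz)) > 0))
})

test_that("beamlet libraries round-trip through disk with a manifest", {
  spec <- plan_spec("cube",
    depth_range = c(2, 2.4), lateral_halfwidth = 0.1,
    spot_spacing = 0.25, collimation_strategy = "none"
  )
  lay <- spot_layout(spec)[1:2, ]
  g <- voxel_grid(c(-1, -1, 0), 0.25, c(8, 8, 12))
  dir <- file.path(tempdir(), "lib")
  man <- write_beamlet_library(lay, g, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_mhd(file.path(dir, man$dose_file[1]))
  par <- surrogate_params(lay$energy[1])
  ref <- make_surrogate_scoremaps(par, g, center = c(lay$x[1], lay$y[1]))
  expect_equal(back$map, ref$sum_dose, tolerance = 1e-12)
  expect_equal(back$grid$spacing, g$spacing)
})
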
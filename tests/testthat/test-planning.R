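test_that("spot layout spans the target with the configured spacings", {
  spec <- plan_spec("cube", collimation_strategy = "fixed_field")
  lay <- spot_layout(spec)
  # layer ranges span the depth extent
  expect_lte(max(lay$layer_depth), spec$depth_range[2] + 1e-6)
  expect_gte(max(lay$layer_depth), spec$depth_range[2] - 0.1)
  expect_lte(abs(min(lay$layer_depth) - spec$depth_range[1]), 0.6)
  # adjacent layers differ by the energy spacing
  es <- sort(unique(lay$energy), decreasing = TRUE)
  expect_equal(diff(es), rep(-4, length(es) - 1))
  # spots on the 0.25 cm lattice with one-spot margin
  expect_true(all(abs(lay$x / 0.25 - round(lay$x / 0.25)) < 1e-9))
  expect_lte(max(lay$x), spec$lateral_halfwidth + 2 * 0.25 + 1e-9)
  # fixed_field: every layer shares the target-boundary aperture
  expect_equal(unique(lay$aperture_halfwidth), spec$lateral_halfwidth)
})

test_that("inverted-pyramid apertures expand from the distal layer upward", {
  spec <- plan_spec("pyramid", collimation_strategy = "per_layer_target_width")
  lay <- spot_layout(spec)
  per <- dplyr::distinct(lay[, c("layer", "layer_depth", "aperture_halfwidth")])
  per <- per[order(per$layer_depth, decreasing = TRUE), ]
  # deepest (apex) layer is the tightest; each shallower layer opens up
  expect_true(all(diff(per$aperture_halfwidth) >= -1e-9))
  expect_gt(
    max(per$aperture_halfwidth), min(per$aperture_halfwidth)
  )
  # uncollimated strategy carries no apertures
  lay0 <- spot_layout(plan_spec("pyramid", collimation_strategy = "none"))
  expect_true(all(is.na(lay0$aperture_halfwidth)))
})

test_that("a one-voxel target still yields a layer with spots", {
  spec <- plan_spec("cube",
    depth_range = c(5, 5.1), lateral_halfwidth = 0.05,
    collimation_strategy = "none"
  )
  lay <- spot_layout(spec)
  expect_gte(nrow(lay), 1)
  expect_equal(length(unique(lay$layer)), 1)
})

test_that("optimizer solves identity and duplicated-beamlet cases", {
  # identity influence: one beamlet per target voxel with unit dose
  infl <- diag(6)
  rois <- list(target = rep(TRUE, 6))
  fit <- optimize_weights(infl, rois, prescription = 25, lambda = 0)
  expect_equal(fit$weights, rep(25, 6), tolerance = 1e-3)
  expect_true(fit$converged)
  # duplicated beamlet pair splits the weight evenly
  infl2 <- cbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1))
  fit2 <- optimize_weights(infl2, list(target = rep(TRUE, 3)), 10, lambda = 0)
  expect_equal(fit2$weights[1], fit2$weights[2], tolerance = 1e-6)
  expect_equal(fit2$weights[1] + fit2$weights[2], 10, tolerance = 1e-3)
  expect_true(all(fit2$weights >= 0))
  # infeasible coverage is reported, not silent
  infl3 <- cbind(c(1, 0), c(1, 0))
  expect_warning(
    optimize_weights(infl3, list(target = c(TRUE, TRUE)), 10),
    "no dose"
  )
})

test_that("tidy and glance summarize plan fits", {
  fit <- optimize_weights(diag(3), list(target = rep(TRUE, 3)), 5, lambda = 0)
  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  expect_true(all(c("beamlet", "weight") %in% names(td)))
  g <- glance(fit)
  expect_equal(g$n_beamlets, 3)
  expect_true(g$converged)
})

test_that("composite maps follow the weighted accumulator recombination", {
  par <- surrogate_params(90)
  g <- voxel_grid(c(-1.5, -1.5, 0), 0.25, c(12, 12, 30))
  m1 <- make_surrogate_scoremaps(par, g, center = c(-0.25, 0))
  m2 <- make_surrogate_scoremaps(par, g, center = c(0.25, 0))
  # single beamlet with any weight: composite LETd equals the beamlet's
  c1 <- composite_maps(list(m1), weights = 7)
  expect_equal(c1$letd, letd_map(m1))
  # permuting beamlet order leaves the composite unchanged
  cab <- composite_maps(list(m1, m2), c(2, 3))
  cba <- composite_maps(list(m2, m1), c(3, 2))
  expect_equal(cab$dose, cba$dose)
  expect_equal(cab$letd, cba$letd)
  # equal dose in a voxel: composite LETd is the mean of the two
  mA <- make_surrogate_scoremaps(par, g)
  mB <- mA
  mB$sum_e2l <- mA$sum_e2l * 1.5 # LETd scaled 1.5x, same dose
  cc <- composite_maps(list(mA, mB), c(1, 1))
  la <- letd_map(mA)
  ok <- !is.na(la) & !is.na(cc$letd)
  expect_equal(cc$letd[ok], (la[ok] + 1.5 * la[ok]) / 2, tolerance = 1e-9)
  # convex-hull bound over contributing beamlets
  expect_true(all(cc$letd[ok] >= la[ok] - 1e-9))
  expect_true(all(cc$letd[ok] <= 1.5 * la[ok] + 1e-9))
  expect_error(composite_maps(list(m1), c(-1)), "nonnegative")
})

test_that("separable influence composition matches per-beamlet score maps", {
  spec <- plan_spec("cube",
    depth_range = c(2, 2.6), lateral_halfwidth = 0.3,
    collimation_strategy = "none"
  )
  lay <- spot_layout(spec)
  g <- voxel_grid(c(-1.5, -1.5, 0), 0.125, c(24, 24, 28))
  infl <- plan_influence(lay, g, stride = 1L)
  w <- seq_len(nrow(lay)) / nrow(lay)
  comp <- compose_plan(infl, w)
  # oracle: build every beamlet map explicitly and recombine
  maps <- lapply(seq_len(nrow(lay)), function(i) {
    par <- surrogate_params(lay$energy[i])
    make_surrogate_scoremaps(par, g, center = c(lay$x[i], lay$y[i]))
  })
  ref <- composite_maps(maps, w)
  expect_equal(comp$dose / max(comp$dose), ref$dose / max(ref$dose),
    tolerance = 1e-6
  )
  ok <- !is.na(comp$letd) & !is.na(ref$letd)
  expect_gt(mean(ok), 0.001)
  expect_equal(comp$letd[ok], ref$letd[ok], tolerance = 1e-6)
})

test_that("optimized surrogate plans reach the prescription coverage", {
  # small cube so the optimizer acceptance run stays quick
  spec <- plan_spec("cube",
    depth_range = c(5, 6.5), lateral_halfwidth = 1,
    collimation_strategy = "none"
  )
  lay <- spot_layout(spec)
  g <- voxel_grid(c(-3, -3, 0), 0.25, c(24, 24, 32))
  rois <- make_rois(spec, g)
  infl <- plan_influence(lay, g, stride = 1L)
  fit <- optimize_weights(infl, rois, 25, max_iter = 600)
  comp <- compose_plan(infl, fit$weights)
  d95 <- dvh_value(comp$dose[rois$target], 0.95)
  dose <- comp$dose * 25 / d95
  # normalized target D95 equals the prescription by construction
  expect_equal(dvh_value(dose[rois$target], 0.95), 25, tolerance = 1e-9)
  expect_true(all(fit$weights >= 0))
  # collimated variant achieves the same D95 after its own normalization,
  # with a smaller half-prescription volume
  specc <- plan_spec("cube",
    depth_range = c(5, 6.5), lateral_halfwidth = 1,
    collimation_strategy = "fixed_field"
  )
  inflc <- plan_influence(spot_layout(specc), g, stride = 1L)
  fitc <- optimize_weights(inflc, rois, 25, max_iter = 600)
  compc <- compose_plan(inflc, fitc$weights)
  dosec <- compc$dose * 25 / dvh_value(compc$dose[rois$target], 0.95)
  expect_equal(dvh_value(dosec[rois$target], 0.95), 25, tolerance = 1e-9)
  v50u <- sum(dose >= 12.5, na.rm = TRUE)
  v50c <- sum(dosec >= 12.5, na.rm = TRUE)
  expect_lt(v50c, v50u)
})

test_that("ROI rings are disjoint shells around the target", {
  spec <- plan_spec("cube")
  g <- voxel_grid(c(-6, -6, 0), 0.25, c(48, 48, 48))
  rois <- make_rois(spec, g)
  expect_true(any(rois$target))
  expect_false(any(rois$target & rois$ring5))
  expect_false(any(rois$ring5 & rois$ring10))
  expect_false(any(rois$ring10 & rois$ring20))
  expect_true(all(rois$target | !rois$target & rois$body))
  # ring5 voxels sit within 5 mm of the target surface
  d <- dcslet:::target_distance(spec, g)
  expect_true(all(d[rois$ring5] <= 0.5 + 1e-9))
  expect_true(all(d[rois$ring10] > 0.5 - 1e-9 & d[rois$ring10] <= 1.0 + 1e-9))
})
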
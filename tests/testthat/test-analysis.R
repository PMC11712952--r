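test_that("median filter removes spikes, keeps constants, is idempotent on steps", {
  const <- array(3, c(5, 5, 5))
  expect_equal(median_filter3(const), const)
  spike <- const
  spike[3, 3, 3] <- 100
  expect_equal(median_filter3(spike), const)
  # 1D step edge in a slab is a fixed point (brute-force small-array check)
  step <- array(rep(c(0, 0, 1, 1, 1), each = 1), c(5, 1, 1))
  step <- array(rep(step, 25), c(5, 5, 5))
  once <- median_filter3(step)
  expect_equal(median_filter3(once), once)
  # NA voxels are ignored, not propagated
  na <- const
  na[2, 2, 2] <- NA
  out <- median_filter3(na)
  expect_equal(out[4, 4, 4], 3)
  expect_true(is.na(out[2, 2, 2]) || out[2, 2, 2] == 3)
})

test_that("Gaussian smoothing is normalized and matches direct convolution", {
  const <- array(7, c(5, 5, 5))
  expect_equal(gaussian_smooth3(const), const, tolerance = 1e-12)
  set.seed(4)
  arr <- array(runif(125), c(5, 5, 5))
  # interior-supported map conserves its total (support at least two
  # kernel radii from every face)
  inner <- array(0, c(13, 13, 13))
  inner[6:8, 6:8, 6:8] <- 1
  expect_equal(sum(gaussian_smooth3(inner)), sum(inner), tolerance = 1e-9)
  # matches the brute-force renormalized convolution oracle on 5^3
  expect_equal(gaussian_smooth3(arr, 0.5), oracle_gauss3(arr, 0.5),
    tolerance = 1e-10
  )
})

test_that("find_bragg_peak refines the discrete argmax", {
  z <- seq(0, 10, by = 0.1)
  tri <- pmax(0, 1 - abs(z - 5.2) / 2)
  expect_equal(find_bragg_peak(z, tri), 5.2, tolerance = 1e-9)
  par <- surrogate_params(150)
  z <- seq(0, 17, by = 0.1)
  d <- surrogate_depth_dose(par, z)
  dense <- seq(14, 16.5, by = 1e-4)
  oracle <- dense[which.max(surrogate_depth_dose(par, dense))]
  expect_equal(find_bragg_peak(z, d), oracle, tolerance = 0.05)
  expect_error(find_bragg_peak(z, z), "interior")
})

test_that("planar dose-weighted LETd reduces correctly on degenerate planes", {
  g <- tiny_grid(4)
  d <- array(1, g$dims)
  l <- array(seq_len(64) / 10, g$dims)
  # uniform dose: arithmetic mean of the plane LETd
  expect_equal(
    planar_dose_weighted_letd(d, l, g, g$origin[3] + 0.05),
    mean(l[, , 1])
  )
  # dose concentrated in one voxel: that voxel's LETd
  d2 <- array(0, g$dims)
  d2[2, 3, 1] <- 5
  expect_equal(
    planar_dose_weighted_letd(d2, l, g, g$origin[3] + 0.05),
    l[2, 3, 1]
  )
  # result bounded by the plane's LET range
  set.seed(9)
  d3 <- array(runif(64), g$dims)
  v <- planar_dose_weighted_letd(d3, l, g, g$origin[3] + 0.05)
  expect_gte(v, min(l[, , 1]))
  expect_lte(v, max(l[, , 1]))
  expect_error(
    planar_dose_weighted_letd(array(0, g$dims), l, g, g$origin[3] + 0.05),
    "no dose"
  )
  expect_error(planar_dose_weighted_letd(d, l, g, 99), "outside")
})

test_that("10% penumbra LET interpolates the outermost crossing per side", {
  x <- seq(-3, 3, by = 0.1)
  # rectangular dose profile: crossing at the edge, LET evaluated there
  dose <- ifelse(abs(x) <= 1, 1, 0)
  letd <- 1 + abs(x)
  p <- penumbra_letd_at_10pct(tibble::tibble(position = x, dose = dose, letd = letd))
  expect_equal(sort(abs(p$position)), c(1.0, 1.0), tolerance = 0.11)
  # symmetric Gaussian dose with flat LET: both sides equal
  doseg <- exp(-x^2 / (2 * 0.6^2))
  pg <- penumbra_letd_at_10pct(tibble::tibble(position = x, dose = doseg, letd = rep(2, length(x))))
  expect_equal(pg$letd[1], pg$letd[2])
  expect_equal(pg$letd_mean[1], 2)
  expect_equal(abs(pg$position[1]), abs(pg$position[2]), tolerance = 1e-9)
  # collimated surrogate: edge LET ridge makes penumbra LET > center LET
  par <- surrogate_params(150, aperture = list(x = c(-0.5, 0.5), y = NULL))
  xx <- seq(-2, 2, by = 0.05)
  prof <- tibble::tibble(
    position = xx,
    dose = surrogate_lateral(par, xx, z = 3, axis = "x"),
    letd = surrogate_letd(par, 3, x = xx)
  )
  pc <- penumbra_letd_at_10pct(prof)
  expect_gt(pc$letd_mean[1], surrogate_letd(par, 3, x = 0))
  expect_error(
    penumbra_letd_at_10pct(tibble::tibble(position = x, dose = rep(1, length(x)), letd = letd)),
    "crossing"
  )
})

test_that("volume histograms are monotone and invert to Dxx values", {
  g <- tiny_grid(4)
  roi <- array(TRUE, g$dims)
  d <- array(2, g$dims)
  vh <- volume_histogram(d, roi)
  expect_true(all(diff(vh$volume_fraction) <= 0))
  expect_equal(max(vh$volume_fraction), 1)
  expect_equal(min(vh$volume_fraction), 0)
  # uniform dose: step function at d, D95 = d
  expect_equal(dvh_value(d[roi], 0.95), 2)
  expect_equal(dvh_value(vh, 0.95), 2, tolerance = 0.02)
  set.seed(2)
  vals <- array(runif(64), g$dims)
  expect_lte(dvh_value(vals[roi], 0.95), dvh_value(vals[roi], 0.5))
  expect_lte(dvh_value(vals[roi], 0.5), dvh_value(vals[roi], 0.05))
  # difference histogram of uniform maps: median equals the difference
  diffmap <- array(0.5, g$dims)
  dv <- volume_histogram(diffmap, roi)
  expect_equal(dvh_value(dv, 0.5), 0.5, tolerance = 0.02)
  expect_error(volume_histogram(d, array(FALSE, g$dims)), "empty")
})

test_that("plan metrics normalize to physical D95 and scale-invariantly", {
  g <- voxel_grid(c(-2, -2, 0), 0.25, c(16, 16, 16))
  spec <- plan_spec("cube",
    depth_range = c(1, 3), lateral_halfwidth = 1,
    collimation_strategy = "none"
  )
  rois <- make_rois(spec, g)
  set.seed(5)
  dose <- array(1, g$dims) + 0.1 * array(runif(prod(g$dims)), g$dims)
  dose[rois$target] <- 10 + runif(sum(rois$target))
  letd <- array(2, g$dims)
  rbe_d <- dose * 1.1
  m <- plan_metrics(dose, rbe_d, letd, rois, g)
  expect_equal(m$physical[m$metric == "target_D95"], 1, tolerance = 1e-9)
  m2 <- plan_metrics(dose * 2, rbe_d * 2, letd, rois, g)
  # all normalized metrics are invariant under rescaling the plan
  expect_equal(
    m$physical[m$metric != "V50_cm3"],
    m2$physical[m2$metric != "V50_cm3"],
    tolerance = 1e-9
  )
  expect_equal(
    m$physical[m$metric == "V50_cm3"],
    m2$physical[m2$metric == "V50_cm3"]
  )
  expect_equal(m$physical[m$metric == "target_letd_q75"], 2)
})
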
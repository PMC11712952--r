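test_that("score_step splits segments at voxel faces conservatively", {
  g <- tiny_grid(4)
  m <- score_maps(g)
  # wholly inside one voxel
  m1 <- score_step(m, c(-0.15, -0.15, -0.15), c(-0.15, -0.15, -0.11), eps = 2)
  expect_equal(sum(m1$sum_e), 2)
  expect_equal(sum(m1$sum_l), 0.04)
  expect_equal(sum(m1$sum_e2l), 4 / 0.04)
  # split evenly across two voxels: each gets (eps/2, l/2, eps^2/(2l))
  m2 <- score_step(m, c(-0.05, -0.15, -0.15), c(0.05, -0.15, -0.15), eps = 2)
  got <- m2$sum_e[m2$sum_e > 0]
  expect_equal(got, c(1, 1))
  expect_equal(m2$sum_e2l[m2$sum_e2l > 0], c(1^2 / 0.05, 1^2 / 0.05))
  expect_equal(sum(m2$sum_e), 2) # conservation over sub-steps
  # diagonal segment still conserves energy
  m3 <- score_step(m, c(-0.19, -0.19, -0.19), c(0.19, 0.17, 0.13), eps = 5)
  expect_equal(sum(m3$sum_e), 5, tolerance = 1e-9)
})

test_that("point deposits reach dose but not the LET accumulators", {
  g <- tiny_grid(4)
  m <- score_step(score_maps(g), c(0.05, 0.05, 0.05), c(0, 0, 0),
    eps = 3, l = 0, point = TRUE
  )
  expect_equal(sum(m$sum_dose), 3)
  expect_equal(sum(m$sum_e), 0)
  expect_equal(sum(m$sum_l), 0)
  expect_error(
    score_step(score_maps(g), c(0, 0, 0), c(0, 0, 0), eps = 1, l = 0),
    "point"
  )
})

test_that("LET map conversions follow the accumulator definitions", {
  g <- tiny_grid(2, spacing = 1)
  m <- score_maps(g)
  # steps (eps=1, l=1) and (eps=3, l=1) in one voxel (MeV, cm here):
  # LET_t = 2 MeV/cm = 0.2 keV/um, LET_d = (1+9)/4 = 2.5 MeV/cm
  m$sum_e[1, 1, 1] <- 4
  m$sum_dose[1, 1, 1] <- 4
  m$sum_l[1, 1, 1] <- 2
  m$sum_e2l[1, 1, 1] <- 10
  expect_equal(lett_map(m)[1, 1, 1], 2 * 0.1)
  expect_equal(letd_map(m)[1, 1, 1], 2.5 * 0.1)
  expect_true(is.na(lett_map(m)[2, 2, 2]))
  # uniform steps: LET_d = LET_t
  m2 <- score_maps(g)
  m2$sum_e[1, 1, 1] <- 2
  m2$sum_dose[1, 1, 1] <- 2
  m2$sum_l[1, 1, 1] <- 2
  m2$sum_e2l[1, 1, 1] <- 2
  expect_equal(letd_map(m2)[1, 1, 1], lett_map(m2)[1, 1, 1])
})

test_that("LET_d >= LET_t against a brute-force random-step oracle", {
  set.seed(7)
  g <- tiny_grid(1, spacing = 1)
  for (rep in 1:20) {
    k <- sample(2:40, 1)
    eps <- runif(k, 0.01, 2)
    l <- runif(k, 0.01, 0.5)
    m <- score_maps(g)
    for (i in seq_len(k)) {
      m$sum_e[1] <- m$sum_e[1] + eps[i]
      m$sum_dose[1] <- m$sum_dose[1] + eps[i]
      m$sum_l[1] <- m$sum_l[1] + l[i]
      m$sum_e2l[1] <- m$sum_e2l[1] + eps[i]^2 / l[i]
    }
    o <- oracle_let(eps, l)
    expect_equal(lett_map(m)[1], o$lett * 0.1)
    expect_equal(letd_map(m)[1], o$letd * 0.1)
    expect_gte(o$letd, o$lett - 1e-12)
  }
})

test_that("merging maps equals scoring the union of steps", {
  g <- tiny_grid(4)
  a <- score_step(score_maps(g), c(-0.1, 0, 0), c(0.1, 0, 0), eps = 1)
  b <- score_step(score_maps(g), c(0, -0.1, 0), c(0, 0.1, 0), eps = 2)
  u <- score_step(a, c(0, -0.1, 0), c(0, 0.1, 0), eps = 2)
  m <- merge_score_maps(a, b)
  expect_equal(m$sum_e, u$sum_e)
  expect_equal(m$sum_e2l, u$sum_e2l)
  expect_equal(m$sum_l, u$sum_l)
  expect_error(
    merge_score_maps(a, score_maps(tiny_grid(5))), "match"
  )
})

test_that("LET maps are invariant under uniform weight rescaling", {
  sim <- cached_sim(90, n = 4000, seed = 42)
  m <- sim$maps
  m2 <- m
  m2$sum_e <- m$sum_e * 3
  m2$sum_dose <- m$sum_dose * 3
  m2$sum_l <- m$sum_l * 3
  m2$sum_e2l <- m$sum_e2l * 3
  expect_equal(letd_map(m2), letd_map(m))
  expect_equal(lett_map(m2), lett_map(m))
  # dose is linear
  expect_equal(dose_map(m2), 3 * dose_map(m))
})

test_that("dose map conserves total energy over the grid", {
  sim <- cached_sim(90, n = 4000, seed = 42)
  d <- dose_map(sim$maps, in_gray = FALSE)
  expect_equal(
    sum(d) * prod(sim$maps$grid$spacing) * 1.0,
    sum(sim$maps$sum_dose)
  )
  expect_equal(sum(dose_map(score_maps(tiny_grid(2)))), 0)
})

test_that("plane spectra follow the 0.1-unit binning convention", {
  sp <- plane_spectrum(tibble::tibble(energy = 149.95, weight = 1))
  expect_equal(sp$energy_hist$bin_left, 149.9)
  sp2 <- record_plane_crossing(sp, 149.91)
  expect_equal(sp2$energy_hist$count, 2)
  sp3 <- record_plane_crossing(sp2, 42.0)
  expect_equal(sum(sp3$energy_hist$count), 3)
  # monoenergetic crossings occupy a single energy bin
  mono <- plane_spectrum(tibble::tibble(energy = rep(88.88, 50), weight = 1))
  expect_equal(nrow(mono$energy_hist), 1)
  expect_equal(mono$energy_hist$count, 50)
  expect_error(record_plane_crossing(sp, -1), "positive")
})
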
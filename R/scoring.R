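# Per-voxel accumulators and LET/dose map conversions.
#
# A voxel accumulates, over all scored step segments i inside it,
#   sum_e  = sum eps_i      (MeV)
#   sum_l  = sum l_i        (cm)
#   sum_e2l = sum eps_i^2 / l_i  (MeV^2/cm)
# from which the track-averaged LET is sum_e / sum_l and the
# dose-averaged LET is sum_e2l / sum_e (converted to keV/um).

#' Voxel grid
#'
#' Axis-aligned voxel lattice; voxel `(i, j, k)` (1-based in R) covers the
#' half-open box `[origin + (i-1)*spacing, origin + i*spacing)`.
#'
#' @param origin Length-3 numeric, cm.
#' @param spacing Length-3 numeric (or scalar), cm, positive.
#' @param dims Length-3 integer, voxel counts.
#' @return A `voxel_grid` object.
#' @export
voxel_grid <- function(origin, spacing, dims) {
  spacing <- rep_len(as.numeric(spacing), 3)
  origin <- rep_len(as.numeric(origin), 3)
  dims <- rep_len(as.integer(dims), 3)
  if (any(spacing <= 0)) abort("spacing must be positive")
  if (any(dims < 1)) abort("dims must be >= 1")
  structure(list(origin = origin, spacing = spacing, dims = dims),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf(
    "<voxel_grid> %dx%dx%d voxels, spacing %.3g/%.3g/%.3g cm, origin (%.3g, %.3g, %.3g)\n",
    x$dims[1], x$dims[2], x$dims[3], x$spacing[1], x$spacing[2], x$spacing[3],
    x$origin[1], x$origin[2], x$origin[3]
  ))
  invisible(x)
}

#' Default beamlet scoring grid
#'
#' 10 x 10 cm lateral, 20 cm deep water phantom at 1 mm isotropic
#' resolution, centered on the beam axis with the surface at z = 0.
#'
#' @param spacing Isotropic voxel edge, cm.
#' @return A [voxel_grid()].
#' @export
beamlet_grid <- function(spacing = 0.1) {
  n_lat <- round(10 / spacing)
  n_z <- round(20 / spacing)
  voxel_grid(c(-5, -5, 0), spacing, c(n_lat, n_lat, n_z))
}

#' Depth-slice centers of a grid
#' @param grid A [voxel_grid()].
#' @return Numeric vector of voxel-center z coordinates, cm.
#' @export
grid_depths <- function(grid) {
  grid$origin[3] + (seq_len(grid$dims[3]) - 0.5) * grid$spacing[3]
}

#' Empty score maps on a grid
#'
#' @param grid A [voxel_grid()].
#' @return A `score_maps` object with zeroed accumulator arrays
#'   `sum_e` (MeV, LET-scored track deposits), `sum_l` (cm), `sum_e2l`
#'   (MeV^2/cm), `sum_dose` (MeV, all deposits including point deposits)
#'   and `histories = 0`.
#' @export
score_maps <- function(grid = beamlet_grid()) {
  z <- array(0, dim = grid$dims)
  structure(
    list(
      grid = grid, sum_e = z, sum_l = z, sum_e2l = z, sum_dose = z,
      histories = 0
    ),
    class = "score_maps"
  )
}

#' @export
print.score_maps <- function(x, ...) {
  cat(sprintf(
    "<score_maps> %dx%dx%d, %g histories, total energy %.4g MeV\n",
    x$grid$dims[1], x$grid$dims[2], x$grid$dims[3], x$histories, sum(x$sum_e)
  ))
  invisible(x)
}

#' Merge score maps by accumulator addition
#'
#' Exact: converting the merged maps equals converting a single run over
#' the union of steps.
#'
#' @param a,b `score_maps` on identical grids.
#' @return Merged `score_maps`.
#' @export
merge_score_maps <- function(a, b) {
  check_same_grid(a$grid, b$grid)
  a$sum_e <- a$sum_e + b$sum_e
  a$sum_l <- a$sum_l + b$sum_l
  a$sum_e2l <- a$sum_e2l + b$sum_e2l
  a$sum_dose <- a$sum_dose + b$sum_dose
  a$histories <- a$histories + b$histories
  a
}

check_same_grid <- function(g1, g2) {
  if (!isTRUE(all.equal(g1$origin, g2$origin)) ||
    !isTRUE(all.equal(g1$spacing, g2$spacing)) ||
    !identical(g1$dims, g2$dims)) {
    abort("voxel grids do not match")
  }
  invisible(TRUE)
}

# Split a segment p0 -> p1 at voxel faces; returns data.frame of voxel
# linear indices and sub-lengths. Reference implementation used by the
# R-level scorer and the oracle tests (the MC kernel has its own copy).
segment_voxels <- function(grid, p0, p1) {
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  if (len <= 0) {
    return(data.frame(index = integer(), length = numeric()))
  }
  u <- d / len
  # clip to grid box
  lo <- grid$origin
  hi <- grid$origin + grid$spacing * grid$dims
  t0 <- 0
  t1 <- len
  for (a in 1:3) {
    if (abs(u[a]) < 1e-14) {
      if (p0[a] < lo[a] || p0[a] >= hi[a]) {
        return(data.frame(index = integer(), length = numeric()))
      }
    } else {
      ta <- (lo[a] - p0[a]) / u[a]
      tb <- (hi[a] - p0[a]) / u[a]
      t0 <- max(t0, min(ta, tb))
      t1 <- min(t1, max(ta, tb))
    }
  }
  if (t1 <= t0) {
    return(data.frame(index = integer(), length = numeric()))
  }
  # face crossing parameters inside [t0, t1]
  ts <- c(t0, t1)
  for (a in 1:3) {
    if (abs(u[a]) >= 1e-14) {
      faces <- lo[a] + grid$spacing[a] * (0:grid$dims[a])
      tf <- (faces - p0[a]) / u[a]
      ts <- c(ts, tf[tf > t0 + 1e-12 & tf < t1 - 1e-12])
    }
  }
  ts <- sort(unique(ts))
  mids <- (head(ts, -1) + tail(ts, -1)) / 2
  lens <- diff(ts)
  idx3 <- sapply(1:3, function(a) {
    pmin(pmax(floor((p0[a] + mids * u[a] - lo[a]) / grid$spacing[a]), 0),
      grid$dims[a] - 1
    )
  })
  idx3 <- matrix(idx3, ncol = 3)
  lin <- 1 + idx3[, 1] + grid$dims[1] * (idx3[, 2] + grid$dims[2] * idx3[, 3])
  keep <- lens > 1e-14
  data.frame(index = lin[keep], length = lens[keep])
}

#' Score one step segment into the accumulator maps
#'
#' The segment from `p0` to `p1` is split at voxel faces; the sub-step of
#' length `l_j` in voxel `v` adds `eps_j = eps * l_j / l`, `l_j` and
#' `eps_j^2 / l_j` to that voxel's accumulators. A point deposit
#' (`l = 0`, `point = TRUE`) adds `eps` to `sum_dose` only, since the
#' dose-averaged LET estimator is undefined at zero path length.
#'
#' @param maps A [score_maps()] object.
#' @param p0,p1 Segment end points, cm (length-3).
#' @param eps Energy deposited over the segment, MeV.
#' @param l Step path length, cm (must equal `|p1 - p0|` for scored steps).
#' @param point Logical: point deposit with no track length.
#' @return Updated `score_maps`.
#' @export
score_step <- function(maps, p0, p1, eps, l = sqrt(sum((p1 - p0)^2)),
                       point = FALSE) {
  stopifnot(inherits(maps, "score_maps"))
  if (point || l == 0) {
    if (!point && eps > 0) abort("zero-length step with energy must be scored as a point deposit")
    sv <- segment_voxels(maps$grid, p0, p0 + c(0, 0, 1e-13))
    if (nrow(sv) > 0) {
      maps$sum_dose[sv$index[1]] <- maps$sum_dose[sv$index[1]] + eps
    }
    return(maps)
  }
  if (l < 0) abort("negative path length")
  sv <- segment_voxels(maps$grid, p0, p1)
  if (nrow(sv) == 0) {
    return(maps)
  }
  e_j <- eps * sv$length / l
  for (r in seq_len(nrow(sv))) {
    i <- sv$index[r]
    maps$sum_e[i] <- maps$sum_e[i] + e_j[r]
    maps$sum_dose[i] <- maps$sum_dose[i] + e_j[r]
    maps$sum_l[i] <- maps$sum_l[i] + sv$length[r]
    maps$sum_e2l[i] <- maps$sum_e2l[i] + e_j[r]^2 / sv$length[r]
  }
  maps
}

default_let_mask <- function(maps, mask_rel = 1e-4) {
  dmax <- max(maps$sum_dose)
  if (dmax <= 0) {
    return(array(FALSE, dim = maps$grid$dims))
  }
  maps$sum_dose > mask_rel * dmax
}

#' Track-averaged LET map
#'
#' `sum_e / sum_l` per voxel, in keV/um. Voxels with no track length, or
#' with dose below `mask_rel` of the map maximum (statistical noise
#' floor), are masked as `NA`.
#'
#' @param maps A [score_maps()].
#' @param mask_rel Relative dose threshold for reporting a voxel's LET.
#' @return 3D array, keV/um, `NA` where masked.
#' @export
lett_map <- function(maps, mask_rel = 1e-4) {
  ok <- maps$sum_l > 0 & default_let_mask(maps, mask_rel)
  out <- array(NA_real_, dim = maps$grid$dims)
  out[ok] <- maps$sum_e[ok] / maps$sum_l[ok] * MEV_PER_CM_TO_KEV_PER_UM
  out
}

#' Dose-averaged LET map
#'
#' `sum_e2l / sum_e` per voxel, in keV/um, masked like [lett_map()].
#'
#' @inheritParams lett_map
#' @return 3D array, keV/um, `NA` where masked.
#' @export
letd_map <- function(maps, mask_rel = 1e-4) {
  ok <- maps$sum_e > 0 & maps$sum_l > 0 & default_let_mask(maps, mask_rel)
  out <- array(NA_real_, dim = maps$grid$dims)
  out[ok] <- maps$sum_e2l[ok] / maps$sum_e[ok] * MEV_PER_CM_TO_KEV_PER_UM
  out
}

#' Dose map
#'
#' `sum_dose / (rho * voxel volume)` per voxel (all deposits, including
#' point deposits that are excluded from the LET accumulators). With
#' `in_gray = TRUE` the MeV/g values are converted to Gy (per simulated
#' batch, not per MU).
#'
#' @param maps A [score_maps()].
#' @param density Medium density, g/cm^3.
#' @param in_gray Convert MeV/g to Gy.
#' @param per_history Divide by the number of histories.
#' @return 3D array of dose values.
#' @export
dose_map <- function(maps, density = 1.0, in_gray = TRUE, per_history = FALSE) {
  vol <- prod(maps$grid$spacing)
  d <- maps$sum_dose / (density * vol)
  if (in_gray) d <- d * MEV_PER_G_TO_GY
  if (per_history && maps$histories > 0) d <- d / maps$histories
  d
}

#' @export
as_tibble.score_maps <- function(x, ...) {
  g <- x$grid
  idx <- which(x$sum_e > 0 | x$sum_l > 0)
  if (length(idx) == 0) {
    return(tibble(
      x = numeric(), y = numeric(), z = numeric(),
      sum_e = numeric(), sum_l = numeric(), sum_e2l = numeric()
    ))
  }
  a <- arrayInd(idx, g$dims)
  tibble(
    x = g$origin[1] + (a[, 1] - 0.5) * g$spacing[1],
    y = g$origin[2] + (a[, 2] - 0.5) * g$spacing[2],
    z = g$origin[3] + (a[, 3] - 0.5) * g$spacing[3],
    sum_e = x$sum_e[idx], sum_l = x$sum_l[idx], sum_e2l = x$sum_e2l[idx]
  )
}

# ---- planar spectra -------------------------------------------------------

#' Plane-crossing spectra
#'
#' Kinetic-energy and track-LET histograms of particles crossing a tally
#' plane, on fixed 0.1 MeV and 0.1 keV/um bins. Counts are weight sums.
#'
#' @param crossings Tibble with columns `energy` and `weight` (as returned
#'   by [transport()]), or `NULL` for an empty spectrum.
#' @param z_plane Plane position, cm.
#' @param energy_bin,lett_bin Bin widths (0.1 by convention).
#' @return A `plane_spectrum` object with `energy_hist` and `lett_hist`
#'   tibbles (`bin_left`, `count`).
#' @export
plane_spectrum <- function(crossings = NULL, z_plane = 0,
                           energy_bin = 0.1, lett_bin = 0.1) {
  sp <- structure(
    list(
      z_plane = z_plane, energy_bin = energy_bin, lett_bin = lett_bin,
      energy_hist = tibble(bin_left = numeric(), count = numeric()),
      lett_hist = tibble(bin_left = numeric(), count = numeric())
    ),
    class = "plane_spectrum"
  )
  if (!is.null(crossings) && nrow(crossings) > 0) {
    w <- if ("weight" %in% names(crossings)) crossings$weight else rep(1, nrow(crossings))
    sp$energy_hist <- bin_weighted(crossings$energy, w, energy_bin)
    sp$lett_hist <- bin_weighted(let_in_water(pmax(crossings$energy, 0.5)), w, lett_bin)
  }
  sp
}

bin_weighted <- function(x, w, width) {
  left <- floor(x / width) * width
  agg <- tapply(w, left, sum)
  tibble(bin_left = as.numeric(names(agg)), count = as.numeric(agg)) |>
    dplyr::arrange(.data$bin_left)
}

#' Record one plane crossing into a spectrum
#'
#' Increments the energy bin `[floor(E/w)*w, ...)` and the corresponding
#' track-LET bin (LET of a proton of energy `E` in water).
#'
#' @param spectrum A [plane_spectrum()].
#' @param energy Kinetic energy, MeV (> 0).
#' @param weight Statistical weight.
#' @return Updated `plane_spectrum`.
#' @export
record_plane_crossing <- function(spectrum, energy, weight = 1) {
  if (energy <= 0) abort("crossing energy must be positive")
  add_one <- function(hist, value, width) {
    left <- floor(value / width) * width
    i <- which(abs(hist$bin_left - left) < width * 1e-9)
    if (length(i) == 1) {
      hist$count[i] <- hist$count[i] + weight
    } else {
      hist <- dplyr::arrange(
        dplyr::bind_rows(hist, tibble(bin_left = left, count = weight)),
        .data$bin_left
      )
    }
    hist
  }
  spectrum$energy_hist <- add_one(spectrum$energy_hist, energy, spectrum$energy_bin)
  spectrum$lett_hist <- add_one(
    spectrum$lett_hist, let_in_water(max(energy, 0.5)), spectrum$lett_bin
  )
  spectrum
}

#' @export
print.plane_spectrum <- function(x, ...) {
  cat(sprintf(
    "<plane_spectrum> z = %.3g cm, %.6g weighted crossings\n",
    x$z_plane, sum(x$energy_hist$count)
  ))
  invisible(x)
}

#' @rdname autoplot-dcslet
#' @export
autoplot.plane_spectrum <- function(object, ...) {
  d <- dplyr::bind_rows(
    dplyr::mutate(object$energy_hist, panel = "kinetic energy (MeV)"),
    dplyr::mutate(object$lett_hist, panel = "track LET (keV/μm)")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_left, y = .data$count)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "weighted counts")
}
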
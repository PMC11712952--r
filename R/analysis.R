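# Map post-processing and plan/beamlet analysis: filters, Bragg-peak
# finding, planar dose-weighted LET, penumbra LET, volume histograms and
# plan metrics.

#' One-voxel-span median filter
#'
#' 3x3x3 median per voxel with shrunken neighborhoods at the edges; `NA`
#' voxels are ignored within a neighborhood.
#'
#' @param map 3D array.
#' @return Filtered array of the same shape.
#' @export
median_filter3 <- function(map) {
  stopifnot(length(dim(map)) == 3)
  out <- cpp_median_filter3(as.numeric(map), as.integer(dim(map)))
  array(out, dim = dim(map))
}

gauss_kernel <- function(sigma) {
  if (sigma <= 0) {
    return(1)
  }
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

smooth_along <- function(arr, kernel, axis) {
  if (length(kernel) == 1) {
    return(arr)
  }
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  r <- (length(kernel) - 1) / 2
  # banded convolution matrix with renormalized edge rows (kernel mass
  # falling outside the array is redistributed)
  n <- da[1]
  cm <- matrix(0, n, n)
  for (j in seq_along(kernel)) {
    off <- j - r - 1
    idx <- seq_len(n)
    src <- idx + off
    okk <- src >= 1 & src <= n
    cm[cbind(idx[okk], src[okk])] <- cm[cbind(idx[okk], src[okk])] + kernel[j]
  }
  cm <- cm / rowSums(cm)
  sm <- cm %*% m
  out <- array(sm, dim = da)
  aperm(out, order(perm))
}

#' Separable Gaussian smoothing
#'
#' Gaussian kernel truncated at 4 sigma and renormalized (edge rows are
#' renormalized as well, so a constant map is exactly preserved).
#'
#' `NA` (masked) voxels are handled by normalized convolution: they do
#' not contaminate their neighbors and stay `NA` themselves.
#'
#' @param map 3D array.
#' @param sigma Kernel standard deviation in voxels (default 0.5).
#' @return Smoothed array.
#' @export
gaussian_smooth3 <- function(map, sigma = 0.5) {
  stopifnot(length(dim(map)) == 3)
  k <- gauss_kernel(sigma)
  run <- function(a) {
    s <- smooth_along(a, k, 1)
    s <- smooth_along(s, k, 2)
    smooth_along(s, k, 3)
  }
  na <- is.na(map)
  if (!any(na)) {
    return(run(map))
  }
  filled <- map
  filled[na] <- 0
  wt <- array(1, dim(map))
  wt[na] <- 0
  num <- run(filled)
  den <- run(wt)
  out <- num / pmax(den, 1e-12)
  out[na] <- NA_real_
  dim(out) <- dim(map)
  out
}

#' Bragg-peak depth of a depth-dose curve
#'
#' Discrete argmax refined by a parabola through the three surrounding
#' samples. A curve whose maximum sits on the boundary (monotone curve)
#' is an error.
#'
#' @param depth Depth coordinates, cm (ascending).
#' @param dose Dose values.
#' @return Refined peak depth, cm.
#' @export
find_bragg_peak <- function(depth, dose) {
  stopifnot(length(depth) == length(dose))
  i <- which.max(dose)
  if (i == 1 || i == length(dose)) abort("depth-dose curve has no interior maximum")
  y0 <- dose[i - 1]
  y1 <- dose[i]
  y2 <- dose[i + 1]
  denom <- y0 - 2 * y1 + y2
  delta <- if (abs(denom) < 1e-300) 0 else 0.5 * (y0 - y2) / denom
  delta <- max(min(delta, 0.5), -0.5)
  h <- depth[i + 1] - depth[i]
  depth[i] + delta * h
}

nearest_slice <- function(grid, z) {
  k <- round((z - grid$origin[3]) / grid$spacing[3] + 0.5)
  if (k < 1 || k > grid$dims[3]) abort("plane outside grid")
  as.integer(k)
}

#' Planar dose-weighted dose-averaged LET
#'
#' `sum(LETd * D) / sum(D)` over the unmasked voxels of the depth plane
#' nearest `z`.
#'
#' @param dose_map,letd_map Congruent 3D arrays.
#' @param grid The [voxel_grid()] of the maps.
#' @param z Depth of the plane, cm.
#' @return Dose-weighted LETd, keV/um.
#' @export
planar_dose_weighted_letd <- function(dose_map, letd_map, grid, z) {
  k <- nearest_slice(grid, z)
  d <- dose_map[, , k]
  l <- letd_map[, , k]
  ok <- !is.na(l) & !is.na(d) & d > 0
  if (!any(ok)) abort("plane has no dose")
  sum(l[ok] * d[ok]) / sum(d[ok])
}

#' Lateral profile through the beamlet centroid
#'
#' Extracts dose and LETd along one lateral axis at depth `z`, through the
#' dose-weighted centroid of the plane.
#'
#' @param dose_map,letd_map Congruent 3D arrays.
#' @param grid Their [voxel_grid()].
#' @param z Depth, cm.
#' @param axis `"x"` or `"y"`.
#' @return Tibble with `position` (cm), `dose`, `letd`.
#' @export
lateral_profile <- function(dose_map, letd_map, grid, z, axis = c("x", "y")) {
  axis <- match.arg(axis)
  k <- nearest_slice(grid, z)
  d <- dose_map[, , k]
  xs <- grid$origin[1] + (seq_len(grid$dims[1]) - 0.5) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(grid$dims[2]) - 0.5) * grid$spacing[2]
  tot <- sum(d)
  cx <- if (tot > 0) sum(rowSums(d) * xs) / tot else 0
  cy <- if (tot > 0) sum(colSums(d) * ys) / tot else 0
  if (axis == "x") {
    j <- which.min(abs(ys - cy))
    tibble(position = xs, dose = d[, j], letd = letd_map[, j, k])
  } else {
    i <- which.min(abs(xs - cx))
    tibble(position = ys, dose = d[i, ], letd = letd_map[i, , k])
  }
}

interp_at <- function(x, y, x0) {
  approx(x, y, xout = x0, rule = 2)$y
}

#' LET at the 10%-of-peak lateral penumbra
#'
#' Finds, on each side of the profile peak, the outermost position where
#' the dose falls to 10% of the profile maximum (linear interpolation) and
#' interpolates the LETd there.
#'
#' @param profile Tibble from [lateral_profile()] (`position`, `dose`,
#'   `letd`).
#' @return Tibble with one row per side: `side`, `position`, `letd`, and
#'   the mean in attribute-free column `letd_mean` repeated.
#' @export
penumbra_letd_at_10pct <- function(profile) {
  d <- profile$dose
  x <- profile$position
  l <- profile$letd
  pk <- max(d, na.rm = TRUE)
  if (!is.finite(pk) || pk <= 0) abort("profile has no peak")
  thr <- 0.1 * pk
  ipk <- which.max(d)
  find_side <- function(idx) {
    # outermost crossing: scan from the outside toward the peak
    below <- d[idx] < thr
    cross <- which(diff(below) != 0)
    if (length(cross) == 0) abort("no 10% crossing inside the grid")
    j <- cross[1] # first transition moving inward from the boundary
    i1 <- idx[j]
    i2 <- idx[j + 1]
    f <- (thr - d[i1]) / (d[i2] - d[i1])
    pos <- x[i1] + f * (x[i2] - x[i1])
    lv <- l[i1] + f * (l[i2] - l[i1])
    if (is.na(lv)) {
      lv <- if (!is.na(l[i2])) l[i2] else l[i1]
    }
    c(pos, lv)
  }
  left <- find_side(seq(1, ipk))
  right <- find_side(seq(length(d), ipk))
  res <- tibble(
    side = c("left", "right"),
    position = c(left[1], right[1]),
    letd = c(left[2], right[2])
  )
  res$letd_mean <- mean(res$letd)
  res
}

#' Cumulative volume histogram
#'
#' Volume fraction of the ROI at or above each threshold. For
#' `kind = "difference"` supply the difference map directly (convention:
#' RBE-weighted minus physical).
#'
#' @param map 3D array (dose, LETd, or a difference map).
#' @param roi Logical array of the same shape (nonempty).
#' @param edges Optional threshold vector; defaults to 256 levels spanning
#'   the ROI values.
#' @return A `vh_curve` tibble: `threshold`, `volume_fraction`
#'   (monotone nonincreasing from 1 to 0).
#' @export
volume_histogram <- function(map, roi, edges = NULL) {
  if (!any(roi)) abort("empty ROI")
  v <- map[roi]
  v <- v[!is.na(v)]
  if (length(v) == 0) abort("ROI has no defined values")
  if (is.null(edges)) {
    lo <- min(0, min(v))
    hi <- max(v) * 1.001 + 1e-12
    edges <- seq(lo, hi, length.out = 256)
  }
  frac <- vapply(edges, function(t) mean(v >= t), numeric(1))
  out <- tibble(threshold = edges, volume_fraction = frac)
  class(out) <- c("vh_curve", class(out))
  out
}

#' Dose at a given volume fraction (DVH inverse)
#'
#' `dvh_value(values, 0.95)` is D95: the largest threshold received by at
#' least that fraction of the ROI volume.
#'
#' @param values Numeric vector of ROI voxel values (or a `vh_curve`).
#' @param volume_fraction Fraction in (0, 1].
#' @return Threshold value.
#' @export
dvh_value <- function(values, volume_fraction) {
  if (inherits(values, "vh_curve")) {
    ok <- values$volume_fraction >= volume_fraction
    if (!any(ok)) {
      return(min(values$threshold))
    }
    return(max(values$threshold[ok]))
  }
  v <- values[!is.na(values)]
  quantile(v, probs = 1 - volume_fraction, names = FALSE, type = 7)
}

#' @rdname autoplot-dcslet
#' @export
autoplot.vh_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$threshold, .data$volume_fraction)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::labs(x = "threshold", y = "volume fraction ≥ threshold")
}

#' Plan metric table
#'
#' Target D95, normal-tissue ring median doses (5/10/20 mm), body mean,
#' skin max, half-prescription volume and the target LETd upper quartile;
#' physical and RBE-weighted doses are both reported, normalized to the
#' physical target D95.
#'
#' @param dose_map Physical dose array (Gy).
#' @param rbe_dose_map RBE-weighted dose array (Gy(RBE)).
#' @param letd_map Dose-averaged LET array (keV/um).
#' @param rois List of logical masks: `target`, `ring5`, `ring10`,
#'   `ring20`, `skin`, `body`.
#' @param grid The plan [voxel_grid()].
#' @return Tibble with columns `metric`, `physical`, `rbe_weighted`.
#' @export
plan_metrics <- function(dose_map, rbe_dose_map, letd_map, rois, grid) {
  d95 <- dvh_value(dose_map[rois$target], 0.95)
  if (d95 <= 0) abort("target has no dose")
  dn <- dose_map / d95
  rn <- rbe_dose_map / d95
  voxvol <- prod(grid$spacing)
  ring_med <- function(mask) {
    if (is.null(mask) || !any(mask)) {
      return(c(NA_real_, NA_real_))
    }
    c(median(dn[mask], na.rm = TRUE), median(rn[mask], na.rm = TRUE))
  }
  r5 <- ring_med(rois$ring5)
  r10 <- ring_med(rois$ring10)
  r20 <- ring_med(rois$ring20)
  v50_phys <- sum(dn >= 0.5, na.rm = TRUE) * voxvol
  v50_rbe <- sum(rn >= 0.5, na.rm = TRUE) * voxvol
  letd_q3 <- quantile(letd_map[rois$target], 0.75, na.rm = TRUE, names = FALSE)
  tibble(
    metric = c(
      "target_D95", "ring5_median", "ring10_median", "ring20_median",
      "body_mean", "skin_max", "V50_cm3", "target_letd_q75"
    ),
    physical = c(
      dvh_value(dn[rois$target], 0.95), r5[1], r10[1], r20[1],
      mean(dn[rois$body], na.rm = TRUE), max(dn[rois$skin], na.rm = TRUE),
      v50_phys, letd_q3
    ),
    rbe_weighted = c(
      dvh_value(rn[rois$target], 0.95), r5[2], r10[2], r20[2],
      mean(rn[rois$body], na.rm = TRUE), max(rn[rois$skin], na.rm = TRUE),
      v50_rbe, NA_real_
    )
  )
}
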
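# Spot/energy-layer layout, collimation strategies, nonnegative weight
# optimization to a uniform prescription, and weighted composite
# recombination of dose and LETd.
#
# For lattice spot layouts the surrogate beamlet maps are separable in
# (x, y, z), so per-layer composition reduces to small matrix products
# Fx %*% W %*% t(Fy) per depth slice; this is exact for the surrogate
# model and avoids storing thousands of full voxel maps.

#' Plan specification
#'
#' @param target `"cube"` (rectangular prism, 4 cm deep x 5 x 5 cm) or
#'   `"pyramid"` (inverted pyramid: 5 x 5 cm base at the shallow face,
#'   small square apex at the deep end, so per-layer apertures expand
#'   from the most distal layer upward).
#' @param prescription Target dose, Gy.
#' @param energy_spacing Energy-layer spacing, MeV.
#' @param spot_spacing Lateral spot spacing, cm.
#' @param collimation_strategy `"none"`, `"fixed_field"` (aperture fixed
#'   at the target lateral boundary for every layer) or
#'   `"per_layer_target_width"` (aperture tracks each layer's target
#'   cross-section).
#' @param depth_range Target depth extent `c(z_shallow, z_deep)`, cm.
#' @param lateral_halfwidth Target lateral half-width at the deep face, cm.
#' @param apex_halfwidth Pyramid face half-width at the shallow end, cm.
#' @return A `plan_spec` object.
#' @export
plan_spec <- function(target = c("cube", "pyramid"), prescription = 25,
                      energy_spacing = 4, spot_spacing = 0.25,
                      collimation_strategy = c("none", "fixed_field",
                        "per_layer_target_width"),
                      depth_range = c(2.5, 6.5), lateral_halfwidth = 2.5,
                      apex_halfwidth = 0.25) {
  target <- match.arg(target)
  collimation_strategy <- match.arg(collimation_strategy)
  if (prescription <= 0) abort("prescription must be positive")
  if (energy_spacing <= 0 || spot_spacing <= 0) abort("spacings must be positive")
  structure(
    list(
      target = target, prescription = prescription,
      energy_spacing = energy_spacing, spot_spacing = spot_spacing,
      collimation_strategy = collimation_strategy,
      depth_range = depth_range, lateral_halfwidth = lateral_halfwidth,
      apex_halfwidth = apex_halfwidth
    ),
    class = "plan_spec"
  )
}

#' Default planning grid
#'
#' 12 x 12 cm lateral, 8 cm deep at 1.25 mm isotropic spacing (the spot
#' lattice then falls on whole voxel multiples).
#'
#' @return A [voxel_grid()].
#' @export
plan_grid <- function() {
  voxel_grid(c(-6, -6, 0), 0.125, c(96, 96, 64))
}

# target lateral half-width at depth z; the pyramid is inverted (5 x 5 cm
# base at the shallow face, small apex at the deep end), so the
# collimating aperture expands from the most distal energy layer upward
target_halfwidth_at <- function(spec, z) {
  zr <- spec$depth_range
  if (spec$target == "cube") {
    w <- rep(spec$lateral_halfwidth, length(z))
  } else {
    f <- (zr[2] - z) / (zr[2] - zr[1])
    w <- spec$apex_halfwidth +
      (spec$lateral_halfwidth - spec$apex_halfwidth) * pmin(pmax(f, 0), 1)
  }
  w[z < zr[1] | z > zr[2]] <- NA_real_
  w
}

#' Target mask on a grid
#'
#' @param spec A [plan_spec()].
#' @param grid A [voxel_grid()].
#' @return Logical 3D array.
#' @export
target_mask <- function(spec, grid) {
  xs <- grid$origin[1] + (seq_len(grid$dims[1]) - 0.5) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(grid$dims[2]) - 0.5) * grid$spacing[2]
  zs <- grid_depths(grid)
  out <- array(FALSE, grid$dims)
  for (k in seq_along(zs)) {
    w <- target_halfwidth_at(spec, zs[k])
    if (is.na(w)) next
    out[, , k] <- outer(abs(xs) <= w, abs(ys) <= w, `&`)
  }
  out
}

# distance from every voxel center to the target (union of per-slice
# axis-aligned boxes; exact for box targets, slice-resolution for the
# pyramid)
target_distance <- function(spec, grid) {
  xs <- grid$origin[1] + (seq_len(grid$dims[1]) - 0.5) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(grid$dims[2]) - 0.5) * grid$spacing[2]
  zs <- grid_depths(grid)
  wz <- target_halfwidth_at(spec, zs)
  tk <- which(!is.na(wz))
  dist <- array(Inf, grid$dims)
  dx2 <- function(v, w) pmax(abs(v) - w, 0)^2
  for (k in seq_along(zs)) {
    best <- NULL
    for (kk in tk) {
      dz <- abs(zs[k] - zs[kk])
      # skip target slices that cannot improve the lateral-only bound
      dxy <- outer(dx2(xs, wz[kk]), dx2(ys, wz[kk]), `+`)
      cand <- dxy + dz^2
      best <- if (is.null(best)) cand else pmin(best, cand)
    }
    dist[, , k] <- sqrt(best)
  }
  dist
}

#' Regions of interest for plan analysis
#'
#' Target, disjoint normal-tissue shells at 5/10/20 mm expansions, skin
#' (first 5 mm of phantom depth) and body (whole phantom).
#'
#' @param spec A [plan_spec()].
#' @param grid A [voxel_grid()].
#' @return Named list of logical arrays: `target`, `ring5`, `ring10`,
#'   `ring20`, `skin`, `body`.
#' @export
make_rois <- function(spec, grid) {
  tm <- target_mask(spec, grid)
  d <- target_distance(spec, grid)
  zs <- grid_depths(grid)
  skin <- array(FALSE, grid$dims)
  skin[, , zs <= 0.5] <- TRUE
  list(
    target = tm,
    ring5 = !tm & d <= 0.5,
    ring10 = !tm & d > 0.5 & d <= 1.0,
    ring20 = !tm & d > 1.0 & d <= 2.0,
    skin = skin & !tm,
    body = array(TRUE, grid$dims)
  )
}

#' Spot and energy-layer layout
#'
#' Energy layers are chosen so their ranges span the target depth extent
#' at the configured energy spacing (deepest layer at the distal face,
#' proximal margin of half an energy step). Per layer, spots sit on a
#' square lattice at the spot spacing covering the layer's lateral target
#' cross-section plus one spot margin. Collimation follows the strategy:
#' fixed at the target boundary, per-layer target width, or absent.
#'
#' @param spec A [plan_spec()].
#' @param material Water (for range/energy conversion).
#' @return Tibble with one row per beamlet: `beamlet`, `layer`, `energy`,
#'   `layer_depth`, `x`, `y`, `aperture_halfwidth` (NA if uncollimated).
#' @export
spot_layout <- function(spec, material = material_water()) {
  zr <- spec$depth_range
  e_deep <- energy_at_range(material, zr[2])
  energies <- e_deep
  repeat {
    e_next <- energies[length(energies)] - spec$energy_spacing
    if (e_next <= 1) break
    r_next <- csda_range(material, e_next)
    r_cur <- csda_range(material, energies[length(energies)])
    if (r_next < zr[1] - (r_cur - r_next) / 2) break
    energies <- c(energies, e_next)
  }
  layers <- purrr::imap_dfr(energies, function(e, i) {
    depth <- csda_range(material, e)
    w <- target_halfwidth_at(spec, min(max(depth, zr[1]), zr[2]))
    n_half <- ceiling((w + spec$spot_spacing) / spec$spot_spacing)
    pos <- seq(-n_half, n_half) * spec$spot_spacing
    ap <- switch(spec$collimation_strategy,
      none = NA_real_,
      fixed_field = spec$lateral_halfwidth,
      per_layer_target_width = w
    )
    tidyr::expand_grid(x = pos, y = pos) |>
      dplyr::mutate(
        layer = i, energy = e, layer_depth = depth,
        aperture_halfwidth = ap
      )
  })
  layers$beamlet <- seq_len(nrow(layers))
  layers[, c("beamlet", "layer", "energy", "layer_depth", "x", "y",
             "aperture_halfwidth")]
}

# per-layer separable operators on a grid (optionally strided for the
# optimization voxels)
build_layer_ops <- function(layout, grid, stride = 1L,
                            surrogate_args = list()) {
  xs <- grid$origin[1] + (seq_len(grid$dims[1]) - 0.5) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(grid$dims[2]) - 0.5) * grid$spacing[2]
  zs <- grid_depths(grid)
  ix <- seq(1, length(xs), by = stride)
  iz <- seq(1, length(zs), by = stride)
  layers <- split(layout, layout$layer)
  ops <- lapply(layers, function(ly) {
    e <- ly$energy[1]
    ap_hw <- ly$aperture_halfwidth[1]
    aperture <- if (is.na(ap_hw)) {
      NULL
    } else {
      list(x = c(-ap_hw, ap_hw), y = c(-ap_hw, ap_hw))
    }
    par <- do.call(
      surrogate_params,
      c(list(energy = e, aperture = aperture), surrogate_args)
    )
    sx <- sort(unique(ly$x))
    sy <- sort(unique(ly$y))
    widx <- matrix(NA_integer_, length(sx), length(sy))
    widx[cbind(match(ly$x, sx), match(ly$y, sy))] <- ly$beamlet
    dd <- surrogate_depth_dose(par, zs)
    ld <- par$.let_depth(zs)
    fx <- lapply(zs, function(z) {
      outer(xs, sx, function(x, c0) surrogate_lateral(par, x, z, "x", c0))
    })
    fy <- lapply(zs, function(z) {
      outer(ys, sy, function(y, c0) surrogate_lateral(par, y, z, "y", c0))
    })
    list(
      params = par, sx = sx, sy = sy, widx = widx,
      dd = dd, ld = ld, fx = fx, fy = fy,
      bx = surrogate_edge_boost(par, xs, "x"),
      by = surrogate_edge_boost(par, ys, "y"),
      ix = ix, iz = iz
    )
  })
  structure(
    list(layers = ops, grid = grid, stride = stride, layout = layout),
    class = "plan_influence"
  )
}

#' Separable surrogate influence operator for a plan layout
#'
#' @param layout A [spot_layout()] tibble.
#' @param grid Composite [voxel_grid()] (default [plan_grid()]).
#' @param stride Voxel stride used for the optimization sub-grid.
#' @param surrogate_args Extra arguments passed to [surrogate_params()].
#' @return A `plan_influence` object.
#' @export
plan_influence <- function(layout, grid = plan_grid(), stride = 2L,
                           surrogate_args = list()) {
  build_layer_ops(layout, grid, stride, surrogate_args)
}

# forward dose on the (possibly strided) grid; weights indexed by beamlet
influence_forward <- function(influence, weights, strided = TRUE) {
  g <- influence$grid
  ix <- if (strided) influence$layers[[1]]$ix else seq_len(g$dims[1])
  iz <- if (strided) influence$layers[[1]]$iz else seq_len(g$dims[3])
  out <- array(0, c(length(ix), length(ix), length(iz)))
  for (ly in influence$layers) {
    w <- matrix(0, length(ly$sx), length(ly$sy))
    w[!is.na(ly$widx)] <- weights[ly$widx[!is.na(ly$widx)]]
    for (j in seq_along(iz)) {
      k <- iz[j]
      if (ly$dd[k] <= 0) next
      fxk <- ly$fx[[k]][ix, , drop = FALSE]
      fyk <- ly$fy[[k]][ix, , drop = FALSE]
      out[, , j] <- out[, , j] + ly$dd[k] * (fxk %*% w %*% t(fyk))
    }
  }
  out
}

# adjoint: residual array on the strided grid -> gradient per beamlet
influence_adjoint <- function(influence, resid) {
  grad <- numeric(nrow(influence$layout))
  ix <- influence$layers[[1]]$ix
  iz <- influence$layers[[1]]$iz
  for (ly in influence$layers) {
    g <- matrix(0, length(ly$sx), length(ly$sy))
    for (j in seq_along(iz)) {
      k <- iz[j]
      if (ly$dd[k] <= 0) next
      fxk <- ly$fx[[k]][ix, , drop = FALSE]
      fyk <- ly$fy[[k]][ix, , drop = FALSE]
      g <- g + ly$dd[k] * (t(fxk) %*% resid[, , j] %*% fyk)
    }
    ok <- !is.na(ly$widx)
    grad[ly$widx[ok]] <- g[ok]
  }
  grad
}

#' Optimize nonnegative beamlet weights to a uniform prescription
#'
#' Minimizes `sum_target (D - p)^2 + lambda * sum_normal D^2` subject to
#' `w >= 0` by projected gradient descent with a power-iteration step
#' size, iterated to a relative objective change below `tol`.
#'
#' Methods exist for a dense influence matrix (voxels x beamlets) and for
#' the separable [plan_influence()] operator.
#'
#' @param influence Influence matrix or `plan_influence` operator.
#' @param rois List with logical `target` (and optionally `normal`) masks
#'   matching the influence voxel space; for `plan_influence` these are
#'   arrays on the full grid and are strided internally.
#' @param prescription Prescription dose, Gy.
#' @param lambda Normal-tissue penalty weight.
#' @param max_iter,tol Iteration cap and relative-objective tolerance.
#' @return A `plan_fit` object: `weights`, `objective`, `iterations`,
#'   `converged`, `coverage_diagnostic`.
#' @export
optimize_weights <- function(influence, rois, prescription, lambda = 0.05,
                             max_iter = 300, tol = 1e-6) {
  UseMethod("optimize_weights")
}

pg_optimize <- function(forward, adjoint, n_w, tmask, nmask, prescription,
                        lambda, max_iter, tol) {
  penal <- ifelse(tmask, 1, lambda * nmask)
  target_arr <- ifelse(tmask, prescription, 0)
  objective <- function(d) sum(penal * (d - target_arr)^2)
  # power iteration for the Lipschitz constant of A' P A
  v <- rep(1, n_w)
  for (i in 1:8) {
    av <- forward(v)
    v2 <- adjoint(penal * av)
    nv <- sqrt(sum(v2^2))
    if (nv == 0) break
    v <- v2 / nv
  }
  lip <- {
    av <- forward(v)
    2 * sum(penal * av^2) / sum(v^2)
  }
  if (!is.finite(lip) || lip <= 0) lip <- 1
  step <- 1 / lip
  # accelerated projected gradient (FISTA with restart on objective
  # increase), started from one projected gradient step at zero
  g0 <- adjoint(penal * (0 - target_arr))
  w <- pmax(-step * g0, 0)
  y <- w
  tk <- 1
  obj <- objective(forward(w))
  trace <- obj
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    g <- 2 * adjoint(penal * (forward(y) - target_arr))
    w_new <- pmax(y - step * g, 0)
    obj_new <- objective(forward(w_new))
    if (obj_new > obj) {
      # restart momentum
      y <- w
      tk <- 1
      g <- 2 * adjoint(penal * (forward(y) - target_arr))
      w_new <- pmax(y - step * g, 0)
      obj_new <- objective(forward(w_new))
      if (obj_new > obj) {
        step <- step / 2
        next
      }
    }
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- w_new + (tk - 1) / t_new * (w_new - w)
    rel <- (obj - obj_new) / max(obj, 1e-300)
    w <- w_new
    tk <- t_new
    obj <- obj_new
    trace <- c(trace, obj)
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  list(weights = w, objective = obj, trace = trace, iterations = it,
       converged = converged)
}

#' @rdname optimize_weights
#' @export
optimize_weights.matrix <- function(influence, rois, prescription,
                                    lambda = 0.05, max_iter = 300,
                                    tol = 1e-6) {
  tmask <- as.logical(rois$target)
  nmask <- if (!is.null(rois$normal)) as.logical(rois$normal) else !tmask
  if (!any(tmask)) abort("target mask is empty")
  res <- pg_optimize(
    forward = function(w) as.numeric(influence %*% w),
    adjoint = function(r) as.numeric(crossprod(influence, r)),
    n_w = ncol(influence), tmask = tmask, nmask = nmask,
    prescription = prescription, lambda = lambda,
    max_iter = max_iter, tol = tol
  )
  cover <- as.numeric(influence[tmask, , drop = FALSE] %*% res$weights)
  new_plan_fit(res, coverage_diagnostic = sum(cover <= 0))
}

#' @rdname optimize_weights
#' @export
optimize_weights.plan_influence <- function(influence, rois, prescription,
                                            lambda = 0.05, max_iter = 300,
                                            tol = 1e-6) {
  ix <- influence$layers[[1]]$ix
  iz <- influence$layers[[1]]$iz
  tmask <- rois$target[ix, ix, iz]
  body <- if (!is.null(rois$body)) rois$body[ix, ix, iz] else !tmask
  nmask <- body & !tmask
  if (!any(tmask)) abort("target mask is empty")
  res <- pg_optimize(
    forward = function(w) influence_forward(influence, w, strided = TRUE),
    adjoint = function(r) influence_adjoint(influence, r),
    n_w = nrow(influence$layout), tmask = tmask, nmask = nmask,
    prescription = prescription, lambda = lambda,
    max_iter = max_iter, tol = tol
  )
  d <- influence_forward(influence, res$weights, strided = TRUE)
  zero_cov <- sum(d[tmask] <= 0)
  new_plan_fit(res, coverage_diagnostic = zero_cov)
}

new_plan_fit <- function(res, coverage_diagnostic = 0) {
  if (coverage_diagnostic > 0) {
    warn(sprintf(
      "%d target voxels received no dose (infeasible coverage)",
      coverage_diagnostic
    ))
  }
  structure(
    list(
      weights = res$weights, objective = res$objective,
      trace = res$trace, iterations = res$iterations,
      converged = res$converged, coverage_diagnostic = coverage_diagnostic
    ),
    class = "plan_fit"
  )
}

#' @export
print.plan_fit <- function(x, ...) {
  cat(sprintf(
    "<plan_fit> %d beamlets, objective %.6g after %d iterations (%s)\n",
    length(x$weights), x$objective, x$iterations,
    if (x$converged) "converged" else "not converged"
  ))
  invisible(x)
}

#' Tidy beamlet weights of a plan fit
#' @param x A `plan_fit`.
#' @param layout Optional [spot_layout()] to join beamlet coordinates.
#' @param ... Unused.
#' @export
tidy.plan_fit <- function(x, layout = NULL, ...) {
  out <- tibble(beamlet = seq_along(x$weights), weight = x$weights)
  if (!is.null(layout)) out <- dplyr::left_join(layout, out, by = "beamlet")
  out
}

#' One-row summary of a plan fit
#' @param x A `plan_fit`.
#' @param ... Unused.
#' @export
glance.plan_fit <- function(x, ...) {
  tibble(
    n_beamlets = length(x$weights),
    n_active = sum(x$weights > 0),
    objective = x$objective,
    iterations = x$iterations,
    converged = x$converged,
    coverage_diagnostic = x$coverage_diagnostic
  )
}

#' Composite dose and LETd maps from weighted beamlets
#'
#' Accumulates the weighted accumulator maps (`sum_e`, `sum_e2l`,
#' `sum_l`) over beamlets and converts: composite LETd is the ratio of
#' the composite energy-transfer distributions, not an average of
#' per-beamlet LETd maps.
#'
#' @param beamlet_maps List of [score_maps()] on one grid.
#' @param weights Nonnegative weights, one per beamlet.
#' @return List with `maps` (merged `score_maps`), `dose` (relative),
#'   `letd` (keV/um).
#' @export
composite_maps <- function(beamlet_maps, weights) {
  stopifnot(length(beamlet_maps) == length(weights))
  if (any(weights < 0)) abort("weights must be nonnegative")
  acc <- NULL
  for (i in seq_along(beamlet_maps)) {
    m <- beamlet_maps[[i]]
    stopifnot(inherits(m, "score_maps"))
    scaled <- m
    scaled$sum_e <- m$sum_e * weights[i]
    scaled$sum_l <- m$sum_l * weights[i]
    scaled$sum_e2l <- m$sum_e2l * weights[i]
    scaled$sum_dose <- m$sum_dose * weights[i]
    acc <- if (is.null(acc)) scaled else merge_score_maps(acc, scaled)
  }
  list(
    maps = acc,
    dose = dose_map(acc, in_gray = FALSE),
    letd = letd_map(acc)
  )
}

#' Composite maps from a separable plan influence operator
#'
#' Full-resolution composite physical dose and dose-averaged LET for an
#' optimized weight vector (exact for the surrogate model).
#'
#' @param influence A [plan_influence()].
#' @param weights Beamlet weights.
#' @return List with `dose` and `letd` arrays on the influence grid.
#' @export
compose_plan <- function(influence, weights) {
  g <- influence$grid
  dose <- array(0, g$dims)
  e2l <- array(0, g$dims)
  nz <- g$dims[3]
  for (ly in influence$layers) {
    w <- matrix(0, length(ly$sx), length(ly$sy))
    w[!is.na(ly$widx)] <- weights[ly$widx[!is.na(ly$widx)]]
    if (all(w == 0)) next
    boost <- 1 + outer(ly$bx, ly$by, `+`)
    for (k in seq_len(nz)) {
      if (ly$dd[k] <= 0) next
      m <- ly$dd[k] * (ly$fx[[k]] %*% w %*% t(ly$fy[[k]]))
      dose[, , k] <- dose[, , k] + m
      e2l[, , k] <- e2l[, , k] + ly$ld[k] * boost * m
    }
  }
  letd <- array(NA_real_, g$dims)
  ok <- dose > 1e-4 * max(dose)
  letd[ok] <- e2l[ok] / dose[ok]
  list(dose = dose, letd = letd)
}

#' Plan a target with and without collimation and compare
#'
#' Builds the layout, optimizes uncollimated and collimated plans to the
#' prescription, normalizes each to physical target D95 = prescription,
#' and reports composite maps, metric tables, and the half-prescription
#' volume reduction.
#'
#' @param target `"cube"` or `"pyramid"`.
#' @param prescription Gy.
#' @param grid Composite grid.
#' @param lambda Normal-tissue penalty.
#' @param stride Optimization voxel stride.
#' @param max_iter Optimizer iteration cap.
#' @return List with per-delivery results (`uncollimated`, `collimated`:
#'   each has `fit`, `dose`, `letd`, `rbe_dose`, `metrics`, `v50_cm3`)
#'   plus `v50_reduction_pct`, `rois`, `spec_uncollimated`,
#'   `spec_collimated`.
#' @export
plan_study <- function(target = c("cube", "pyramid"), prescription = 25,
                       grid = plan_grid(), lambda = 0.05, stride = 2L,
                       max_iter = 1200) {
  target <- match.arg(target)
  strategy <- if (target == "cube") "fixed_field" else "per_layer_target_width"
  run_one <- function(coll_strategy) {
    spec <- plan_spec(target,
      prescription = prescription,
      collimation_strategy = coll_strategy
    )
    layout <- spot_layout(spec)
    rois <- make_rois(spec, grid)
    infl <- plan_influence(layout, grid, stride = stride)
    fit <- optimize_weights(infl, rois, prescription,
      lambda = lambda, max_iter = max_iter
    )
    comp <- compose_plan(infl, fit$weights)
    d95 <- dvh_value(comp$dose[rois$target], 0.95)
    scale <- prescription / d95
    dose <- comp$dose * scale
    rbe_d <- rbe_weighted_dose(dose, comp$letd, fill_letd = 0)
    v50 <- sum(dose >= 0.5 * prescription, na.rm = TRUE) * prod(grid$spacing)
    list(
      spec = spec, layout = layout, fit = fit, dose = dose,
      letd = comp$letd, rbe_dose = rbe_d,
      metrics = plan_metrics(dose, rbe_d, comp$letd, rois, grid),
      v50_cm3 = v50, rois = rois
    )
  }
  unc <- run_one("none")
  col <- run_one(strategy)
  list(
    target = target,
    uncollimated = unc, collimated = col,
    rois = unc$rois,
    v50_reduction_pct = 100 * (unc$v50_cm3 - col$v50_cm3) / unc$v50_cm3
  )
}
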
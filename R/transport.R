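# R surface over the condensed-history transport kernel.

#' Transport configuration
#'
#' @param max_step_water,max_step_nickel Maximum step length, cm. Steps are
#'   additionally refined near the end of range (<= 20% of the residual
#'   range) so the Bragg peak is resolved.
#' @param energy_cutoff Kinetic-energy cutoff, MeV; below it the residual
#'   energy is deposited locally (residual range < 8 um of water).
#' @param nuclear_model Enable the nuclear-interaction surrogate.
#' @param nuclear_rate_per_cm Interaction rate scale: probability per cm in
#'   unit-density material at >= 20 MeV (density- and energy-scaled).
#' @param nuclear_local_fraction Fraction of the interacting proton's energy
#'   deposited locally as a lumped dose surrogate.
#' @param straggling Enable Gaussian (Bohr) energy-loss straggling.
#' @param scattering Enable Highland multiple Coulomb scattering.
#' @param seed Integer seed for the counter-based per-history streams.
#' @return A `transport_config` list.
#' @export
transport_config <- function(max_step_water = 0.05, max_step_nickel = 0.02,
                             energy_cutoff = 0.5, nuclear_model = TRUE,
                             nuclear_rate_per_cm = 0.01,
                             nuclear_local_fraction = 0.6,
                             straggling = TRUE, scattering = TRUE,
                             seed = 1L) {
  if (max_step_water <= 0 || max_step_nickel <= 0) abort("max_step must be positive")
  if (energy_cutoff < 0.5) abort("energy_cutoff must be >= the table minimum (0.5 MeV)")
  structure(
    list(
      max_step_water = max_step_water, max_step_nickel = max_step_nickel,
      energy_cutoff = energy_cutoff, nuclear_model = nuclear_model,
      nuclear_rate_per_cm = nuclear_rate_per_cm,
      nuclear_local_fraction = nuclear_local_fraction,
      straggling = straggling, scattering = scattering, seed = as.integer(seed)
    ),
    class = "transport_config"
  )
}

#' Highland multiple-scattering angle
#'
#' `theta0 = 13.6 MeV / (beta p c) * sqrt(x / X0) * (1 + 0.038 ln(x / X0))`,
#' clamped to be nonnegative (zero path gives zero).
#'
#' @param energy Proton kinetic energy, MeV.
#' @param path_gcm2 Traversed mass thickness, g/cm^2 (>= 0).
#' @param x0_gcm2 Radiation length of the medium, g/cm^2.
#' @return Scattering angle sigma per projection, radians.
#' @export
highland_theta0 <- function(energy, path_gcm2, x0_gcm2) {
  if (any(path_gcm2 < 0)) abort("path must be nonnegative")
  pc <- sqrt(energy * (energy + 2 * PROTON_MASS_MEV))
  beta <- pc / (energy + PROTON_MASS_MEV)
  t <- path_gcm2 / x0_gcm2
  th <- ifelse(
    t > 0,
    13.6 / (beta * pc) * sqrt(t) * (1 + 0.038 * log(t)),
    0
  )
  pmin(pmax(th, 0), 1.5)
}

#' Bohr energy-loss straggling sigma
#'
#' Gaussian straggling width for a step of length `ds` in the material:
#' `sigma^2 = 0.1569 * (Z/A) * rho * ds` (MeV^2, ds in cm).
#'
#' @param material A `material_spec`.
#' @param ds Step length, cm.
#' @return Straggling sigma, MeV.
#' @export
bohr_sigma <- function(material, ds) {
  sqrt(0.1569 * material$z_over_a * material$density * ds)
}

#' One condensed-history step (reference implementation)
#'
#' Mirrors the transport kernel's step rule in R: the mean loss follows
#' the exact CSDA range-energy relation (`E - E(range(E) - ds)`), with
#' optional Bohr straggling added and the total truncated to `[0, E]`;
#' all remaining energy is deposited when the residual range fits inside
#' the step.
#'
#' @param energy Kinetic energy before the step, MeV.
#' @param material A `material_spec`.
#' @param ds Step length, cm.
#' @param straggling Sample Gaussian straggling (uses the R RNG).
#' @return List with `eps` (MeV deposited), `l` (cm), `energy_after` (MeV)
#'   and `alive` (FALSE when the proton ranged out within the step).
#' @export
condensed_history_step <- function(energy, material, ds, straggling = FALSE) {
  if (ds <= 0) abort("step length must be positive")
  res <- csda_range(material, energy)
  if (res <= ds) {
    return(list(eps = energy, l = max(res, 1e-6), energy_after = 0, alive = FALSE))
  }
  eps <- energy - energy_at_range(material, res - ds)
  if (straggling) eps <- eps + bohr_sigma(material, ds) * rnorm(1)
  eps <- min(max(eps, 0), energy)
  list(eps = eps, l = ds, energy_after = energy - eps, alive = TRUE)
}

material_for_cpp <- function(material) {
  e <- material$stopping_table$energy
  list(
    log_e = log(e),
    log_s = log(material$stopping_table$stopping_power),
    log_r = log(pmax(csda_range(material, e), 1e-12)),
    density = material$density,
    z_over_a = material$z_over_a,
    x0 = material$radiation_length,
    e_min = material$.e_range[1],
    e_max = material$.e_range[2]
  )
}

blades_for_cpp <- function(collimation) {
  b <- collimation$blades
  if (nrow(b) == 0) {
    return(matrix(numeric(), ncol = 7))
  }
  cbind(
    ifelse(b$axis == "X", 0, 1), b$side,
    b$z_center - b$thickness / 2, b$z_center + b$thickness / 2,
    b$offset, b$extent, b$z_center
  )
}

#' Transport a particle batch through the beamline and phantom
#'
#' Runs the condensed-history Monte Carlo: vacuum flight between
#' components, Highland scattering and Bohr straggling in nickel blades
#' and water, per-step `(eps, l, eps^2/l)` scoring into the voxel grid,
#' the nuclear surrogate, and plane-crossing records at `plane_z`.
#'
#' @param particles Tibble from [sample_primaries()].
#' @param collimation A [build_collimation()] config.
#' @param grid Scoring [voxel_grid()] (water phantom).
#' @param config A [transport_config()].
#' @param source_distance Effective source distance, cm (for the focused
#'   blade edges).
#' @param plane_z Spectral tally plane, cm (default the phantom surface).
#' @param record_plane Record plane crossings.
#' @return A `beamlet_transport` list: `maps` ([score_maps()]),
#'   `crossings` tibble (`energy`, `x`, `y`, `weight`, `origin`), and a
#'   one-row `ledger` tibble whose energy channels close to the initial
#'   energy.
#' @export
transport <- function(particles, collimation = build_collimation(),
                      grid = beamlet_grid(), config = transport_config(),
                      source_distance = 200, plane_z = grid$origin[3],
                      record_plane = TRUE) {
  stopifnot(is.data.frame(particles), inherits(collimation, "collimation_config"))
  need <- c("x", "y", "z", "ux", "uy", "uz", "energy", "weight")
  if (!all(need %in% names(particles))) abort("particles lack required columns")
  pm <- as.matrix(particles[, need])
  orig <- match(particles$origin %||% rep("primary", nrow(pm)),
    c("primary", "collimator_scatter", "nuclear_secondary")
  ) - 1L
  cfg <- c(config, list(
    plane_z = plane_z, record_plane = record_plane,
    source_distance = source_distance, seed = as.double(config$seed)
  ))
  res <- cpp_transport(
    pm, orig, material_for_cpp(material_water()),
    material_for_cpp(material_nickel()), blades_for_cpp(collimation),
    grid$origin, grid$spacing, grid$dims, cfg
  )
  maps <- score_maps(grid)
  maps$sum_e <- array(res$sum_e, dim = grid$dims)
  maps$sum_l <- array(res$sum_l, dim = grid$dims)
  maps$sum_e2l <- array(res$sum_e2l, dim = grid$dims)
  maps$sum_dose <- array(res$sum_dose, dim = grid$dims)
  maps$histories <- nrow(pm)
  cr <- res$crossings
  crossings <- tibble(
    energy = cr[, 1], x = cr[, 2], y = cr[, 3], weight = cr[, 4],
    origin = c("primary", "collimator_scatter", "nuclear_secondary")[
      res$crossing_origin + 1L
    ]
  )
  led <- as.list(res$ledger)
  ledger <- tibble(
    initial = led$initial, scored = led$scored, external = led$external,
    escaped = led$escaped, nuclear_unaccounted = led$nuclear_unaccounted,
    closure = (led$scored + led$external + led$escaped +
      led$nuclear_unaccounted) / led$initial
  )
  structure(
    list(
      maps = maps, crossings = crossings, ledger = ledger,
      collimation = collimation, config = config, plane_z = plane_z
    ),
    class = "beamlet_transport"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.beamlet_transport <- function(x, ...) {
  cat(sprintf(
    "<beamlet_transport> %s, %g histories, %d plane crossings, closure %.8f\n",
    x$collimation$scenario, x$maps$histories, nrow(x$crossings),
    x$ledger$closure
  ))
  invisible(x)
}

#' Simulate one beamlet end to end
#'
#' Samples primaries from the divergent Gaussian source, builds the
#' requested collimation scenario, and transports through the trimmers
#' into the water phantom.
#'
#' @param energy Nominal energy, MeV.
#' @param n Number of histories.
#' @param scenario Collimation scenario name.
#' @param offset Trimmer offset, cm.
#' @param seed Integer seed (drives both source sampling and transport).
#' @param grid Scoring grid.
#' @param config Transport configuration (its seed is overridden by `seed`).
#' @param source Source model override.
#' @return A `beamlet_transport` object (see [transport()]) with the
#'   source model attached.
#' @export
simulate_beamlet <- function(energy, n = 1e5, scenario = "uncollimated",
                             offset = 0, seed = 1L, grid = beamlet_grid(),
                             config = transport_config(),
                             source = source_model(energy)) {
  config$seed <- as.integer(seed)
  particles <- sample_primaries(source, n, seed = seed)
  collim <- build_collimation(scenario, offset, energy)
  out <- transport(particles, collim, grid, config,
    source_distance = source$source_distance
  )
  out$source <- source
  out
}

#' Integral depth-dose curve
#'
#' Laterally integrated dose per depth slab.
#'
#' @param maps A [score_maps()] or `beamlet_transport`.
#' @return Tibble with `depth` (cm, voxel centers) and `dose` (relative).
#' @export
idd <- function(maps) {
  if (inherits(maps, "beamlet_transport")) maps <- maps$maps
  stopifnot(inherits(maps, "score_maps"))
  d <- apply(maps$sum_dose, 3, sum)
  tibble(depth = grid_depths(maps$grid), dose = d)
}

#' Tidy the plane crossings of a transport run
#' @param x A `beamlet_transport`.
#' @param ... Unused.
#' @export
tidy.beamlet_transport <- function(x, ...) x$crossings

#' One-row summary of a transport run
#' @param x A `beamlet_transport`.
#' @param ... Unused.
#' @export
glance.beamlet_transport <- function(x, ...) {
  i <- idd(x)
  pk <- tryCatch(find_bragg_peak(i$depth, i$dose), error = function(e) NA_real_)
  tibble(
    scenario = x$collimation$scenario,
    offset = x$collimation$common_offset,
    histories = x$maps$histories,
    crossings = nrow(x$crossings),
    energy_closure = x$ledger$closure,
    bragg_peak_depth = pk
  )
}

#' @rdname autoplot-dcslet
#' @export
autoplot.beamlet_transport <- function(object, ...) {
  d <- idd(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$depth, y = .data$dose / max(.data$dose))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth (cm)", y = "relative integral depth dose")
}
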
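# Material constants and proton stopping-power / range services.
#
# Stopping tables are generated at construction from the Bethe formula
# (no shell or density corrections) and rescaled by a single per-material
# factor so that the water CSDA ranges at 90/120/150 MeV reproduce the
# Bragg-peak depths used throughout the analysis (6.4 / 10.65 / 15.75 cm).

PROTON_MASS_MEV <- 938.272
ELECTRON_MASS_MEV <- 0.510999
BETHE_K <- 0.307075 # MeV cm^2 / mol: 4 pi N_A r_e^2 m_e c^2

# Water BP-depth anchors (cm) at the three study energies (MeV).
WATER_RANGE_ANCHORS <- c(`90` = 6.4, `120` = 10.65, `150` = 15.75)

# MeV/cm -> keV/um
MEV_PER_CM_TO_KEV_PER_UM <- 0.1
# MeV/g -> Gy
MEV_PER_G_TO_GY <- 1.602176634e-10

#' Bethe mass electronic stopping power for protons
#'
#' Closed-form Bethe formula without shell or density-effect corrections,
#' used to generate the packaged stopping tables and available directly as
#' an independent cross-check.
#'
#' @param energy Proton kinetic energy in MeV (vectorized).
#' @param mean_excitation_energy Mean excitation energy I in eV.
#' @param z_over_a Ratio Z/A of the medium in mol/g.
#' @return Mass stopping power in MeV cm^2/g.
#' @export
bethe_stopping_power <- function(energy, mean_excitation_energy, z_over_a) {
  stopifnot(all(energy > 0))
  g <- 1 + energy / PROTON_MASS_MEV
  b2 <- 1 - 1 / g^2
  me <- ELECTRON_MASS_MEV
  wmax <- 2 * me * b2 * g^2 /
    (1 + 2 * g * me / PROTON_MASS_MEV + (me / PROTON_MASS_MEV)^2)
  i_mev <- mean_excitation_energy * 1e-6
  BETHE_K * z_over_a / b2 * (0.5 * log(2 * me * b2 * g^2 * wmax / i_mev^2) - b2)
}

#' Logarithmic energy grid for stopping tables
#'
#' @param e_min,e_max Energy bounds in MeV; the minimum must not exceed
#'   1 MeV so low-energy collimator scatter remains representable.
#' @param n Number of grid points.
#' @return Numeric vector of strictly increasing energies (MeV).
#' @export
energy_grid <- function(e_min = 0.5, e_max = 250, n = 400) {
  if (e_min <= 0 || e_max <= e_min) abort("invalid energy grid bounds")
  if (e_min > 1) abort("energy grid must reach down to at least 1 MeV")
  exp(seq(log(e_min), log(e_max), length.out = n))
}

new_material_spec <- function(name, density, mean_excitation_energy,
                              radiation_length, z_over_a, stopping_table,
                              range_scale = 1) {
  stopifnot(density > 0, all(stopping_table$stopping_power > 0))
  e <- stopping_table$energy
  s <- stopping_table$stopping_power
  if (is.unsorted(e, strictly = TRUE)) abort("stopping table energies must increase")
  # log-log interpolation of S(E)
  s_fun <- approxfun(log(e), log(s), rule = 1)
  # cumulative CSDA range from table minimum, cm: integral dE / (S * rho)
  # on a fine log grid for smoothness
  ef <- exp(seq(log(min(e)), log(max(e)), length.out = 2000))
  sf <- exp(s_fun(log(ef)))
  inv <- 1 / (sf * density)
  dr <- c(0, cumsum((inv[-1] + inv[-length(ef)]) / 2 * diff(ef)))
  r_fun <- approxfun(log(ef), log(dr + 1e-12))
  e_of_r <- approxfun(log(dr[-1]), log(ef[-1]), rule = 2)
  structure(
    list(
      name = name,
      density = density,
      mean_excitation_energy = mean_excitation_energy,
      radiation_length = radiation_length,
      z_over_a = z_over_a,
      stopping_table = stopping_table,
      range_scale = range_scale,
      .s_fun = s_fun,
      .r_fun = r_fun,
      .e_of_r = e_of_r,
      .e_range = range(e)
    ),
    class = "material_spec"
  )
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf(
    "<material_spec> %s: rho=%.4g g/cm^3, I=%.4g eV, X0=%.4g g/cm^2, Z/A=%.4g, %d-point table\n",
    x$name, x$density, x$mean_excitation_energy, x$radiation_length,
    x$z_over_a, nrow(x$stopping_table)
  ))
  invisible(x)
}

build_material <- function(name, density, i_ev, x0, z_over_a,
                           grid = energy_grid(), stopping_table = NULL) {
  if (is.null(stopping_table)) {
    s <- bethe_stopping_power(grid, i_ev, z_over_a)
    stopping_table <- tibble(energy = grid, stopping_power = s)
  }
  new_material_spec(name, density, i_ev, x0, z_over_a, stopping_table)
}

# Bragg-peak shift of the model itself: with Bohr range straggling plus
# the source energy spread, the IDD maximum sits proximal to the CSDA
# range by an amount computed from the regularized power-law Bragg curve.
peak_shift_for <- function(material, energy, energy_sigma) {
  r0 <- csda_range(material, energy)
  es <- seq(material$.e_range[1], energy, length.out = 1500)
  s <- mass_stopping_power(material, es) * material$density
  dvar <- 0.1569 * material$z_over_a * material$density / s^2 *
    c(0, diff(es)) / s
  s_bohr <- sqrt(sum(dvar))
  s_beam <- energy_sigma /
    (mass_stopping_power(material, energy) * material$density)
  sig <- sqrt(s_bohr^2 + s_beam^2)
  # peak of int_0^R S(E(v)) phi((z - (R - v))/sig) dv, v the residual
  # range, using the model's own stopping profile; the substitution
  # w = v^0.565 tames the ~v^-0.435 singularity at the track end
  w <- seq(1e-7, r0^0.565, length.out = 3000)
  v <- w^(1 / 0.565)
  jac <- (1 / 0.565) * w^(1 / 0.565 - 1)
  sv <- mass_stopping_power(
    material, energy_at_range(material, pmax(v, 1e-6))
  ) * jac
  z <- seq(0.0005, r0 + 3 * sig, by = 0.001)
  d <- vapply(z, function(zz) sum(dnorm((zz - r0 + v) / sig) * sv), numeric(1))
  # evaluate the curve the way the analysis pipeline does: 1 mm depth
  # bins and parabolic refinement, so the calibration covers the whole
  # measurement chain including the estimator's behavior on the skewed
  # binned peak
  zc <- seq(0.05, r0 + 3 * sig - 0.05, by = 0.1)
  dv <- vapply(
    zc, function(c0) mean(d[z >= c0 - 0.05 & z < c0 + 0.05]), numeric(1)
  )
  r0 - find_bragg_peak(zc, dv) + detour_for(material, energy)
}

# Mean depth deficit from multiple Coulomb scattering: the path length is
# the CSDA range, but the penetration depth is shorter by the accumulated
# 1 - cos(theta) along the track, evaluated with the same per-step
# Highland model the transport kernel uses.
detour_for <- function(material, energy, ds = 0.05) {
  e <- energy
  var2 <- 0
  det <- 0
  repeat {
    res <- csda_range(material, e)
    step <- min(ds, max(0.2 * res, 1e-4))
    if (res <= step) {
      det <- det + var2 / 2 * res
      break
    }
    det <- det + var2 / 2 * step
    th0 <- highland_theta0(e, step * material$density, material$radiation_length)
    var2 <- var2 + 2 * th0^2
    e <- energy_at_range(material, res - step)
    if (e <= material$.e_range[1] + 1e-9) break
  }
  det
}

#' Model-predicted Bragg-peak depth
#'
#' CSDA range minus the peak shift caused by range straggling and the
#' beam energy spread; this is the depth at which the simulated integral
#' depth dose is expected to peak.
#'
#' @param energy Nominal energy, MeV.
#' @param energy_sigma Beam energy spread, MeV (default 0.7% of nominal).
#' @param material Water.
#' @return Depth in cm.
#' @export
predicted_peak_depth <- function(energy, energy_sigma = 0.007 * energy,
                                 material = material_water()) {
  vapply(
    seq_along(energy),
    function(i) {
      csda_range(material, energy[i]) -
        peak_shift_for(material, energy[i], energy_sigma[min(i, length(energy_sigma))])
    },
    numeric(1)
  )
}

# Calibration of the Bethe tables against the printed simulated BP depths:
# one scale factor plus a small energy tilt (E/100)^alpha, frozen below
# 20 MeV, standing in for the shell/binding corrections absent from the
# plain Bethe formula. Solved once so that the model's own predicted peak
# depths (CSDA range minus peak shift) match the anchors.
water_calibration <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) {
      return(cache)
    }
    m0 <- build_material("water", 1.0, 75, 36.08, 0.5551)
    anchor_e <- as.numeric(names(WATER_RANGE_ANCHORS))
    printed <- as.numeric(WATER_RANGE_ANCHORS)
    tilt <- function(e, a) (pmax(e, 20) / 100)^a
    range_with <- function(e0, a) {
      es <- seq(m0$.e_range[1], e0, length.out = 3000)
      s <- mass_stopping_power(m0, es) * tilt(es, a)
      inv <- 1 / s
      sum((inv[-1] + inv[-length(inv)]) / 2 * diff(es))
    }
    shifts <- vapply(
      anchor_e, function(e) peak_shift_for(m0, e, 0.007 * e), numeric(1)
    )
    target_r <- printed + shifts
    fit_for <- function(a) {
      r <- vapply(anchor_e, range_with, numeric(1), a = a)
      b <- sum(r * target_r) / sum(r^2)
      list(resid = sum((b * r - target_r)^2), scale = 1 / b)
    }
    a_opt <- optimize(function(a) fit_for(a)$resid, c(-0.05, 0.05))$minimum
    cache <<- list(
      scale = fit_for(a_opt)$scale, alpha = a_opt,
      shifts = setNames(shifts, names(WATER_RANGE_ANCHORS)),
      target_ranges = setNames(target_r, names(WATER_RANGE_ANCHORS))
    )
    cache
  }
})

calibrated_table <- function(i_ev, z_over_a, grid = energy_grid()) {
  cal <- water_calibration()
  s <- bethe_stopping_power(grid, i_ev, z_over_a) * cal$scale *
    (pmax(grid, 20) / 100)^cal$alpha
  tibble(energy = grid, stopping_power = s)
}

#' Water material specification
#'
#' Liquid water with I = 75 eV, X0 = 36.08 g/cm^2. The Bethe-generated
#' stopping table is calibrated (scale plus small energy tilt) so the
#' model's predicted Bragg-peak depths at 90/120/150 MeV match the
#' 6.4/10.65/15.75 cm anchors within 1 mm.
#'
#' @param stopping_table Optional replacement table, a data frame with
#'   columns `energy` (MeV) and `stopping_power` (MeV cm^2/g).
#' @return A `material_spec` object.
#' @export
material_water <- function(stopping_table = NULL) {
  if (is.null(stopping_table)) {
    stopping_table <- calibrated_table(75, 0.5551)
  }
  build_material("water", 1.0, 75, 36.08, 0.5551,
    stopping_table = as_tibble(stopping_table)
  )
}

#' Nickel material specification
#'
#' Nickel trimmer-blade material: rho = 8.902 g/cm^3, I = 311 eV,
#' X0 = 12.68 g/cm^2 (1.424 cm). The water calibration factors are
#' reused since nickel has no printed range anchor.
#'
#' @inheritParams material_water
#' @return A `material_spec` object.
#' @export
material_nickel <- function(stopping_table = NULL) {
  if (is.null(stopping_table)) {
    stopping_table <- calibrated_table(311, 0.4703)
  }
  build_material("nickel", 8.902, 311, 12.68, 0.4703,
    stopping_table = as_tibble(stopping_table)
  )
}

check_energy_range <- function(material, energy) {
  lo <- material$.e_range[1]
  hi <- material$.e_range[2]
  if (any(energy < lo - 1e-12 | energy > hi + 1e-12)) {
    abort(sprintf(
      "energy outside stopping table range [%.3g, %.3g] MeV for %s",
      lo, hi, material$name
    ))
  }
}

#' Mass electronic stopping power from the material table
#'
#' Log-log interpolation on the packaged stopping table.
#'
#' @param material A `material_spec`.
#' @param energy Proton kinetic energy in MeV (vectorized).
#' @return Mass stopping power, MeV cm^2/g.
#' @export
mass_stopping_power <- function(material, energy) {
  check_energy_range(material, energy)
  exp(material$.s_fun(log(pmax(energy, material$.e_range[1]))))
}

#' CSDA range
#'
#' Continuous-slowing-down range in cm, integrating dE/(S(E) rho) from the
#' 0.5 MeV table cutoff up to `energy`. The sub-cutoff residual (< 8 um of
#' water) is deposited locally by the transport loop, not ranged.
#'
#' @inheritParams mass_stopping_power
#' @return Range in cm.
#' @export
csda_range <- function(material, energy) {
  check_energy_range(material, energy)
  pmax(exp(material$.r_fun(log(energy))) - 1e-12, 0)
}

#' Energy whose CSDA range equals a given depth
#'
#' Inverse of [csda_range()], used to pick energy layers for a target
#' depth extent.
#'
#' @param material A `material_spec`.
#' @param range_cm Range in cm (vectorized).
#' @return Proton kinetic energy, MeV.
#' @export
energy_at_range <- function(material, range_cm) {
  stopifnot(all(range_cm > 0))
  exp(material$.e_of_r(log(range_cm)))
}

#' LET of a proton in water
#'
#' Unrestricted stopping-power LET: `S(E) * rho_water * 0.1`, i.e.
#' MeV/cm expressed in keV/um.
#'
#' @param energy Proton kinetic energy, MeV (vectorized).
#' @param material Water material (override to supply a replacement table).
#' @return LET in keV/um.
#' @export
let_in_water <- function(energy, material = material_water()) {
  mass_stopping_power(material, energy) * material$density *
    MEV_PER_CM_TO_KEV_PER_UM
}

#' Write or read a material stopping table as CSV
#'
#' @param material A `material_spec`.
#' @param path CSV path (columns `energy`, `stopping_power`).
#' @return `write_material_table` returns `path` invisibly;
#'   `read_material_table` returns a tibble usable as `stopping_table`.
#' @export
write_material_table <- function(material, path) {
  write.csv(material$stopping_table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_material_table
#' @export
read_material_table <- function(path) {
  as_tibble(read.csv(path))
}
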
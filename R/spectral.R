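# Reduction of exit-plane spectra to tail features and scatter fractions.

#' Percentile of a binned histogram
#'
#' Linear interpolation within the bin containing cumulative fraction `q`,
#' with a left-continuous CDF built from the bin left edges. Bin width is
#' inferred from the spacing of `bin_left`.
#'
#' @param hist Tibble with `bin_left` and `count` columns.
#' @param q Fraction in (0, 1).
#' @return Interpolated percentile value.
#' @export
hist_percentile <- function(hist, q) {
  if (nrow(hist) == 0 || sum(hist$count) <= 0) abort("empty histogram")
  if (q <= 0 || q >= 1) abort("q must lie strictly inside (0, 1)")
  o <- order(hist$bin_left)
  left <- hist$bin_left[o]
  cnt <- hist$count[o]
  width <- if (length(left) > 1) min(diff(left)) else 0.1
  cum <- cumsum(cnt) / sum(cnt)
  target <- q
  i <- which(cum >= target - 1e-12)[1]
  below <- if (i > 1) cum[i - 1] else 0
  frac <- (target - below) / (cum[i] - below)
  left[i] + frac * width
}

#' Scatter fraction of an energy spectrum
#'
#' Fraction of the weighted counts with bin center below
#' `nominal_energy - 3 * sigma`, the threshold tied to the incident
#' Gaussian spectrum model (not the empirical mean). A pure Gaussian
#' spectrum therefore gives the Normal tail mass beyond -3 sigma,
#' about 0.00135.
#'
#' @param energy_hist Tibble with `bin_left` and `count`.
#' @param nominal_energy Incident-spectrum mean, MeV.
#' @param sigma Incident-spectrum standard deviation, MeV.
#' @param bin_width Histogram bin width (default 0.1 MeV).
#' @return Fraction in `[0, 1]`.
#' @export
scatter_fraction <- function(energy_hist, nominal_energy, sigma,
                             bin_width = 0.1) {
  if (nrow(energy_hist) == 0 || sum(energy_hist$count) <= 0) {
    abort("empty histogram")
  }
  centers <- energy_hist$bin_left + bin_width / 2
  thr <- nominal_energy - 3 * sigma
  sum(energy_hist$count[centers < thr]) / sum(energy_hist$count)
}

#' Spectral features of one exit-plane spectrum
#'
#' Mean energy, 1st-percentile energy, 99th-percentile track LET and the
#' scatter fraction.
#'
#' @param spectrum A [plane_spectrum()].
#' @param nominal_energy,sigma Incident-spectrum Gaussian parameters, MeV.
#' @return One-row tibble.
#' @export
spectral_features <- function(spectrum, nominal_energy, sigma) {
  eh <- spectrum$energy_hist
  if (nrow(eh) == 0 || sum(eh$count) <= 0) abort("empty spectrum")
  centers <- eh$bin_left + spectrum$energy_bin / 2
  tibble(
    mean_energy = sum(centers * eh$count) / sum(eh$count),
    p1_energy = hist_percentile(eh, 0.01),
    p99_lett = hist_percentile(spectrum$lett_hist, 0.99),
    scatter_fraction = scatter_fraction(
      eh, nominal_energy, sigma, spectrum$energy_bin
    )
  )
}

#' Sweep spectral features over collimation scenarios and offsets
#'
#' Simulates each (energy, scenario, offset) cell with the shared seed and
#' reduces the exit-plane spectrum to its features. The uncollimated
#' reference row is included once per energy (offset `NA`).
#'
#' @param energies Nominal energies, MeV.
#' @param scenarios Collimation scenario names (uncollimated is always
#'   added as the reference).
#' @param offsets Trimmer offsets, cm.
#' @param n Histories per cell.
#' @param seed Integer seed.
#' @param config Transport configuration.
#' @return Tibble with one row per cell: `energy`, `scenario`,
#'   `offset_cm`, `mean_E`, `p1_E`, `p99_LETt`, `scatter_fraction`.
#' @export
feature_sweep <- function(energies = c(90, 120, 150),
                          scenarios = c("X1", "Y1", "XY_pair", "four_trimmer_GRID"),
                          offsets = c(0, 0.25, 0.5, 1.0),
                          n = 1e5, seed = 1L, config = transport_config()) {
  cells <- dplyr::bind_rows(
    tidyr::expand_grid(energy = energies, scenario = "uncollimated", offset = NA_real_),
    tidyr::expand_grid(energy = energies, scenario = scenarios, offset = offsets)
  )
  purrr::pmap_dfr(cells, function(energy, scenario, offset) {
    src <- source_model(energy)
    sim <- simulate_beamlet(
      energy,
      n = n, scenario = scenario,
      offset = ifelse(is.na(offset), 0, offset), seed = seed,
      config = config, source = src
    )
    sp <- plane_spectrum(sim$crossings, z_plane = sim$plane_z)
    f <- spectral_features(sp, energy, src$energy_sigma)
    tibble(
      energy = energy, scenario = scenario, offset_cm = offset,
      mean_E = f$mean_energy, p1_E = f$p1_energy, p99_LETt = f$p99_lett,
      scatter_fraction = f$scatter_fraction
    )
  })
}

#' @rdname autoplot-dcslet
#' @param features A [feature_sweep()] result (for the feature panel plot).
#' @export
plot_feature_sweep <- function(features) {
  ref <- dplyr::filter(features, .data$scenario == "uncollimated")
  d <- dplyr::filter(features, .data$scenario != "uncollimated") |>
    tidyr::pivot_longer(c("p1_E", "p99_LETt", "scatter_fraction"),
      names_to = "feature", values_to = "value"
    )
  rl <- tidyr::pivot_longer(ref, c("p1_E", "p99_LETt", "scatter_fraction"),
    names_to = "feature", values_to = "value"
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$offset_cm, .data$value,
    color = .data$scenario
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(
      data = rl, ggplot2::aes(yintercept = .data$value),
      linetype = "dashed"
    ) +
    ggplot2::facet_grid(feature ~ energy, scales = "free_y") +
    ggplot2::labs(x = "trimmer offset (cm)", y = NULL)
}
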
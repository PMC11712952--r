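#' ggplot2 methods for dcslet result objects
#'
#' `autoplot()` methods: a `plane_spectrum` draws the kinetic-energy and
#' track-LET histograms; a `beamlet_transport` draws the integral
#' depth-dose curve; a `vh_curve` draws the cumulative volume histogram.
#' `plot_feature_sweep()` draws the spectral-feature panels (tail
#' percentiles and scatter fraction vs. trimmer offset per energy) with
#' the uncollimated reference as a dashed line.
#'
#' @param object Object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-dcslet
NULL
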
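# Phenomenological proton RBE model (McNamara-type):
#   RBE_max = p0 + p1 * LETd / (a/b)x
#   RBE_min = p2 + p3 * sqrt((a/b)x) * LETd
#   RBE = (1 / 2D) [ sqrt((a/b)x^2 + 4 D (a/b)x RBE_max + 4 D^2 RBE_min^2)
#                    - (a/b)x ]
# with the D -> 0 limit equal to RBE_max.

#' RBE model parameters
#'
#' Fit coefficients of the phenomenological proton RBE model and the
#' photon linear-quadratic ratio of the tissue.
#'
#' @param p0,p1,p2,p3 Unitless fit coefficients.
#' @param alpha_beta_x Photon (alpha/beta)x, Gy (> 0).
#' @return An `rbe_params` list.
#' @export
rbe_params <- function(p0 = 0.99064, p1 = 0.35605, p2 = 1.1012,
                       p3 = -0.0038703, alpha_beta_x = 3.49) {
  if (alpha_beta_x <= 0) abort("alpha_beta_x must be positive")
  structure(
    list(p0 = p0, p1 = p1, p2 = p2, p3 = p3, alpha_beta_x = alpha_beta_x),
    class = "rbe_params"
  )
}

#' Relative biological effectiveness from dose and dose-averaged LET
#'
#' Vectorized over `dose` and `letd`. At zero dose the continuous limit
#' `RBE_max` is returned; `NA` inputs propagate.
#'
#' @param dose Physical dose, Gy (>= 0).
#' @param letd Dose-averaged LET, keV/um (>= 0).
#' @param params An [rbe_params()] object.
#' @return Unitless RBE.
#' @export
rbe <- function(dose, letd, params = rbe_params()) {
  ok <- !is.na(dose) & !is.na(letd)
  if (any(dose[ok] < 0) || any(letd[ok] < 0)) {
    abort("dose and letd must be nonnegative")
  }
  ab <- params$alpha_beta_x
  rmax <- params$p0 + params$p1 * letd / ab
  rmin <- params$p2 + params$p3 * sqrt(ab) * letd
  out <- rmax
  pos <- ok & dose > 0
  d <- dose[pos]
  out[pos] <- (sqrt(ab^2 + 4 * d * ab * rmax[pos] + 4 * d^2 * rmin[pos]^2) - ab) /
    (2 * d)
  out[!ok] <- NA_real_
  out
}

#' RBE-weighted dose map
#'
#' Voxelwise `D * RBE(D, LETd)`. Voxels masked (`NA`) in the LET map are
#' treated with the `RBE_max`-limit where dose is present but LET is
#' undefined only if `fill_letd` is given; otherwise they stay masked.
#'
#' @param dose_map,letd_map Congruent arrays (Gy, keV/um).
#' @param params An [rbe_params()].
#' @param fill_letd Optional LET value substituted where `letd_map` is
#'   `NA` but dose is positive (e.g. 0 for negligible-dose regions).
#' @return Array of RBE-weighted dose, Gy(RBE).
#' @export
rbe_weighted_dose <- function(dose_map, letd_map, params = rbe_params(),
                              fill_letd = NULL) {
  if (!identical(dim(dose_map), dim(letd_map))) abort("map grids do not match")
  l <- letd_map
  if (!is.null(fill_letd)) l[is.na(l) & !is.na(dose_map)] <- fill_letd
  out <- dose_map * rbe(dose_map, l, params)
  dim(out) <- dim(dose_map)
  out
}
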
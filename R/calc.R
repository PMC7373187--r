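## Closed-form biophysics calculators.

AVOGADRO <- 6.02214076e23  # mol^-1, exact (2019 SI)

#' DNA contour length from base-pair count
#'
#' B-form DNA rises 0.34 nm per base pair along the helical axis, so a 1-kbp
#' fragment is 340 nm long.
#'
#' @param n_bp Number of base pairs (>= 0).
#' @return Contour length in nm.
#' @examples
#' bp_to_contour_length(1000)  # 340
#' @export
bp_to_contour_length <- function(n_bp) {
  if (any(n_bp < 0)) stop("`n_bp` must be >= 0")
  n_bp * RISE_PER_BP
}

#' Rectangular-box cell geometry
#'
#' @param x_um,y_um,z_um Box dimensions in micrometres (> 0); defaults are a
#'   typical Caulobacter stalked-cell approximation.
#' @export
cell_geometry <- function(x_um = 0.7, y_um = 0.7, z_um = 2.0) {
  d <- c(x_um, y_um, z_um)
  if (any(!is.finite(d)) || any(d <= 0))
    stop("all cell dimensions must be positive")
  structure(list(x_um = x_um, y_um = y_um, z_um = z_um),
            class = "cell_geometry")
}

#' Cell volume in litres from a box geometry
#'
#' Product of the dimensions in um^3 times 1e-15 L/um^3; a 0.7 x 0.7 x 2.0 um
#' box is 0.98e-15 L, i.e. ~1e-15 L to one significant figure.
#'
#' @param geometry A [cell_geometry()].
#' @return Volume in litres.
#' @export
box_volume_liters <- function(geometry = cell_geometry()) {
  stopifnot(inherits(geometry, "cell_geometry"))
  geometry$x_um * geometry$y_um * geometry$z_um * 1e-15
}

#' Intracellular concentration from copy number
#'
#' `copies / (N_A * volume)`: 3,000 copies in 1e-15 L is 4.98 uM, i.e. ~5 uM.
#' No rounding is applied in computation; round only when reporting.
#'
#' @param copies Molecule copy number (>= 0).
#' @param volume_liters Cell volume in litres (> 0).
#' @return Concentration in mol/L.
#' @examples
#' copies_to_concentration(3000, 1e-15) * 1e6  # ~4.98 uM
#' @export
copies_to_concentration <- function(copies, volume_liters) {
  if (any(copies < 0)) stop("`copies` must be >= 0")
  if (any(volume_liters <= 0)) stop("`volume_liters` must be > 0")
  copies / (AVOGADRO * volume_liters)
}
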
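#' Rod-shaped cell geometry
#'
#' Describes the idealized geometry of a rod-shaped bacterium as a cylinder
#' of diameter `diameter_um` capped by hemispheres, lying on the coverslip,
#' imaged by evanescent-field (TIRF) illumination with penetration depth
#' `penetration_depth_um`. Only the cylindrical sidewall is considered for
#' patch placement; poles are excluded.
#'
#' @param length_um Cell length, pole to pole (um). Must exceed the diameter.
#' @param diameter_um Cell diameter (um).
#' @param penetration_depth_um Evanescent-field penetration depth (um);
#'   must lie strictly between 0 and the cell diameter.
#' @return An object of class `cell_geometry`.
#' @examples
#' geom <- cell_geometry(3, 0.89)
#' visible_fraction(geom)
#' @export
cell_geometry <- function(length_um = 3, diameter_um = 0.89,
                          penetration_depth_um = 0.2) {
  stopifnot(is.numeric(length_um), is.numeric(diameter_um),
            is.numeric(penetration_depth_um))
  if (!(diameter_um > 0)) stop("diameter_um must be positive")
  if (!(length_um > diameter_um)) stop("length_um must exceed diameter_um")
  if (!(penetration_depth_um > 0 && penetration_depth_um < diameter_um))
    stop("penetration_depth_um must be in (0, diameter_um)")
  structure(list(length_um = length_um, diameter_um = diameter_um,
                 penetration_depth_um = penetration_depth_um),
            class = "cell_geometry")
}

#' Fraction of the cell circumference visible under TIRF illumination
#'
#' A point on the cylinder surface at azimuthal angle phi (phi = 0 at the
#' coverslip) sits at height z = (D/2)(1 - cos phi). It is visible when
#' z <= h, i.e. |phi| <= arccos(1 - 2h/D), so the visible fraction of the
#' circumference is arccos(1 - 2h/D) / pi. For h >= D the whole
#' circumference is visible and the fraction is capped at 1.
#'
#' @param geom A [cell_geometry()], or a cell diameter in um.
#' @param penetration_depth_um Penetration depth (um); ignored when `geom`
#'   is a `cell_geometry`.
#' @return Visible fraction in (0, 1].
#' @export
visible_fraction <- function(geom, penetration_depth_um = NULL) {
  if (inherits(geom, "cell_geometry")) {
    d <- geom$diameter_um
    h <- geom$penetration_depth_um
  } else {
    d <- geom
    h <- penetration_depth_um
  }
  stopifnot(d > 0, h > 0)
  if (h >= d) return(1)
  acos(1 - 2 * h / d) / pi
}

#' Width of the visible band on the projected cell image
#'
#' Lateral (projected) half-width of the illuminated strip is
#' (D/2) sin(arccos(1 - 2h/D)); the full chord width is twice that.
#'
#' @inheritParams visible_fraction
#' @return Chord width (um) of the visible strip.
#' @export
visible_width <- function(geom, penetration_depth_um = NULL) {
  if (inherits(geom, "cell_geometry")) {
    d <- geom$diameter_um
    h <- geom$penetration_depth_um
  } else {
    d <- geom
    h <- penetration_depth_um
  }
  if (h >= d) return(d)
  d * sin(acos(1 - 2 * h / d))
}

#' Projected area of the visible sidewall strip
#'
#' The cylindrical sidewall has axial extent L - D (hemispherical poles
#' excluded); the illuminated strip has chord width [visible_width()].
#'
#' @inheritParams visible_fraction
#' @return Projected visible area (um^2).
#' @export
visible_area <- function(geom) {
  stopifnot(inherits(geom, "cell_geometry"))
  (geom$length_um - geom$diameter_um) * visible_width(geom)
}
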